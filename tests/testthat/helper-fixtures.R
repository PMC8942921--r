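# shared fixtures and independent oracles

# one-row site table with given pool counts
make_site <- function(counts_w, counts_m, qual = 60, base_qual = NA_real_,
                      alt = "T", pos = 100) {
  s <- data.frame(chrom = "chr1", pos = pos, ref = "A", alt = alt,
                  qual = qual, base_qual = base_qual, has_depth = TRUE,
                  stringsAsFactors = FALSE)
  s$counts_w <- list(as.integer(counts_w))
  s$counts_m <- list(as.integer(counts_m))
  s
}

# random biallelic site table, sorted, on one chromosome
random_sites <- function(n, chrom_len = 1e6, seed = 1) {
  set.seed(seed)
  pos <- sort(sample.int(chrom_len, n))
  s <- data.frame(chrom = "chr1", pos = pos, ref = "A", alt = "T",
                  qual = runif(n, 10, 80),
                  base_qual = ifelse(runif(n) < 0.3, NA, runif(n, 10, 60)),
                  has_depth = TRUE, stringsAsFactors = FALSE)
  s$counts_w <- lapply(seq_len(n), function(i) {
    d <- sample(0:150, 1); a <- rbinom(1, d, runif(1)); c(d - a, a)
  })
  s$counts_m <- lapply(seq_len(n), function(i) {
    d <- sample(0:150, 1); a <- rbinom(1, d, runif(1)); c(d - a, a)
  })
  s
}

# O(sites x windows) reference for window aggregation
brute_force_aggregate <- function(windows, indexed) {
  windows$n_sites <- 0L
  windows$mean_index_w <- NA_real_
  windows$mean_index_m <- NA_real_
  windows$mean_delta <- NA_real_
  windows$mean_depth <- NA_real_
  for (i in seq_len(nrow(windows))) {
    p0 <- indexed$pos - 1
    inw <- indexed$chrom == windows$chrom[i] &
      p0 >= windows$start[i] & p0 < windows$end[i]
    windows$n_sites[i] <- sum(inw)
    if (any(inw)) {
      windows$mean_index_w[i] <- mean(indexed$snp_index_w[inw])
      windows$mean_index_m[i] <- mean(indexed$snp_index_m[inw])
      windows$mean_delta[i] <- mean(indexed$delta[inw])
      windows$mean_depth[i] <-
        mean((indexed$depth_w[inw] + indexed$depth_m[inw]) / 2)
    }
  }
  windows
}

# exact distribution of the majority-oriented delta SNP-index for one
# individual per pool sequenced to depth one read: full enumeration over
# genotype dosage (1:2:1) and the single read of each pool
enumerate_null_delta_n1_d1 <- function() {
  gp <- c(`0` = 0.25, `1` = 0.5, `2` = 0.25)
  prob <- numeric(0)
  for (gm in 0:2) for (rm in 0:1) for (gw in 0:2) for (rw in 0:1) {
    fm <- gm / 2
    fw <- gw / 2
    p <- gp[[as.character(gm)]] * gp[[as.character(gw)]] *
      (if (rm == 1) fm else 1 - fm) * (if (rw == 1) fw else 1 - fw)
    if (p == 0) next
    # orientation: majority allele of the single M read (tie impossible)
    im <- 1                       # the M read always matches itself
    iw <- if (rw == rm) 1 else 0  # W read matches the M-pool allele or not
    d <- as.character(im - iw)
    if (!d %in% names(prob)) prob[d] <- 0
    prob[d] <- prob[d] + p
  }
  prob
}

# a genotype/phenotype table with the given consistent class counts
consistent_calls <- function(n_hom_wt, n_het, n_hom_mut) {
  g <- c(rep("hom_wt", n_hom_wt), rep("het", n_het), rep("hom_mut", n_hom_mut))
  data.frame(id = seq_along(g), genotype = g,
             phenotype = ifelse(g == "hom_mut", "dwarf", "normal"),
             stringsAsFactors = FALSE)
}

# marker offset (bp) giving recombination fraction r at 3 cM/Mb under Haldane
bp_for_r <- function(r, cm_per_mb = 3) {
  if (r >= 0.5) return(1e9)
  d <- -log(1 - 2 * r) / 2                 # Morgans
  d * 100 / cm_per_mb * 1e6
}
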