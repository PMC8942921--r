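#' Simulate an F2 population from a cross model
#'
#' Each individual is the union of two gametes, generated independently per
#' chromosome as a Markov chain along the ordered markers: the first marker's
#' allele is mutant with probability 1/2, and the allele switches between
#' adjacent markers with the Haldane recombination fraction
#' `c = (1 - exp(-2 d)) / 2`, where `d` (Morgans) is the physical gap scaled by
#' the model's `cm_per_mb`. Dosages are gamete sums; the phenotype is
#' `"dwarf"` iff the causal-locus dosage is 2.
#'
#' @param model a [cross_model()].
#' @param seed seed for this stage; defaults to a stream derived from the
#'   model seed.
#' @return a list with `dosage` (n_f2 x markers integer matrix of mutant-allele
#'   dosages in 0..2), `phenotype` (`"normal"`/`"dwarf"`), and `markers`
#'   (data frame of chrom/pos, one row per dosage column).
#' @export
simulate_f2 <- function(model, seed = derive_seed(model$seed, 1L)) {
  stopifnot(inherits(model, "cross_model"))
  mk <- marker_table(model)
  n <- model$n_f2
  with_seed(seed, {
    dos <- matrix(0L, nrow = n, ncol = nrow(mk))
    for (ch in names(model$markers)) {
      cols <- which(mk$chrom == ch)
      pos <- model$markers[[ch]]
      d <- diff(pos) / 1e6 * model$cm_per_mb / 100  # Morgans
      cfrac <- 0.5 * (1 - exp(-2 * d))
      g <- gamete_matrix(2L * n, cfrac)
      odd <- seq(1L, 2L * n, by = 2L)
      dos[, cols] <- g[odd, , drop = FALSE] + g[odd + 1L, , drop = FALSE]
    }
    phen <- ifelse(dos[, causal_index(model)] == 2L, "dwarf", "normal")
    list(dosage = dos, phenotype = phen, markers = mk)
  })
}

# ng gametes over length(cfrac)+1 ordered markers; 0/1 = wild-type/mutant
gamete_matrix <- function(ng, cfrac) {
  m <- length(cfrac) + 1L
  g <- matrix(0L, nrow = ng, ncol = m)
  g[, 1L] <- stats::rbinom(ng, 1L, 0.5)
  for (j in seq_along(cfrac)) {
    sw <- stats::rbinom(ng, 1L, cfrac[j])
    g[, j + 1L] <- (g[, j] + sw) %% 2L
  }
  g
}

#' Build phenotypic pools and their true allele frequencies
#'
#' Selects the first `pool_size_w` phenotypically normal and the first
#' `pool_size_m` dwarf individuals in simulation order (a deterministic rule,
#' so pooled data are reproducible) and returns each pool's per-marker mutant
#' allele frequency, `sum(dosage) / (2 * pool size)`.
#'
#' @param f2 result of [simulate_f2()].
#' @param model the [cross_model()] that produced it.
#' @return list with `w_idx`, `m_idx` (row indices), `freq_w`, `freq_m`
#'   (per-marker frequencies in `[0, 1]`) and `markers`.
#' @export
build_pools <- function(f2, model) {
  w_all <- which(f2$phenotype == "normal")
  m_all <- which(f2$phenotype == "dwarf")
  if (length(w_all) < model$pool_size_w) {
    stop(sprintf("need %d normal individuals for the W pool but only %d exist",
                 model$pool_size_w, length(w_all)))
  }
  if (length(m_all) < model$pool_size_m) {
    stop(sprintf("need %d dwarf individuals for the M pool but only %d exist",
                 model$pool_size_m, length(m_all)))
  }
  w_idx <- w_all[seq_len(model$pool_size_w)]
  m_idx <- m_all[seq_len(model$pool_size_m)]
  list(
    w_idx = w_idx, m_idx = m_idx,
    freq_w = colSums(f2$dosage[w_idx, , drop = FALSE]) / (2 * length(w_idx)),
    freq_m = colSums(f2$dosage[m_idx, , drop = FALSE]) / (2 * length(m_idx)),
    markers = f2$markers
  )
}

#' Sample pooled reads at given allele frequencies
#'
#' Total depth per site is `depth_mean` exactly (`depth_model = "fixed"`) or
#' Poisson-distributed around it. Each read reports the mutant allele with
#' probability `freq * (1 - error_rate) + (1 - freq) * error_rate` — a
#' symmetric per-read allele flip.
#'
#' @param freq vector of pool mutant-allele frequencies in `[0, 1]`.
#' @param model a [cross_model()] supplying depth and error parameters.
#' @param seed seed for this stage.
#' @return list with integer vectors `ref`, `alt` and `depth` (= ref + alt).
#' @export
sample_reads <- function(freq, model, seed = derive_seed(model$seed, 2L)) {
  stopifnot(all(freq >= 0 & freq <= 1))
  with_seed(seed, {
    n <- length(freq)
    depth <- switch(model$depth_model,
      fixed = rep.int(as.integer(round(model$depth_mean)), n),
      poisson = stats::rpois(n, model$depth_mean)
    )
    p_alt <- freq * (1 - model$error_rate) + (1 - freq) * model$error_rate
    alt <- stats::rbinom(n, depth, p_alt)
    list(ref = depth - alt, alt = alt, depth = depth)
  })
}

#' Simulate a complete pooled-sequencing BSA dataset
#'
#' Runs [simulate_f2()], [build_pools()] and [sample_reads()] (one independent
#' read-sampling stream per pool) and assembles a VCF-ready site table in
#' which the alternate allele is, by construction, the mutant allele, plus a
#' truth table recording the pools' true allele frequencies and the causal
#' marker. Fully deterministic given the model (including its seed).
#'
#' @param object a [cross_model()].
#' @param nsim unused (one dataset per call); present for the generic.
#' @param seed overrides the model seed if non-NULL.
#' @param ... unused.
#' @return object of class `"f2_sim"`: the model plus `f2`, `pools`, `sites`
#'   (see [read_sites()] for the column contract) and `truth` (chrom, pos,
#'   true_freq_w, true_freq_m, is_causal).
#' @export
#' @examples
#' sim <- simulate(study_cross_model(seed = 7, n_f2 = 150))
#' head(sim$truth[sim$truth$is_causal, ])
simulate.cross_model <- function(object, nsim = 1, seed = NULL, ...) {
  seed <- as.integer(seed %||% object$seed)
  f2 <- simulate_f2(object, derive_seed(seed, 1L))
  pools <- build_pools(f2, object)
  rw <- sample_reads(pools$freq_w, object, derive_seed(seed, 2L))
  rm_ <- sample_reads(pools$freq_m, object, derive_seed(seed, 3L))
  mk <- f2$markers
  sites <- data.frame(
    chrom = mk$chrom, pos = mk$pos,
    ref = "A", alt = "T",
    qual = object$variant_qual, base_qual = object$base_qual,
    has_depth = TRUE, stringsAsFactors = FALSE
  )
  sites$counts_w <- unname(Map(function(r, a) c(r, a), rw$ref, rw$alt))
  sites$counts_m <- unname(Map(function(r, a) c(r, a), rm_$ref, rm_$alt))
  truth <- data.frame(
    chrom = mk$chrom, pos = mk$pos,
    true_freq_w = pools$freq_w, true_freq_m = pools$freq_m,
    is_causal = seq_len(nrow(mk)) == causal_index(object),
    stringsAsFactors = FALSE
  )
  structure(
    list(model = object, seed = seed, f2 = f2, pools = pools,
         sites = sites, truth = truth),
    class = "f2_sim"
  )
}

#' @export
print.f2_sim <- function(x, ...) {
  cat(sprintf("Simulated F2 BSA dataset: %d sites, seed %d\n",
              nrow(x$sites), x$seed))
  cat(sprintf("  phenotypes: %d normal / %d dwarf of %d F2\n",
              sum(x$f2$phenotype == "normal"),
              sum(x$f2$phenotype == "dwarf"), x$model$n_f2))
  ci <- which(x$truth$is_causal)
  cat(sprintf("  causal %s:%s  true freq W=%.3f M=%.3f\n",
              x$truth$chrom[ci],
              format(x$truth$pos[ci], big.mark = ",", scientific = FALSE),
              x$truth$true_freq_w[ci], x$truth$true_freq_m[ci]))
  invisible(x)
}

#' Write a simulated dataset to disk as VCF plus truth table
#'
#' Emits one VCF v4.2 record per marker with two samples, `"W"` and `"M"`,
#' genotypes `"./."` (pools carry no single genotype) and per-sample allele
#' depths (`AD`), and a tab-separated truth file. Identical models (including
#' seed) produce byte-identical output.
#'
#' @param model a [cross_model()] or an already-simulated `"f2_sim"`.
#' @param vcf_path,truth_path output paths.
#' @return invisibly, a list with the two paths and the simulation object.
#' @export
emit_dataset <- function(model, vcf_path, truth_path) {
  sim <- if (inherits(model, "f2_sim")) model else simulate(model)
  write_sites(sim$sites, vcf_path,
              chrom_lengths = sim$model$chromosomes,
              source_line = sprintf("bsamap simulate seed=%d", sim$seed))
  tr <- sim$truth
  tr$true_freq_w <- formatC(tr$true_freq_w, digits = 6, format = "f")
  tr$true_freq_m <- formatC(tr$true_freq_m, digits = 6, format = "f")
  tr$is_causal <- as.integer(tr$is_causal)
  con <- file(truth_path, "w")
  on.exit(close(con))
  writeLines(sprintf("# bsamap truth file; seed=%d", sim$seed), con)
  utils::write.table(tr, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(vcf = vcf_path, truth = truth_path, sim = sim))
}

#' Read a truth table written by [emit_dataset()]
#' @param path truth file path.
#' @return data frame with chrom, pos, true_freq_w, true_freq_m, is_causal.
#' @export
read_truth <- function(path) {
  tr <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  tr$is_causal <- as.logical(tr$is_causal)
  tr
}
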