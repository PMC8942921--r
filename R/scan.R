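#' Sliding windows over one chromosome
#'
#' Windows are anchored at 0 and advanced by `step` while the start lies
#' inside the chromosome; each window's end is truncated at the chromosome
#' length. Coordinates are 0-based half-open internally (a 1-based site
#' position `p` belongs to windows with `start <= p - 1 < end`).
#'
#' @param chrom_length chromosome length in bp.
#' @param window_size window width in bp (default 2,500,000 — a 2500-kb
#'   sliding window).
#' @param step step size in bp (default 20,000).
#' @param chrom chromosome name for the output table.
#' @return data frame with `chrom`, `start`, `end` in ascending start order.
#' @export
make_windows <- function(chrom_length, window_size = 2.5e6, step = 2e4,
                         chrom = "chr") {
  if (window_size <= 0 || step <= 0 || chrom_length <= 0) {
    stop("chrom_length, window_size and step must be positive")
  }
  starts <- step * (seq_len(ceiling(chrom_length / step)) - 1)
  data.frame(chrom = chrom, start = starts,
             end = pmin(starts + window_size, chrom_length),
             stringsAsFactors = FALSE)
}

make_windows_genome <- function(chrom_lengths, window_size = 2.5e6,
                                step = 2e4) {
  do.call(rbind, lapply(names(chrom_lengths), function(ch) {
    make_windows(chrom_lengths[[ch]], window_size, step, chrom = ch)
  }))
}

#' Average SNP-indices over sliding windows
#'
#' Assigns every indexed site to all windows covering it and computes
#' unweighted means of the W-pool index, M-pool index and delta per window,
#' plus the site count and mean depth (used for confidence-band lookup).
#' Windows without sites carry `NA` means and `n_sites = 0`.
#'
#' @param windows window table from [make_windows()] (possibly several
#'   chromosomes row-bound).
#' @param indexed indexed site table from [index_sites()], sorted by
#'   `(chrom, pos)`.
#' @return the window table with `n_sites`, `mean_index_w`, `mean_index_m`,
#'   `mean_delta` and `mean_depth` appended.
#' @export
aggregate_windows <- function(windows, indexed) {
  ord <- order(indexed$chrom, indexed$pos)
  if (!identical(ord, seq_len(nrow(indexed)))) {
    stop("indexed sites must be sorted by (chrom, pos)")
  }
  windows$n_sites <- 0L
  windows$mean_index_w <- NA_real_
  windows$mean_index_m <- NA_real_
  windows$mean_delta <- NA_real_
  windows$mean_depth <- NA_real_
  for (ch in unique(windows$chrom)) {
    wi <- which(windows$chrom == ch)
    si <- which(indexed$chrom == ch)
    if (length(si) == 0) next
    pos0 <- indexed$pos[si] - 1  # 0-based site coordinates, sorted
    cum <- function(x) c(0, cumsum(x))
    cw <- cum(indexed$snp_index_w[si])
    cm <- cum(indexed$snp_index_m[si])
    cd <- cum(indexed$delta[si])
    cdep <- cum((indexed$depth_w[si] + indexed$depth_m[si]) / 2)
    # sites with start <= pos0 < end: ranks via binary search on sorted pos0
    lo <- findInterval(windows$start[wi] - 0.5, pos0)   # count of pos0 < start
    hi <- findInterval(windows$end[wi] - 0.5, pos0)     # count of pos0 < end
    n <- hi - lo
    windows$n_sites[wi] <- n
    nz <- n > 0
    idx <- wi[nz]
    windows$mean_index_w[idx] <- (cw[hi + 1] - cw[lo + 1])[nz] / n[nz]
    windows$mean_index_m[idx] <- (cm[hi + 1] - cm[lo + 1])[nz] / n[nz]
    windows$mean_delta[idx] <- (cd[hi + 1] - cd[lo + 1])[nz] / n[nz]
    windows$mean_depth[idx] <- (cdep[hi + 1] - cdep[lo + 1])[nz] / n[nz]
  }
  windows
}

#' Monte-Carlo null distribution of the delta SNP-index
#'
#' Simulates the delta SNP-index at a marker unlinked to the phenotype: each
#' pool's allele frequency is the mean dosage of `pool_size` genotypes drawn
#' 1:2:1 from {0,1,2} (equivalently Binomial(2n, 1/2)/2n), read counts are
#' Binomial(depth, freq) per pool, and the statistic is computed exactly as
#' the analysis does — including the majority orientation on the M pool — so
#' band and statistic are exchangeable. Empirical two-sided quantiles at each
#' confidence level form the band, per depth on a grid.
#'
#' @param pool_size_w,pool_size_m pool sizes.
#' @param depths integer vector of sequencing depths to simulate (the band is
#'   later looked up at the grid depth nearest each window's mean depth).
#' @param levels confidence levels (default 0.95 and 0.99).
#' @param n_reps replicates per depth (at least 1000 for production use;
#'   smaller values are accepted for quick checks).
#' @param seed integer seed; identical arguments give an identical band.
#' @return object of class `"bsa_band"`: `depths`, `levels`, `lower` and
#'   `upper` (depth x level matrices of quantiles), plus the simulation
#'   parameters.
#' @export
null_band <- function(pool_size_w = 50, pool_size_m = 50,
                      depths = c(10, 20, 40, 80), levels = c(0.95, 0.99),
                      n_reps = 2000, seed = 1L) {
  stopifnot(n_reps >= 1, all(depths >= 1), all(levels > 0 & levels < 1))
  lower <- upper <- matrix(NA_real_, length(depths), length(levels),
                           dimnames = list(depths, levels))
  with_seed(seed, {
    for (i in seq_along(depths)) {
      d <- as.integer(depths[i])
      delta <- null_delta_draws(n_reps, pool_size_w, pool_size_m, d)
      for (j in seq_along(levels)) {
        a <- (1 - levels[j]) / 2
        q <- stats::quantile(delta, c(a, 1 - a), names = FALSE)
        lower[i, j] <- q[1]
        upper[i, j] <- q[2]
      }
    }
  })
  structure(
    list(depths = depths, levels = levels, lower = lower, upper = upper,
         pool_size_w = pool_size_w, pool_size_m = pool_size_m,
         n_reps = n_reps, seed = as.integer(seed)),
    class = "bsa_band"
  )
}

# n draws of the majority-oriented delta SNP-index under the null.
# Pool allele frequency: Binomial(2*pool_size, 1/2) / (2*pool_size), i.e.
# the mean of pool_size genotype dosages drawn 1:2:1 from {0,1,2}.
null_delta_draws <- function(n, pool_size_w, pool_size_m, depth) {
  fw <- stats::rbinom(n, 2L * pool_size_w, 0.5) / (2 * pool_size_w)
  fm <- stats::rbinom(n, 2L * pool_size_m, 0.5) / (2 * pool_size_m)
  aw <- stats::rbinom(n, depth, fw)
  am <- stats::rbinom(n, depth, fm)
  alt_major <- am >= depth - am  # tie -> alt, as in the analysis
  im <- ifelse(alt_major, am, depth - am) / depth
  iw <- ifelse(alt_major, aw, depth - aw) / depth
  im - iw
}

#' Simulate unlinked sites through the analysis path
#'
#' Draws `n_sites` independent null sites (the generative model of
#' [null_band()]) and returns them as a site table, so calibration checks can
#' push genuinely unlinked data through [index_sites()] and compare against
#' the band.
#'
#' @inheritParams null_band
#' @param n_sites number of sites.
#' @param depth fixed per-pool depth.
#' @param seed integer seed.
#' @return a site table (one chromosome, positions 1..n_sites).
#' @export
simulate_null_sites <- function(n_sites, pool_size_w = 50, pool_size_m = 50,
                                depth = 40, seed = 1L) {
  with_seed(seed, {
    fw <- stats::rbinom(n_sites, 2L * pool_size_w, 0.5) / (2 * pool_size_w)
    fm <- stats::rbinom(n_sites, 2L * pool_size_m, 0.5) / (2 * pool_size_m)
    aw <- stats::rbinom(n_sites, depth, fw)
    am <- stats::rbinom(n_sites, depth, fm)
    sites <- data.frame(
      chrom = "null", pos = seq_len(n_sites), ref = "A", alt = "T",
      qual = 60, base_qual = NA_real_, has_depth = TRUE,
      stringsAsFactors = FALSE
    )
    sites$counts_w <- unname(Map(function(r, a) c(r, a), depth - aw, aw))
    sites$counts_m <- unname(Map(function(r, a) c(r, a), depth - am, am))
    sites
  })
}

#' @export
print.bsa_band <- function(x, ...) {
  cat(sprintf(
    "Null delta-SNP-index band (pools W=%d/M=%d, %d reps, seed %d)\n",
    x$pool_size_w, x$pool_size_m, x$n_reps, x$seed))
  for (j in seq_along(x$levels)) {
    cat(sprintf("  %g%%: ", 100 * x$levels[j]))
    cat(sprintf("d=%g [%.3f, %.3f]", x$depths,
                x$lower[, j], x$upper[, j]), sep = "  ")
    cat("\n")
  }
  invisible(x)
}

#' Look up band bounds at the nearest simulated depth
#' @param band a `"bsa_band"`.
#' @param depth observed (window mean) depth(s).
#' @param level one of the band's confidence levels.
#' @return two-column matrix `lower`, `upper`, one row per depth.
#' @export
band_lookup <- function(band, depth, level = 0.95) {
  j <- match(level, band$levels)
  if (is.na(j)) {
    stop("level ", level, " not in band (available: ",
         paste(band$levels, collapse = ", "), ")")
  }
  i <- vapply(depth, function(d) which.min(abs(band$depths - d)), integer(1))
  cbind(lower = band$lower[i, j], upper = band$upper[i, j])
}

#' Call candidate regions from significant windows
#'
#' A window is significant when it contains at least one site and its mean
#' delta SNP-index exceeds the upper band value at its mean depth. Runs of at
#' least `min_consecutive` consecutive significant windows on a chromosome
#' are merged into a candidate region spanning the union of their intervals.
#'
#' @param windows aggregated window table (see [aggregate_windows()]).
#' @param band a `"bsa_band"` from [null_band()].
#' @param level confidence level to test against.
#' @param min_consecutive minimum run length of significant windows
#'   (default 3, suppressing isolated noisy windows).
#' @return data frame of regions: `chrom`, `start`, `end`, `peak_start`
#'   (start of the window with the largest mean delta), `max_delta`,
#'   `n_windows`; zero rows when nothing is significant.
#' @export
call_regions <- function(windows, band, level = 0.95, min_consecutive = 3) {
  sig <- rep(FALSE, nrow(windows))
  nz <- windows$n_sites > 0
  if (any(nz)) {
    ub <- band_lookup(band, windows$mean_depth[nz], level)[, "upper"]
    sig[nz] <- windows$mean_delta[nz] > ub
  }
  out <- list()
  for (ch in unique(windows$chrom)) {
    wi <- which(windows$chrom == ch)
    r <- rle(sig[wi])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in which(r$values & r$lengths >= min_consecutive)) {
      run <- wi[starts[k]:ends[k]]
      peak <- run[which.max(windows$mean_delta[run])]
      out[[length(out) + 1]] <- data.frame(
        chrom = ch,
        start = min(windows$start[run]),
        end = max(windows$end[run]),
        peak_start = windows$start[peak],
        max_delta = windows$mean_delta[peak],
        n_windows = length(run),
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(out) == 0) {
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      peak_start = numeric(), max_delta = numeric(),
                      n_windows = integer(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start), , drop = FALSE]
}
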