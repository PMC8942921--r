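#' Bulked-segregant genome scan for a recessive locus
#'
#' The package's central fitter. Runs the full mapping analysis on a two-pool
#' variant table: reliability filtering ([filter_config()]), per-site
#' SNP-index and delta SNP-index ([index_sites()]), sliding-window averaging
#' ([aggregate_windows()]), a Monte-Carlo null confidence band
#' ([null_band()]), and candidate-region calling ([call_regions()]).
#'
#' @param sites a site table (from [read_sites()] or
#'   [simulate.cross_model()]) or a path to a VCF file.
#' @param w_sample,m_sample sample names, used when `sites` is a VCF path.
#' @param chrom_lengths named vector of chromosome lengths; when `NULL`,
#'   each chromosome's largest site position is used.
#' @param window_size,step sliding-window geometry in bp (defaults: 2500-kb
#'   window, 20-kb step).
#' @param filter a [filter_config()].
#' @param level confidence level used for region calling (the band is always
#'   computed at 0.95 and 0.99 so both can be reported).
#' @param pool_size_w,pool_size_m individuals per pool, parameterizing the
#'   null simulation.
#' @param depth_grid depths at which the null band is simulated.
#' @param n_reps null-simulation replicates per depth.
#' @param min_consecutive minimum run of significant windows per region.
#' @param seed integer seed for the null simulation.
#' @return object of class `"bsa_scan"` with components `sites` (indexed
#'   sites), `tally` (filter-reason counts), `windows` (aggregated, with
#'   `ci95_lo/hi` and `ci99_lo/hi` columns), `band`, `regions`, `params`,
#'   `call`.
#' @seealso [print.bsa_scan()], [summary.bsa_scan()], [plot.bsa_scan()]
#' @export
#' @examples
#' sim <- simulate(study_cross_model(seed = 42))
#' fit <- bsa_scan(sim$sites, chrom_lengths = sim$model$chromosomes,
#'                 n_reps = 500, seed = 42)
#' fit
bsa_scan <- function(sites, w_sample = "W", m_sample = "M",
                     chrom_lengths = NULL,
                     window_size = 2.5e6, step = 2e4,
                     filter = filter_config(), level = 0.95,
                     pool_size_w = 50, pool_size_m = 50,
                     depth_grid = c(10, 20, 40, 80), n_reps = 2000,
                     min_consecutive = 3, seed = 1L) {
  cl <- match.call()
  if (is.character(sites)) {
    sites <- read_sites(sites, w_sample = w_sample, m_sample = m_sample)
  }
  ix <- index_sites(sites, filter)
  idx <- ix$sites[order(ix$sites$chrom, ix$sites$pos), , drop = FALSE]
  if (is.null(chrom_lengths)) {
    chrom_lengths <- tapply(sites$pos, sites$chrom, max)
    chrom_lengths <- stats::setNames(as.numeric(chrom_lengths),
                                     names(chrom_lengths))
  }
  windows <- make_windows_genome(chrom_lengths, window_size, step)
  windows <- aggregate_windows(windows, idx)
  band <- null_band(pool_size_w, pool_size_m, depths = depth_grid,
                    levels = c(0.95, 0.99), n_reps = n_reps, seed = seed)
  nz <- windows$n_sites > 0
  for (lv in c(0.95, 0.99)) {
    tag <- if (lv == 0.95) "ci95" else "ci99"
    lo <- hi <- rep(NA_real_, nrow(windows))
    if (any(nz)) {
      b <- band_lookup(band, windows$mean_depth[nz], lv)
      lo[nz] <- b[, "lower"]
      hi[nz] <- b[, "upper"]
    }
    windows[[paste0(tag, "_lo")]] <- lo
    windows[[paste0(tag, "_hi")]] <- hi
  }
  regions <- call_regions(windows, band, level = level,
                          min_consecutive = min_consecutive)
  structure(
    list(sites = idx, tally = ix$tally, windows = windows, band = band,
         regions = regions,
         params = list(window_size = window_size, step = step,
                       filter = filter, level = level,
                       pool_size_w = pool_size_w, pool_size_m = pool_size_m,
                       depth_grid = depth_grid, n_reps = n_reps,
                       min_consecutive = min_consecutive, seed = seed,
                       chrom_lengths = chrom_lengths),
         call = cl),
    class = "bsa_scan"
  )
}

#' @export
print.bsa_scan <- function(x, ...) {
  cat("Bulked-segregant genome scan\n")
  cat(sprintf("  sites: %d passed filter of %d read\n",
              x$tally[["pass"]], sum(x$tally)))
  cat(sprintf("  windows: %d (%g kb, step %g kb); band at %g%% (%d reps)\n",
              nrow(x$windows), x$params$window_size / 1e3,
              x$params$step / 1e3, 100 * x$params$level, x$params$n_reps))
  if (nrow(x$regions) == 0) {
    cat("  no candidate region called\n")
  } else {
    cat(sprintf("  %d candidate region(s):\n", nrow(x$regions)))
    for (i in seq_len(nrow(x$regions))) {
      r <- x$regions[i, ]
      cat(sprintf("    %s:%.2f-%.2f Mb  peak %.2f Mb  max delta %.3f (%d windows)\n",
                  r$chrom, r$start / 1e6, r$end / 1e6,
                  r$peak_start / 1e6, r$max_delta, r$n_windows))
    }
  }
  invisible(x)
}

#' @rdname print.bsa_scan
#' @param object,x a `"bsa_scan"`.
#' @param ... unused.
#' @export
summary.bsa_scan <- function(object, ...) {
  x <- object
  print(x)
  cat("  filter tally:",
      paste(sprintf("%s=%d", names(x$tally), x$tally), collapse = ", "), "\n")
  nz <- x$windows$n_sites > 0
  cat(sprintf("  windows with sites: %d of %d; mean delta range [%.3f, %.3f]\n",
              sum(nz), nrow(x$windows),
              min(x$windows$mean_delta[nz]), max(x$windows$mean_delta[nz])))
  print(x$band)
  invisible(x)
}

#' Plot SNP-index tracks and the delta scan with its confidence band
#'
#' One panel per chromosome: window means of the M-pool and W-pool SNP-index
#' (thin lines) and the delta SNP-index (thick line) against genome position,
#' with the per-window 95% (and 99%, dotted) band and called regions shaded.
#'
#' @param x a `"bsa_scan"`.
#' @param what `"delta"` (default) or `"index"` (pool index tracks only).
#' @param ... passed to [graphics::plot()].
#' @export
plot.bsa_scan <- function(x, what = c("delta", "index"), ...) {
  what <- match.arg(what)
  chroms <- unique(x$windows$chrom)
  old <- graphics::par(mfrow = c(length(chroms), 1),
                       mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (ch in chroms) {
    w <- x$windows[x$windows$chrom == ch & x$windows$n_sites > 0, ]
    mid <- (w$start + w$end) / 2 / 1e6
    if (what == "delta") {
      graphics::plot(mid, w$mean_delta, type = "l", lwd = 2,
                     ylim = c(-1, 1), xlab = paste(ch, "(Mb)"),
                     ylab = expression(Delta ~ "SNP-index"), main = ch, ...)
      graphics::lines(mid, w$ci95_hi, col = "grey40", lty = 2)
      graphics::lines(mid, w$ci95_lo, col = "grey40", lty = 2)
      graphics::lines(mid, w$ci99_hi, col = "grey70", lty = 3)
      graphics::lines(mid, w$ci99_lo, col = "grey70", lty = 3)
      reg <- x$regions[x$regions$chrom == ch, ]
      if (nrow(reg) > 0) {
        graphics::rect(reg$start / 1e6, -1, reg$end / 1e6, 1,
                       col = grDevices::adjustcolor("tomato", 0.15),
                       border = NA)
      }
      graphics::abline(h = 0, col = "grey80")
    } else {
      graphics::plot(mid, w$mean_index_m, type = "l", col = "tomato",
                     ylim = c(0, 1), xlab = paste(ch, "(Mb)"),
                     ylab = "SNP-index", main = ch, ...)
      graphics::lines(mid, w$mean_index_w, col = "steelblue")
      graphics::legend("topright", legend = c("M pool", "W pool"),
                       col = c("tomato", "steelblue"), lty = 1, bty = "n")
    }
  }
  invisible(x)
}
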