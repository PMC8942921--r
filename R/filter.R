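#' Configure the SNP reliability filter
#'
#' The filter keeps a site only if it is (1) bi-allelic between the two
#' pools, (2) its variant quality — and mean base quality when annotated —
#' exceeds `min_quality` (phred 20 by default), and (3) each pool's read
#' depth lies strictly between `min_reads_exclusive` and
#' `max_reads_exclusive` (more than 3 and less than 120 reads by default,
#' so depths of exactly 3 or 120 are rejected).
#'
#' `quality_strict` controls whether the quality comparison is `>` (default)
#' or `>=`; both conventions appear in practice and the choice is exposed
#' rather than hidden.
#'
#' @param min_quality phred threshold for variant and base quality.
#' @param quality_strict if `TRUE`, require quality strictly greater than
#'   `min_quality`; if `FALSE`, greater-or-equal.
#' @param min_reads_exclusive,max_reads_exclusive exclusive per-pool depth
#'   bounds.
#' @param require_biallelic reject multi-allelic records.
#' @return object of class `"filter_config"`.
#' @export
filter_config <- function(min_quality = 20, quality_strict = TRUE,
                          min_reads_exclusive = 3, max_reads_exclusive = 120,
                          require_biallelic = TRUE) {
  stopifnot(min_reads_exclusive >= 0,
            min_reads_exclusive < max_reads_exclusive)
  structure(
    list(min_quality = min_quality, quality_strict = quality_strict,
         min_reads_exclusive = min_reads_exclusive,
         max_reads_exclusive = max_reads_exclusive,
         require_biallelic = require_biallelic),
    class = "filter_config"
  )
}

#' @export
print.filter_config <- function(x, ...) {
  cat(sprintf(
    "SNP filter: biallelic=%s; quality %s %g; per-pool depth in (%g, %g)\n",
    x$require_biallelic, if (x$quality_strict) ">" else ">=",
    x$min_quality, x$min_reads_exclusive, x$max_reads_exclusive))
  invisible(x)
}

# vectorized reason classification; "" = pass.
# First failure wins, in the fixed order multiallelic -> quality -> depth.
# Sites lacking allele depths cannot establish an in-bounds depth and fail
# with reason "depth".
classify_sites <- function(sites, cfg) {
  n <- nrow(sites)
  reason <- character(n)
  n_alt <- lengths(strsplit(sites$alt, ",", fixed = TRUE))
  if (cfg$require_biallelic) {
    reason[n_alt > 1] <- "multiallelic"
  }
  cmp <- if (cfg$quality_strict) `>` else `>=`
  q_ok <- !is.na(sites$qual) & cmp(sites$qual, cfg$min_quality) &
    (is.na(sites$base_qual) | cmp(sites$base_qual, cfg$min_quality))
  reason[reason == "" & !q_ok] <- "quality"
  dsum <- function(col) {
    vapply(sites[[col]], function(v) if (anyNA(v)) NA_real_ else sum(v),
           numeric(1))
  }
  dw <- dsum("counts_w")
  dm <- dsum("counts_m")
  d_ok <- !is.na(dw) & !is.na(dm) &
    dw > cfg$min_reads_exclusive & dw < cfg$max_reads_exclusive &
    dm > cfg$min_reads_exclusive & dm < cfg$max_reads_exclusive
  reason[reason == "" & !d_ok] <- "depth"
  reason
}

#' Test one site against the reliability filter
#'
#' @param site a single-row site table (or list with the same fields, where
#'   `counts_w`/`counts_m` are integer vectors).
#' @param cfg a [filter_config()].
#' @return list with `pass` (logical) and `reason` (`""`, `"multiallelic"`,
#'   `"quality"` or `"depth"`; the first failed criterion wins).
#' @export
#' @examples
#' s <- data.frame(chrom = "chr1", pos = 100, ref = "A", alt = "T",
#'                 qual = 60, base_qual = 35, has_depth = TRUE)
#' s$counts_w <- list(c(27L, 13L)); s$counts_m <- list(c(0L, 40L))
#' passes_filters(s, filter_config())
passes_filters <- function(site, cfg = filter_config()) {
  site <- as_site_df(site)
  r <- classify_sites(site, cfg)[1]
  list(pass = r == "", reason = r)
}

as_site_df <- function(site) {
  if (is.data.frame(site)) return(site)
  df <- data.frame(chrom = site$chrom %||% "chr", pos = site$pos %||% 1,
                   ref = site$ref, alt = paste(site$alts %||% site$alt,
                                               collapse = ","),
                   qual = site$qual, base_qual = site$base_qual %||% NA_real_,
                   stringsAsFactors = FALSE)
  df$counts_w <- list(site$counts_w)
  df$counts_m <- list(site$counts_m)
  df
}

#' Orient a site on its mutant-pool allele
#'
#' The statistic needs each site expressed relative to "the allele carried by
#' the M pool". In a recessive design the mutant pool is nearly fixed for the
#' causal-linked allele, so the majority allele in the M pool is taken as the
#' M-pool allele; ties break toward the alternate allele.
#'
#' @param site single-row site table (bi-allelic).
#' @return the allele string (`ref` or `alt`).
#' @export
pick_m_allele <- function(site) {
  site <- as_site_df(site)
  cm <- site$counts_m[[1]]
  if (length(cm) != 2 || anyNA(cm)) stop("site must be bi-allelic with depths")
  if (sum(cm) == 0) stop("cannot orient a site with zero M-pool depth")
  if (cm[2] >= cm[1]) site$alt else site$ref
}

#' SNP-index and delta SNP-index for one site
#'
#' The SNP-index of a pool is the fraction of its reads carrying the M-pool
#' allele (see [pick_m_allele()]); the delta SNP-index subtracts the W-pool
#' index from the M-pool index. Under the majority orientation the M-pool
#' index is always at least 0.5.
#'
#' @param site single-row site table that passed the filter.
#' @return single-row data frame: `chrom`, `pos`, `m_allele`, `snp_index_w`,
#'   `snp_index_m`, `delta`, `depth_w`, `depth_m`.
#' @export
#' @examples
#' s <- data.frame(chrom = "chr1", pos = 100, ref = "A", alt = "T",
#'                 qual = 60, base_qual = NA, has_depth = TRUE)
#' s$counts_w <- list(c(27L, 13L)); s$counts_m <- list(c(0L, 40L))
#' compute_index(s)  # snp_index_m = 1, snp_index_w = 0.325, delta = 0.675
compute_index <- function(site) {
  site <- as_site_df(site)
  cw <- site$counts_w[[1]]
  cm <- site$counts_m[[1]]
  if (sum(cw) == 0 || sum(cm) == 0) {
    stop("zero depth in a pool; such sites should have been filtered")
  }
  k <- if (cm[2] >= cm[1]) 2L else 1L
  data.frame(
    chrom = site$chrom, pos = site$pos,
    m_allele = if (k == 2L) site$alt else site$ref,
    snp_index_w = cw[k] / sum(cw),
    snp_index_m = cm[k] / sum(cm),
    delta = cm[k] / sum(cm) - cw[k] / sum(cw),
    depth_w = sum(cw), depth_m = sum(cm),
    stringsAsFactors = FALSE
  )
}

#' Filter a site table and compute SNP-indices for the survivors
#'
#' Vectorized pipeline over a whole site table: applies the reliability
#' filter, tallies rejection reasons, orients each passing site on its
#' M-pool majority allele and computes both pools' SNP-index and the delta.
#'
#' @param sites site table from [read_sites()] or [simulate.cross_model()].
#' @param cfg a [filter_config()].
#' @param orient `"majority"` (default; the analysis rule) or `"alt"` (index
#'   the alternate allele as the M-pool allele — used when the mutant allele
#'   is known, e.g. on simulated data where alt is the mutant allele by
#'   construction).
#' @return list with `sites` (indexed table: chrom, pos, m_allele,
#'   snp_index_w, snp_index_m, delta, depth_w, depth_m), `reason` (per input
#'   site) and `tally` (named counts per reason, including `"pass"`; sums to
#'   `nrow(sites)`).
#' @export
index_sites <- function(sites, cfg = filter_config(),
                        orient = c("majority", "alt")) {
  orient <- match.arg(orient)
  stopifnot(is.data.frame(sites), nrow(sites) >= 0)
  reason <- classify_sites(sites, cfg)
  keep <- sites[reason == "", , drop = FALSE]
  tally <- c(pass = sum(reason == ""),
             multiallelic = sum(reason == "multiallelic"),
             quality = sum(reason == "quality"),
             depth = sum(reason == "depth"))
  if (nrow(keep) == 0) {
    out <- data.frame(chrom = character(), pos = numeric(),
                      m_allele = character(), snp_index_w = numeric(),
                      snp_index_m = numeric(), delta = numeric(),
                      depth_w = numeric(), depth_m = numeric(),
                      stringsAsFactors = FALSE)
    return(list(sites = out, reason = reason, tally = tally))
  }
  if (any(lengths(keep$counts_w) != 2L | lengths(keep$counts_m) != 2L)) {
    stop("index computation requires bi-allelic sites; enable ",
         "`require_biallelic` or pre-filter multi-allelic records")
  }
  rw <- vapply(keep$counts_w, `[`, numeric(1), 1L)
  aw <- vapply(keep$counts_w, `[`, numeric(1), 2L)
  rm_ <- vapply(keep$counts_m, `[`, numeric(1), 1L)
  am <- vapply(keep$counts_m, `[`, numeric(1), 2L)
  dw <- rw + aw
  dm <- rm_ + am
  use_alt <- if (orient == "majority") am >= rm_ else rep(TRUE, nrow(keep))
  iw <- ifelse(use_alt, aw, rw) / dw
  im <- ifelse(use_alt, am, rm_) / dm
  out <- data.frame(
    chrom = keep$chrom, pos = keep$pos,
    m_allele = ifelse(use_alt, keep$alt, keep$ref),
    snp_index_w = iw, snp_index_m = im, delta = im - iw,
    depth_w = dw, depth_m = dm,
    stringsAsFactors = FALSE
  )
  list(sites = out, reason = reason, tally = tally)
}
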