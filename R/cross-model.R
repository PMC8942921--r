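#' Parameterize a synthetic F2 pooled-sequencing experiment
#'
#' A `cross_model` captures everything needed to simulate bulked segregant
#' analysis of an F2 population segregating a single recessive locus: the
#' physical map (chromosomes and marker positions), the causal locus, the
#' physical-to-genetic scaling, population and pool sizes, and the pooled
#' read-sampling model (depth and base-error rate). [simulate.cross_model()]
#' turns a model into genotypes, pools, read counts and a VCF-ready site table.
#'
#' Physical distance is converted to genetic distance at a uniform
#' `cm_per_mb`; recombination fractions between adjacent markers follow
#' Haldane's map function (no crossover interference). The trait is recessive:
#' an individual is scored `"dwarf"` iff it carries two mutant alleles at the
#' causal locus, matching a cross whose F1 is uniformly wild type.
#'
#' @param chromosomes named numeric vector of chromosome lengths in bp.
#' @param markers named list (same names as `chromosomes`) of strictly
#'   increasing 1-based marker positions in bp.
#' @param causal list with elements `chrom` and `pos`; must coincide with a
#'   marker on that chromosome.
#' @param cm_per_mb genetic map density, centimorgan per megabase (default 3).
#' @param n_f2 number of F2 individuals to simulate.
#' @param pool_size_w,pool_size_m individuals in the wild-type (W) and mutant
#'   (M) pool. Their sum may not exceed `n_f2`.
#' @param depth_mean expected sequencing depth per site per pool.
#' @param depth_model `"poisson"` (depth drawn per site) or `"fixed"`.
#' @param error_rate per-read probability of reporting the wrong allele;
#'   must lie in `[0, 0.5)`.
#' @param variant_qual,base_qual constant phred-scaled variant and base
#'   qualities written into emitted VCF records.
#' @param seed integer seed governing all randomness downstream of this model.
#' @return an object of class `"cross_model"`.
#' @seealso [study_cross_model()] for the default study design,
#'   [simulate.cross_model()], [emit_dataset()].
#' @export
#' @examples
#' m <- cross_model(
#'   chromosomes = c(chr1 = 1e6),
#'   markers = list(chr1 = c(1, 5e5, 1e6)),
#'   causal = list(chrom = "chr1", pos = 5e5),
#'   n_f2 = 200, seed = 1
#' )
#' m
cross_model <- function(chromosomes, markers, causal,
                        cm_per_mb = 3, n_f2 = 300,
                        pool_size_w = 50, pool_size_m = 50,
                        depth_mean = 40, depth_model = c("poisson", "fixed"),
                        error_rate = 0.01,
                        variant_qual = 60, base_qual = 35,
                        seed = 1L) {
  depth_model <- match.arg(depth_model)
  if (is.null(names(chromosomes)) || any(!nzchar(names(chromosomes)))) {
    stop("`chromosomes` must be a named vector of lengths")
  }
  if (!setequal(names(markers), names(chromosomes))) {
    stop("`markers` must have one entry per chromosome")
  }
  for (ch in names(markers)) {
    p <- markers[[ch]]
    if (length(p) == 0) stop("chromosome ", ch, " has no markers")
    if (any(p < 1) || any(p > chromosomes[[ch]])) {
      stop("marker positions on ", ch, " must lie in [1, ", chromosomes[[ch]], "]")
    }
    if (is.unsorted(p, strictly = TRUE)) {
      stop("marker positions on ", ch, " must be strictly increasing")
    }
  }
  if (!causal$chrom %in% names(markers)) {
    stop("causal chromosome ", causal$chrom, " not in the map")
  }
  if (!causal$pos %in% markers[[causal$chrom]]) {
    stop("causal position must coincide with a marker on ", causal$chrom)
  }
  if (!is_count(n_f2) || n_f2 < 1) stop("`n_f2` must be a positive integer")
  if (!is_count(pool_size_w) || !is_count(pool_size_m) ||
      pool_size_w < 1 || pool_size_m < 1) {
    stop("pool sizes must be positive integers")
  }
  if (pool_size_w + pool_size_m > n_f2) {
    stop("pool_size_w + pool_size_m must not exceed n_f2")
  }
  if (!(error_rate >= 0 && error_rate < 0.5)) {
    stop("`error_rate` must lie in [0, 0.5)")
  }
  if (depth_mean <= 0) stop("`depth_mean` must be positive")
  if (cm_per_mb <= 0) stop("`cm_per_mb` must be positive")

  structure(
    list(
      chromosomes = chromosomes,
      markers = lapply(markers, as.numeric)[names(chromosomes)],
      causal = list(chrom = causal$chrom, pos = as.numeric(causal$pos)),
      cm_per_mb = cm_per_mb, n_f2 = as.integer(n_f2),
      pool_size_w = as.integer(pool_size_w),
      pool_size_m = as.integer(pool_size_m),
      depth_mean = depth_mean, depth_model = depth_model,
      error_rate = error_rate,
      variant_qual = variant_qual, base_qual = base_qual,
      seed = as.integer(seed)
    ),
    class = "cross_model"
  )
}

#' The default study design: two 10-Mb chromosomes, markers every 20 kb
#'
#' Mirrors the mapping experiment the package emulates: an F2 of 300
#' individuals, phenotypic pools of 50 wild-type and 50 dwarf plants, and
#' roughly 40x pooled sequencing. The causal locus sits mid-chromosome-1;
#' chromosome 2 carries no causal variant and serves as the negative control
#' in recovery experiments.
#'
#' @param seed integer seed.
#' @param n_f2 F2 population size (default 300).
#' @param depth_mean expected pool depth (default 40).
#' @param ... further arguments passed to [cross_model()].
#' @return a `"cross_model"`.
#' @export
study_cross_model <- function(seed = 1L, n_f2 = 300, depth_mean = 40, ...) {
  len <- 1e7
  pos <- seq(2e4, len, by = 2e4)
  cross_model(
    chromosomes = c(chr1 = len, chr2 = len),
    markers = list(chr1 = pos, chr2 = pos),
    causal = list(chrom = "chr1", pos = 5e6),
    n_f2 = n_f2, depth_mean = depth_mean, seed = seed, ...
  )
}

#' @export
print.cross_model <- function(x, ...) {
  nm <- sum(lengths(x$markers))
  cat("F2 pooled-sequencing cross model\n")
  cat(sprintf("  genome: %d chromosome(s), %d markers\n",
              length(x$chromosomes), nm))
  cat(sprintf("  causal locus: %s:%s (recessive)\n",
              x$causal$chrom,
              format(x$causal$pos, big.mark = ",", scientific = FALSE)))
  cat(sprintf("  F2 size %d; pools W=%d / M=%d; depth %s(%g); error %.3g\n",
              x$n_f2, x$pool_size_w, x$pool_size_m,
              x$depth_model, x$depth_mean, x$error_rate))
  cat(sprintf("  map density %g cM/Mb (Haldane); seed %d\n",
              x$cm_per_mb, x$seed))
  invisible(x)
}

# marker table in genome order: one row per marker
marker_table <- function(model) {
  data.frame(
    chrom = rep(names(model$markers), lengths(model$markers)),
    pos = unlist(model$markers, use.names = FALSE),
    stringsAsFactors = FALSE
  )
}

causal_index <- function(model) {
  mk <- marker_table(model)
  which(mk$chrom == model$causal$chrom & mk$pos == model$causal$pos)
}
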