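#' Chi-squared goodness-of-fit test for a Mendelian segregation ratio
#'
#' Pearson's statistic `sum((O - E)^2 / E)` against class frequencies
#' proportional to `ratio`, with `k - 1` degrees of freedom and no continuity
#' correction — the standard convention for segregation-ratio tests (the
#' Yates correction is never applied; a 2-class 3:1 table of 218:82 gives
#' 0.871 uncorrected versus 0.751 corrected).
#'
#' @param observed non-negative integer class counts (length >= 2, total > 0).
#' @param ratio positive expected ratio weights, same length; the statistic
#'   is invariant under rescaling of the weights.
#' @param labels optional class labels.
#' @return object of classes `"mendel_test"` and `"htest"`: `statistic`,
#'   `parameter` (df), `p.value`, `observed`, `expected`.
#' @export
#' @examples
#' mendel_test(c(218, 82), c(3, 1))   # X-squared = 0.871, p > 0.05
#' mendel_test(c(74, 142, 84), c(1, 2, 1))
mendel_test <- function(observed, ratio = c(3, 1), labels = names(observed)) {
  if (length(observed) < 2 || length(observed) != length(ratio)) {
    stop("`observed` and `ratio` must have equal length >= 2")
  }
  if (!all(vapply(observed, is_count, logical(1)))) {
    stop("observed counts must be non-negative integers")
  }
  if (sum(observed) == 0) stop("total observed count must be positive")
  if (any(ratio <= 0)) stop("ratio weights must be positive")
  expected <- sum(observed) * ratio / sum(ratio)
  if (any(expected == 0)) stop("expected counts must be positive")
  ht <- stats::chisq.test(as.integer(round(observed)), p = ratio / sum(ratio))
  ht$method <- sprintf(
    "Chi-squared goodness of fit to a %s segregation ratio",
    paste(ratio, collapse = ":"))
  ht$data.name <- deparse(substitute(observed))
  if (!is.null(labels)) {
    names(ht$observed) <- names(ht$expected) <- labels
  }
  class(ht) <- c("mendel_test", "htest")
  ht
}

#' Marker-phenotype co-segregation in a mapping population
#'
#' Checks whether a marker's genotype classes predict the phenotype under a
#' recessive model: predicted phenotype is `"dwarf"` iff the genotype is
#' homozygous mutant. Reports the concordance fraction, the genotype class
#' counts, and any discordant individuals. A concordance of 1 over a
#' reasonably sized population is the classic evidence that the marker is at
#' or tightly linked to the causal variant.
#'
#' @param calls data frame with columns `id`, `genotype` (one of
#'   `"hom_wt"`, `"het"`, `"hom_mut"`) and `phenotype` (`"normal"` or
#'   `"dwarf"`).
#' @param inheritance only `"recessive"` is supported.
#' @return object of class `"coseg"`: `concordance`, `counts` (named by
#'   genotype class), `discordant` (ids), `n`.
#' @export
#' @examples
#' calls <- data.frame(
#'   id = 1:6,
#'   genotype = c("hom_wt", "het", "het", "hom_mut", "hom_mut", "hom_wt"),
#'   phenotype = c("normal", "normal", "normal", "dwarf", "dwarf", "normal")
#' )
#' cosegregation(calls)
cosegregation <- function(calls, inheritance = "recessive") {
  inheritance <- match.arg(inheritance)
  if (!is.data.frame(calls) || nrow(calls) == 0) {
    stop("`calls` must be a non-empty data frame")
  }
  need <- c("id", "genotype", "phenotype")
  if (!all(need %in% names(calls))) {
    stop("`calls` needs columns: ", paste(need, collapse = ", "))
  }
  classes <- c("hom_wt", "het", "hom_mut")
  if (!all(calls$genotype %in% classes)) {
    stop("genotype must be one of: ", paste(classes, collapse = ", "))
  }
  if (!all(calls$phenotype %in% c("normal", "dwarf"))) {
    stop("phenotype must be 'normal' or 'dwarf'")
  }
  predicted <- ifelse(calls$genotype == "hom_mut", "dwarf", "normal")
  match_ok <- predicted == calls$phenotype
  counts <- vapply(classes, function(g) sum(calls$genotype == g), integer(1))
  structure(
    list(concordance = mean(match_ok), counts = counts,
         discordant = calls$id[!match_ok], n = nrow(calls)),
    class = "coseg"
  )
}

#' @export
print.coseg <- function(x, ...) {
  cat("Marker-phenotype co-segregation (recessive model)\n")
  cat(sprintf("  classes: hom_wt=%d, het=%d, hom_mut=%d (n=%d)\n",
              x$counts[["hom_wt"]], x$counts[["het"]],
              x$counts[["hom_mut"]], x$n))
  cat(sprintf("  concordance: %.4g", x$concordance))
  if (length(x$discordant) > 0) {
    cat(sprintf("  (%d discordant: %s)", length(x$discordant),
                paste(utils::head(x$discordant, 10), collapse = ", ")))
  }
  cat("\n")
  invisible(x)
}
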