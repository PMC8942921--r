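#' Read pooled-sequencing variant sites from a VCF
#'
#' Normalizes a two-pool VCF into the site table the rest of the pipeline
#' consumes: one row per record with the per-pool allele-depth vectors
#' (`AD`, reference count first, then alternates in order). Records lacking
#' allele depths are kept with `has_depth = FALSE` and counted, rather than
#' silently dropped, so filter statistics stay auditable. Multi-allelic
#' records are preserved; filtering decides their fate downstream.
#'
#' A per-site mean base quality is read from the INFO field named by
#' `base_qual_info` when present (`NA` otherwise); the annotation is taken as
#' given, one value per site.
#'
#' @param path VCF (v4.x) file path.
#' @param w_sample,m_sample sample names of the wild-type and mutant pool.
#' @param base_qual_info INFO key carrying a phred-scaled base quality.
#' @return data frame with columns `chrom`, `pos`, `ref`, `alt`
#'   (comma-separated when multi-allelic), `qual`, `base_qual`, `has_depth`
#'   and list-columns `counts_w`, `counts_m` (integer vectors of length
#'   `1 + n_alt`, or `NA` when depths are missing).
#' @export
read_sites <- function(path, w_sample = "W", m_sample = "M",
                       base_qual_info = "BQ") {
  if (!file.exists(path)) stop("VCF not found: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  samples <- colnames(vcf@gt)[-1]
  for (s in c(w_sample, m_sample)) {
    if (!s %in% samples) {
      stop(sprintf("sample %s not in VCF; available samples: %s",
                   s, paste(samples, collapse = ", ")))
    }
  }
  fix <- vcf@fix
  ad <- vcfR::extract.gt(vcf, element = "AD")
  parse_ad <- function(x) {
    lapply(x, function(v) {
      if (is.na(v) || v == "." || v == "") return(NA_integer_)
      suppressWarnings(as.integer(strsplit(v, ",", fixed = TRUE)[[1]]))
    })
  }
  cw <- parse_ad(ad[, w_sample])
  cm <- parse_ad(ad[, m_sample])
  bq <- rep(NA_real_, nrow(fix))
  if (!is.null(base_qual_info) &&
      any(grepl(paste0("(^|;)", base_qual_info, "="), fix[, "INFO"]))) {
    bq <- suppressWarnings(
      as.numeric(vcfR::extract.info(vcf, element = base_qual_info))
    )
  }
  n_alt <- lengths(strsplit(fix[, "ALT"], ",", fixed = TRUE))
  has_depth <- !(vapply(cw, function(v) anyNA(v), logical(1)) |
                   vapply(cm, function(v) anyNA(v), logical(1)))
  bad_len <- has_depth & (lengths(cw) != 1L + n_alt | lengths(cm) != 1L + n_alt)
  if (any(bad_len)) {
    stop(sprintf("malformed AD at record %d: expected %d counts",
                 which(bad_len)[1], 1L + n_alt[which(bad_len)[1]]))
  }
  sites <- data.frame(
    chrom = fix[, "CHROM"],
    pos = as.numeric(fix[, "POS"]),
    ref = fix[, "REF"], alt = fix[, "ALT"],
    qual = suppressWarnings(as.numeric(fix[, "QUAL"])),
    base_qual = bq, has_depth = has_depth,
    stringsAsFactors = FALSE
  )
  sites$counts_w <- unname(cw)
  sites$counts_m <- unname(cm)
  message(sprintf("read %d sites from %s (%d lacking allele depths)",
                  nrow(sites), basename(path), sum(!has_depth)))
  sites
}

#' Write a site table as a VCF v4.2 file
#'
#' The inverse of [read_sites()]: two samples (`W`, `M`), format `GT:AD` with
#' genotypes `"./."`, and the per-site base quality in INFO as `BQ`. Output
#' is deterministic for a given site table.
#'
#' @param sites site table as produced by [read_sites()] or
#'   [simulate.cross_model()].
#' @param path output path.
#' @param chrom_lengths optional named vector for `##contig` header lines.
#' @param source_line optional text for a `##source=` header line.
#' @return invisibly, `path`.
#' @export
write_sites <- function(sites, path, chrom_lengths = NULL, source_line = NULL) {
  fmt_ad <- function(v) {
    if (length(v) == 1 && is.na(v)) "." else paste(v, collapse = ",")
  }
  hdr <- c(
    "##fileformat=VCFv4.2",
    if (!is.null(source_line)) paste0("##source=", source_line),
    if (!is.null(chrom_lengths)) {
      sprintf("##contig=<ID=%s,length=%d>",
              names(chrom_lengths), as.integer(chrom_lengths))
    },
    "##INFO=<ID=BQ,Number=1,Type=Float,Description=\"Mean phred-scaled base quality\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths (ref,alt)\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tW\tM"
  )
  fmt_num <- function(x) {
    sub("\\.?0+$", "", formatC(x, digits = 10, format = "f"))
  }
  info <- ifelse(is.na(sites$base_qual), ".",
                 sprintf("BQ=%s", fmt_num(sites$base_qual)))
  rows <- sprintf(
    "%s\t%s\t.\t%s\t%s\t%s\t.\t%s\tGT:AD\t./.:%s\t./.:%s",
    sites$chrom, format(sites$pos, scientific = FALSE, trim = TRUE),
    sites$ref, sites$alt,
    ifelse(is.na(sites$qual), ".", fmt_num(sites$qual)),
    info,
    vapply(sites$counts_w, fmt_ad, character(1)),
    vapply(sites$counts_m, fmt_ad, character(1))
  )
  writeLines(c(hdr, rows), path)
  invisible(path)
}

window_cols <- c("chrom", "start", "end", "n_sites", "mean_index_w",
                 "mean_index_m", "mean_delta", "ci95_lo", "ci95_hi",
                 "ci99_lo", "ci99_hi")

#' Write sliding-window statistics to a tab-separated file
#'
#' Fixed column set `chrom, start, end, n_sites, mean_index_w, mean_index_m,
#' mean_delta, ci95_lo, ci95_hi, ci99_lo, ci99_hi`; windows without sites get
#' the `NA` sentinel in the mean columns. Optional `header` lines are written
#' first, prefixed with `#` (used to record seeds and parameters).
#'
#' @param windows window table (see [aggregate_windows()]); missing
#'   confidence-band columns are filled with `NA`.
#' @param path output path.
#' @param header optional character vector of comment lines (without `#`).
#' @return invisibly, `path`.
#' @export
write_windows <- function(windows, path, header = NULL) {
  for (cc in window_cols) if (is.null(windows[[cc]])) windows[[cc]] <- NA_real_
  out <- windows[window_cols]
  num <- setdiff(window_cols, c("chrom", "start", "end", "n_sites"))
  for (cc in num) {
    out[[cc]] <- ifelse(is.na(out[[cc]]), "NA",
                        formatC(out[[cc]], digits = 6, format = "f"))
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a window table written by [write_windows()]
#' @param path file path.
#' @return data frame with the fixed window columns.
#' @export
read_windows <- function(path) {
  utils::read.delim(path, comment.char = "#", na.strings = "NA",
                    stringsAsFactors = FALSE)
}
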