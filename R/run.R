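#' Read a run configuration
#'
#' Configurations are YAML mappings (or equivalent R lists) holding the
#' parameters of one subcommand plus `out_dir` and `seed`. Parse failures and
#' missing files raise a condition of class `"bsamap_config_error"` so the
#' command-line front-end can map them to exit status 2.
#'
#' @param config path to a YAML file, or a list (returned as-is).
#' @return a named list.
#' @export
read_run_config <- function(config) {
  if (is.list(config)) return(config)
  if (!is.character(config) || length(config) != 1) {
    stop(config_error("config must be a YAML path or a list"))
  }
  if (!file.exists(config)) {
    stop(config_error(paste0("config file not found: ", config)))
  }
  out <- tryCatch(
    yaml::read_yaml(config),
    error = function(e) {
      stop(config_error(paste0("cannot parse ", config, ": ",
                               conditionMessage(e))))
    }
  )
  if (!is.list(out)) stop(config_error("config must be a YAML mapping"))
  out
}

config_error <- function(msg) {
  structure(class = c("bsamap_config_error", "error", "condition"),
            list(message = msg, call = NULL))
}

cfg_model <- function(cfg) {
  seed <- as.integer(cfg$seed %||% 1L)
  study_cross_model(
    seed = seed,
    n_f2 = cfg$n_f2 %||% 300,
    depth_mean = cfg$depth_mean %||% 40,
    pool_size_w = cfg$pool_size_w %||% 50,
    pool_size_m = cfg$pool_size_m %||% 50,
    error_rate = cfg$error_rate %||% 0.01,
    depth_model = cfg$depth_model %||% "poisson",
    cm_per_mb = cfg$cm_per_mb %||% 3
  )
}

write_manifest <- function(path, subcommand, params) {
  params$package_version <- as.character(utils::packageVersion("bsamap"))
  yaml::write_yaml(c(list(subcommand = subcommand), params), path)
  invisible(path)
}

#' Simulate a pooled-sequencing dataset to disk
#'
#' Wraps [simulate.cross_model()] and [emit_dataset()]: writes `sim.vcf`,
#' `truth.tsv` and a `manifest.yaml` recording the full parameterization and
#' seed into `out_dir`. Uses the default study design ([study_cross_model()])
#' with any fields of the config overriding it.
#'
#' @param config YAML path or list; recognized fields: `out_dir`, `seed`,
#'   `n_f2`, `depth_mean`, `pool_size_w`, `pool_size_m`, `error_rate`,
#'   `depth_model`, `cm_per_mb`.
#' @param out_dir overrides the config's output directory.
#' @return invisibly, a list of output paths.
#' @export
run_simulate <- function(config = list(), out_dir = NULL) {
  cfg <- read_run_config(config)
  out_dir <- out_dir %||% cfg$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  model <- cfg_model(cfg)
  vcf <- file.path(out_dir, "sim.vcf")
  truth <- file.path(out_dir, "truth.tsv")
  emit_dataset(model, vcf, truth)
  manifest <- file.path(out_dir, "manifest.yaml")
  write_manifest(manifest, "simulate",
                 model[setdiff(names(model), c("chromosomes", "markers"))])
  message("wrote ", vcf, ", ", truth, ", ", manifest)
  invisible(list(vcf = vcf, truth = truth, manifest = manifest))
}

#' Run the genome scan on a VCF and write window/region tables
#'
#' Full pipeline: read sites, filter, index, window, null band, candidate
#' regions. Writes `windows.tsv` and `regions.tsv` (both headed by comment
#' lines recording seed and parameters), optionally a `scan.png` plot, and
#' logs the filter tally.
#'
#' @param config YAML path or list; fields: `vcf`, `out_dir`, `seed`,
#'   `w_sample`, `m_sample`, `window_size`, `step`, `level`, `n_reps`,
#'   `pool_size_w`, `pool_size_m`, `min_consecutive`, `plot` (logical).
#' @param out_dir overrides the config's output directory.
#' @return invisibly, the fitted `"bsa_scan"` object.
#' @export
run_scan <- function(config = list(), out_dir = NULL) {
  cfg <- read_run_config(config)
  if (is.null(cfg$vcf)) stop(config_error("scan config needs a `vcf` field"))
  out_dir <- out_dir %||% cfg$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(cfg$seed %||% 1L)
  fit <- bsa_scan(
    cfg$vcf,
    w_sample = cfg$w_sample %||% "W", m_sample = cfg$m_sample %||% "M",
    window_size = cfg$window_size %||% 2.5e6, step = cfg$step %||% 2e4,
    level = cfg$level %||% 0.95, n_reps = cfg$n_reps %||% 2000,
    pool_size_w = cfg$pool_size_w %||% 50,
    pool_size_m = cfg$pool_size_m %||% 50,
    min_consecutive = cfg$min_consecutive %||% 3,
    seed = seed
  )
  hdr <- c(
    sprintf("bsamap scan seed=%d level=%g window=%g step=%g reps=%d",
            seed, fit$params$level, fit$params$window_size,
            fit$params$step, fit$params$n_reps),
    sprintf("filter tally: %s",
            paste(sprintf("%s=%d", names(fit$tally), fit$tally),
                  collapse = " "))
  )
  write_windows(fit$windows, file.path(out_dir, "windows.tsv"), header = hdr)
  con <- file(file.path(out_dir, "regions.tsv"), "w")
  writeLines(paste0("# ", hdr), con)
  utils::write.table(fit$regions, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  close(con)
  if (isTRUE(cfg$plot)) {
    grDevices::png(file.path(out_dir, "scan.png"), width = 900,
                   height = 300 * length(unique(fit$windows$chrom)))
    plot(fit)
    grDevices::dev.off()
  }
  message(sprintf("scan: %d/%d sites passed; %d region(s) called",
                  fit$tally[["pass"]], sum(fit$tally), nrow(fit$regions)))
  invisible(fit)
}

#' Segregation-ratio and co-segregation report
#'
#' Runs [mendel_test()] on observed class counts and, when a genotype table
#' is supplied, [cosegregation()] on it.
#'
#' @param config YAML path or list; fields: `counts` (numeric vector or
#'   comma-separated string), `ratio` (likewise, default `3,1`), `genotypes`
#'   (optional TSV path with columns id, genotype, phenotype).
#' @return invisibly, list with `test` (a `"mendel_test"`) and `coseg`
#'   (a `"coseg"` or `NULL`).
#' @export
run_segregation <- function(config = list()) {
  cfg <- read_run_config(config)
  parse_nums <- function(x, what) {
    if (is.character(x)) {
      x <- suppressWarnings(as.numeric(strsplit(x, ",", fixed = TRUE)[[1]]))
    }
    if (length(x) < 2 || anyNA(x)) {
      stop(config_error(paste0("malformed ", what,
                               ": need >= 2 comma-separated numbers")))
    }
    x
  }
  if (is.null(cfg$counts)) {
    stop(config_error("segregation config needs a `counts` field"))
  }
  counts <- parse_nums(cfg$counts, "counts")
  ratio <- parse_nums(cfg$ratio %||% c(3, 1), "ratio")
  ht <- mendel_test(counts, ratio)
  print(ht)
  cs <- NULL
  if (!is.null(cfg$genotypes)) {
    calls <- utils::read.delim(cfg$genotypes, stringsAsFactors = FALSE)
    cs <- cosegregation(calls)
    print(cs)
  }
  invisible(list(test = ht, coseg = cs))
}
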