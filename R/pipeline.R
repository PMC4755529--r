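# End-to-end orchestration: generate or read a cohort, simulate, report.
# Every run writes a manifest sufficient to re-execute it exactly.

#' Build and validate a run configuration
#'
#' A run either reads a cohort from disk (`burden_file`, plus
#' `covariates_file`) or generates one (`generator` = list of
#' [synthetic_cohort_params()] arguments). Exactly one source must be given.
#'
#' @param burden_file,covariates_file Input CSV paths (see [read_cohort()]),
#'   or `NULL` to generate.
#' @param generator Named list of [synthetic_cohort_params()] arguments, or
#'   `NULL` to read from files.
#' @param windows Integer window lengths (default `c(14, 28, 56, 112, 365)`).
#' @param n_reps Monte Carlo repetitions (default 5000).
#' @param seed Master seed; required.
#' @param blanking_days Blanking period (default 30).
#' @param start_day First monitoring day (default 31).
#' @param af_threshold_minutes AF-day threshold (default 5).
#' @param sub_threshold_policy `"zero"` or `"raw"`.
#' @param ci_method `"clopper_pearson"` or `"wilson"`.
#' @param strata One of `"none"`, `"chads2"`, `"median_burden"`, or
#'   `"fixed_burden:<hours>"` (e.g. `"fixed_burden:5.5"`).
#' @param output_dir Directory for artifacts (created if absent).
#' @return A validated `run_config` list.
#' @export
run_config <- function(burden_file = NULL, covariates_file = NULL,
                       generator = NULL,
                       windows = c(14L, 28L, 56L, 112L, 365L),
                       n_reps = 5000L, seed = NULL, blanking_days = 30L,
                       start_day = 31L, af_threshold_minutes = 5,
                       sub_threshold_policy = "zero",
                       ci_method = "clopper_pearson", strata = "none",
                       output_dir = "afsnapshot-out") {
  cfg <- list(burden_file = burden_file, covariates_file = covariates_file,
              generator = generator, windows = as.integer(windows),
              n_reps = as.integer(n_reps),
              seed = if (is.null(seed)) NULL else as.integer(seed),
              blanking_days = as.integer(blanking_days),
              start_day = as.integer(start_day),
              af_threshold_minutes = af_threshold_minutes,
              sub_threshold_policy = sub_threshold_policy,
              ci_method = ci_method, strata = strata,
              output_dir = output_dir)
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  fail <- function(key, why) {
    stop("invalid config key `", key, "`: ", why, call. = FALSE)
  }
  has_files <- !is.null(cfg$burden_file)
  has_gen <- !is.null(cfg$generator)
  if (has_files == has_gen) {
    fail("burden_file/generator",
         "exactly one of input files or generator params must be given")
  }
  if (has_files) {
    if (!file.exists(cfg$burden_file)) {
      fail("burden_file", paste("file not found:", cfg$burden_file))
    }
    if (!is.null(cfg$covariates_file) &&
        !file.exists(cfg$covariates_file)) {
      fail("covariates_file",
           paste("file not found:", cfg$covariates_file))
    }
  }
  if (!length(cfg$windows) || anyNA(cfg$windows) || any(cfg$windows < 1L)) {
    fail("windows", "must be positive integers")
  }
  if (is.na(cfg$n_reps) || cfg$n_reps < 1L) fail("n_reps", "must be >= 1")
  if (is.null(cfg$seed) || is.na(cfg$seed)) {
    fail("seed", "an integer seed is required (no silent nondeterminism)")
  }
  if (is.na(cfg$blanking_days) || cfg$blanking_days < 0L) {
    fail("blanking_days", "must be >= 0")
  }
  if (!cfg$sub_threshold_policy %in% c("zero", "raw")) {
    fail("sub_threshold_policy", "must be \"zero\" or \"raw\"")
  }
  if (!cfg$ci_method %in% c("clopper_pearson", "wilson")) {
    fail("ci_method", "must be \"clopper_pearson\" or \"wilson\"")
  }
  if (!(cfg$strata %in% c("none", "chads2", "median_burden") ||
        grepl("^fixed_burden:[0-9.]+$", cfg$strata))) {
    fail("strata",
         "must be none, chads2, median_burden, or fixed_burden:<hours>")
  }
  structure(cfg, class = "run_config")
}

#' Read a run configuration from JSON or YAML
#'
#' The format is chosen by extension: `.json` via jsonlite, `.yml`/`.yaml`
#' via the yaml package (if installed).
#'
#' @param path Configuration file path.
#' @param ... Overrides applied on top of the file's values (flags beat
#'   config).
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path, ...) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (ext %in% c("yml", "yaml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the yaml package is needed for YAML configs", call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    stop("unsupported config extension: ", ext, call. = FALSE)
  }
  overrides <- list(...)
  raw[names(overrides)] <- overrides
  do.call(run_config, raw)
}

resolve_strata <- function(cohort, cfg) {
  if (cfg$strata == "none") return(NULL)
  if (cfg$strata == "chads2") return(stratify_chads2())
  if (cfg$strata == "median_burden") {
    return(median_burden_split(cohort, cfg$blanking_days)$strata)
  }
  cutoff <- as.numeric(sub("^fixed_burden:", "", cfg$strata))
  stratify_burden(cutoff, cfg$blanking_days)
}

#' Run the full pipeline
#'
#' Generates (or reads) the cohort, runs the snapshot detection simulation
#' for every configured window and stratum, and writes artifacts under
#' `output_dir`: the cohort CSVs (when generated), `calibration.json`, the
#' detection table as `detection_table.csv` and unrounded
#' `detection_table.json`, and `manifest.json` capturing config, seed and
#' package version. Identical config + seed produces byte-identical JSON
#' outputs.
#'
#' @param config A `run_config` (see [run_config()] / [read_run_config()]).
#' @return Invisibly, a list with the detection table, calibration report
#'   (if generated), and artifact paths.
#' @export
run_pipeline <- function(config) {
  config <- validate_run_config(config)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(manifest = file.path(config$output_dir, "manifest.json"))

  if (!is.null(config$generator)) {
    gen_args <- config$generator
    if (is.null(gen_args$seed)) gen_args$seed <- config$seed
    params <- do.call(synthetic_cohort_params, gen_args)
    message("generating synthetic cohort: n = ", params$n_patients,
            ", seed = ", params$seed)
    cohort <- generate_cohort(params)
    paths$burden <- file.path(config$output_dir, "cohort_burden.csv")
    paths$covariates <- file.path(config$output_dir,
                                  "cohort_covariates.csv")
    write_cohort(cohort, paths$burden, paths$covariates)
    calib <- calibration_report(cohort, config$blanking_days,
                                config$af_threshold_minutes)
    paths$calibration <- file.path(config$output_dir, "calibration.json")
    jsonlite::write_json(unclass(calib), paths$calibration,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    message("reading cohort from ", config$burden_file)
    cohort <- read_cohort(config$burden_file, config$covariates_file)
    calib <- NULL
  }

  strata <- resolve_strata(cohort, config)
  message("simulating: windows = ", paste(config$windows, collapse = ","),
          ", reps = ", config$n_reps, ", seed = ", config$seed,
          ", policy = ", config$sub_threshold_policy)
  tab <- detection_table(
    cohort, windows = config$windows, strata = strata,
    n_reps = config$n_reps, seed = config$seed,
    ci_method = config$ci_method,
    af_threshold_minutes = config$af_threshold_minutes,
    sub_threshold_policy = config$sub_threshold_policy,
    blanking_days = config$blanking_days, start_day = config$start_day)

  paths$table_csv <- file.path(config$output_dir, "detection_table.csv")
  paths$table_json <- file.path(config$output_dir, "detection_table.json")
  utils::write.csv(as.data.frame(tab), paths$table_csv, row.names = FALSE)
  jsonlite::write_json(as.data.frame(tab), paths$table_json,
                       digits = NA, pretty = TRUE)

  manifest <- list(package = "afsnapshot",
                   version = as.character(utils::packageVersion("afsnapshot")),
                   config = unclass(config))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  message("artifacts written to ", config$output_dir)
  invisible(list(detection_table = tab, calibration = calib,
                 paths = paths))
}

#' Re-run a pipeline from its manifest
#'
#' @param manifest_path Path to a `manifest.json` written by
#'   [run_pipeline()].
#' @param output_dir Optional new output directory (defaults to the one in
#'   the manifest).
#' @return As [run_pipeline()].
#' @export
run_from_manifest <- function(manifest_path, output_dir = NULL) {
  m <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  cfg <- m$config
  if (!is.null(output_dir)) cfg$output_dir <- output_dir
  if (!is.null(cfg$generator)) cfg$generator <- as.list(cfg$generator)
  run_pipeline(do.call(run_config, cfg))
}
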