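#' Read and validate a run configuration
#'
#' Run configurations are YAML. The schema (all levels in dB, depths in m,
#' ranges in m) is:
#'
#' ```yaml
#' site: {name: ..., season: ...}
#' inputs: {ambient_csv: ambient.csv, pl_csv: pl_samples.csv}
#' band_scheme: {f_low_hz: 1000, f_high_hz: 14800, width_hz: 300}
#' source_level: {mean_db: 155.1, sd_db: 6.5, slope_db_per_band: -0.66, label: SRKW}
#' depth_model: {mu: 2.0212, sigma: 0.7739, z_max_m: 200}
#' detection:
#'   dt_db: 5
#'   n_sl: 100
#'   n_depth: 100
#'   grid: {min_m: 10, max_m: 100000, n: 200}
#'   percentiles: [25, 50, 75]
#'   probability_marks: [0.1, 0.5, 0.9]
#' seed: 1
#' output_dir: out
#' ```
#'
#' Validation runs before any computation and reports *all* offending keys
#' in one error. Relative input paths are resolved against the config
#' file's directory.
#'
#' @param path Path to a YAML config.
#' @return A validated named list of class `run_config` with an attached
#'   `dir` attribute.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  cfg <- yaml::read_yaml(path)
  problems <- character()
  need_num <- function(x, key, positive = FALSE) {
    v <- tryCatch(x[[key]], error = function(e) NULL)
    if (is.null(v) || !is.numeric(v))
      problems <<- c(problems, key)
    else if (positive && any(v <= 0))
      problems <<- c(problems, paste0(key, " (must be positive)"))
  }
  for (key in c("inputs", "source_level", "depth_model", "detection"))
    if (is.null(cfg[[key]]))
      problems <- c(problems, key)
  if (!is.null(cfg$source_level)) {
    need_num(cfg$source_level, "mean_db")
    need_num(cfg$source_level, "sd_db")
    need_num(cfg$source_level, "slope_db_per_band")
  }
  if (!is.null(cfg$depth_model)) {
    need_num(cfg$depth_model, "mu")
    need_num(cfg$depth_model, "sigma", positive = TRUE)
    need_num(cfg$depth_model, "z_max_m", positive = TRUE)
  }
  if (!is.null(cfg$detection)) {
    need_num(cfg$detection, "dt_db")
    need_num(cfg$detection, "n_sl", positive = TRUE)
    need_num(cfg$detection, "n_depth", positive = TRUE)
  }
  if (is.null(cfg$seed) || !is.numeric(cfg$seed))
    problems <- c(problems, "seed")
  if (length(problems))
    stop("invalid config ", path, "; offending keys: ",
         paste(unique(problems), collapse = ", "))
  attr(cfg, "dir") <- dirname(normalizePath(path))
  class(cfg) <- "run_config"
  cfg
}

config_detection <- function(cfg, seed = NULL) {
  det <- cfg$detection
  grid <- det$grid
  rg <- if (is.null(grid)) 10^seq(1, 5, length.out = 200) else
    10^seq(log10(grid$min_m), log10(grid$max_m), length.out = grid$n)
  detection_config(
    dt = det$dt_db %||% 5, n_sl = det$n_sl %||% 100,
    n_depth = det$n_depth %||% 100, range_grid = rg,
    percentiles = unlist(det$percentiles) %||% c(25, 50, 75),
    probability_marks = unlist(det$probability_marks) %||% c(0.1, 0.5, 0.9),
    seed = if (is.null(seed)) cfg$seed else seed)
}

config_scheme <- function(cfg) {
  bs <- cfg$band_scheme
  if (is.null(bs)) make_band_scheme(1000, 14800, 300)
  else make_band_scheme(bs$f_low_hz, bs$f_high_hz, bs$width_hz)
}

config_sl_spec <- function(cfg) {
  sl <- cfg$source_level
  source_level_spec(sl$mean_db, sl$sd_db, sl$slope_db_per_band,
                    label = sl$label %||% "")
}

config_depth <- function(cfg) {
  dm <- cfg$depth_model
  depth_model(dm$mu, dm$sigma, dm$z_max_m %||% 200)
}

config_path <- function(cfg, p) {
  if (is.null(p)) return(NULL)
  if (file.exists(p)) p else file.path(attr(cfg, "dir"), p)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a JSON run manifest
#'
#' Every CLI run stamps its outputs with a manifest: the echoed config, the
#' effective seed, MD5 digests of the input files, the package version and
#' run-specific facts (e.g. the realization count). Timestamps are
#' deliberately excluded so identical runs produce identical manifests.
#'
#' @param path Output path for the JSON.
#' @param config The config list to echo.
#' @param seed Effective seed.
#' @param inputs Character vector of input file paths to digest.
#' @param extra Named list of run-specific entries.
#' @return Invisibly, `path`.
#' @export
write_manifest <- function(path, config, seed, inputs = character(),
                           extra = list()) {
  digests <- if (length(inputs))
    as.list(tools::md5sum(inputs)) else list()
  manifest <- c(list(
    package = "callrange",
    version = as.character(utils::packageVersion("callrange")),
    seed = seed,
    config = unclass(config),
    input_digests = digests), extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
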