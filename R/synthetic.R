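#' Synthetic ambient-noise series
#'
#' Generates a minutes-by-bands SPL matrix with the statistical features of
#' a coastal soundscape record: a base spectrum declining with frequency
#' (ambient levels highest in the lowest band), a shared AR(1) temporal
#' term, independent per-band jitter, and transient broadband "vessel
#' passage" bumps arriving at a Poisson rate with a 1-minute rise and an
#' exponential ~5-minute decay. The event/AR structure is fixture design
#' (real soundscapes are not claimed to follow it); it exists so that
#' temporal stratification is meaningful in tests.
#'
#' With `temporal_sd = 0` and `event_rate = 0` every minute equals the base
#' spectrum exactly.
#'
#' @param scheme A [make_band_scheme()].
#' @param n_minutes Number of minutes, at least 1.
#' @param base_level_at_f_low SPL of the first band's base spectrum (dB).
#' @param spectral_decay Decline of the base spectrum (dB per band,
#'   positive = decreasing with frequency).
#' @param temporal_sd Stationary SD of the shared AR(1) term (dB).
#' @param ar1_coeff AR(1) coefficient in `[0, 1)`.
#' @param event_rate Vessel-passage rate (events per hour).
#' @param event_gain Peak broadband gain of an event (dB).
#' @param band_jitter_sd SD of independent per-band jitter (dB); defaults
#'   to `temporal_sd / 2` so the noise-free limit stays noise-free.
#' @param seed Optional integer seed.
#' @param site_label,season_label Metadata.
#' @return An [ambient_series()].
#' @export
gen_ambient_series <- function(scheme, n_minutes, base_level_at_f_low = 90,
                               spectral_decay = 0.3, temporal_sd = 3,
                               ar1_coeff = 0.7, event_rate = 1,
                               event_gain = 10,
                               band_jitter_sd = temporal_sd / 2,
                               seed = NULL,
                               site_label = "synthetic",
                               season_label = "") {
  stopifnot(inherits(scheme, "band_scheme"))
  if (n_minutes < 1) stop("n_minutes must be at least 1")
  if (ar1_coeff < 0 || ar1_coeff >= 1)
    stop("ar1_coeff must lie in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  nb <- scheme$n_bands
  base <- base_level_at_f_low - spectral_decay * (seq_len(nb) - 1)

  # shared AR(1) with stationary SD temporal_sd
  temporal <- numeric(n_minutes)
  if (temporal_sd > 0) {
    innov_sd <- temporal_sd * sqrt(1 - ar1_coeff^2)
    temporal[1] <- stats::rnorm(1, 0, temporal_sd)
    if (n_minutes > 1) {
      eps <- stats::rnorm(n_minutes - 1, 0, innov_sd)
      for (t in 2:n_minutes)
        temporal[t] <- ar1_coeff * temporal[t - 1] + eps[t - 1]
    }
  }

  # broadband transient events: 1-min rise, exponential decay (tau 5 min)
  events <- numeric(n_minutes)
  if (event_rate > 0) {
    n_ev <- stats::rpois(1, event_rate * n_minutes / 60)
    if (n_ev > 0) {
      starts <- sort(stats::runif(n_ev, 1, n_minutes))
      for (s0 in starts) {
        t <- seq_len(n_minutes)
        shape <- ifelse(t < s0, pmax(0, 1 - (s0 - t)),   # 1-min rise
                        exp(-(t - s0) / 5))              # ~5-min decay
        events <- pmax(events, event_gain * shape)
      }
    }
  }

  jitter <- if (band_jitter_sd > 0)
    matrix(stats::rnorm(n_minutes * nb, 0, band_jitter_sd), n_minutes, nb)
  else matrix(0, n_minutes, nb)

  spl <- matrix(base, n_minutes, nb, byrow = TRUE) +
    (temporal + events) + jitter
  ambient_series(spl, scheme, site_label = site_label,
                 season_label = season_label)
}

#' Synthetic propagation-loss samples
#'
#' Draws samples following `pl = A(band, depth) - n(band, depth) *
#' log10(range)` plus Gaussian residuals. Each tabulated value is the mean
#' of three independently jittered sub-band evaluations, mimicking a
#' propagation model run at three frequencies per band and averaged.
#'
#' @param scheme A [make_band_scheme()].
#' @param depth_grid Source depths (m) at which to sample.
#' @param A_of Function `(band_index, depth) -> A` (dB at 1 m).
#' @param n_of Function `(band_index, depth) -> n` (dB per decade).
#' @param ranges Ranges (m), all positive.
#' @param residual_sd Residual SD per sub-band evaluation (dB).
#' @param seed Optional integer seed.
#' @return A [pl_samples()] table with the generating rules attached as a
#'   `truth` attribute.
#' @export
gen_pl_samples <- function(scheme, depth_grid, A_of, n_of, ranges,
                           residual_sd = 0, seed = NULL) {
  stopifnot(inherits(scheme, "band_scheme"),
            is.function(A_of), is.function(n_of))
  if (any(ranges <= 0)) stop("ranges must be positive")
  if (!is.null(seed)) set.seed(seed)
  grid <- expand.grid(band_index = seq_len(scheme$n_bands),
                      source_depth_m = depth_grid, range_m = ranges,
                      KEEP.OUT.ATTRS = FALSE)
  A <- mapply(A_of, grid$band_index, grid$source_depth_m)
  n <- mapply(n_of, grid$band_index, grid$source_depth_m)
  clean <- A - n * log10(grid$range_m)
  noise3 <- matrix(stats::rnorm(3L * nrow(grid), 0, residual_sd), ncol = 3L)
  grid$pl_db <- clean + rowMeans(noise3)
  out <- pl_samples(grid[c("range_m", "source_depth_m", "band_index", "pl_db")],
                    scheme)
  attr(out, "truth") <- list(A_of = A_of, n_of = n_of,
                             residual_sd = residual_sd)
  out
}

#' Synthetic call band spectrum
#'
#' An affine band spectrum with the given slope plus optional jitter,
#' for exercising [fit_spectral_slope()].
#'
#' @param scheme A [make_band_scheme()].
#' @param slope Slope (dB per band).
#' @param top_level Level of the first band (dB).
#' @param noise_sd Jitter SD (dB).
#' @param seed Optional integer seed.
#' @return Numeric vector of `scheme$n_bands` levels (dB).
#' @export
gen_call_band_spectrum <- function(scheme, slope, top_level = 140,
                                   noise_sd = 0, seed = NULL) {
  stopifnot(inherits(scheme, "band_scheme"))
  if (!is.null(seed)) set.seed(seed)
  top_level + slope * (seq_len(scheme$n_bands) - 1) +
    stats::rnorm(scheme$n_bands, 0, noise_sd)
}

#' Complete synthetic site scenario
#'
#' Bundles every input the pipeline consumes into one self-consistent,
#' seed-reproducible scenario. Three presets are shipped:
#'
#' * `"toy3band"` -- 3 bands (1000--1900 Hz), 60 minutes: small enough for
#'   exhaustive brute-force oracles and quick end-to-end runs.
#' * `"quiet_inshore"` -- full 46-band scheme, modest noise (base 82 dB at
#'   1000 Hz), sparse vessel traffic.
#' * `"noisy_strait"` -- full scheme, elevated noise (base 92 dB) with
#'   frequent vessel passages and slightly stronger spreading loss.
#'
#' Both full-scale presets use the standard call constants (broadband
#' 155.1 +/- 6.5 dB with slope -0.66 dB/band; depth model mu = 2.0212,
#' sigma = 0.7739, truncated at 200 m). `season = "winter"` raises
#' low-frequency noise by 5 dB (tapering with frequency) and weakens the
#' shallow-depth spreading loss, qualitatively emulating a winter surface
#' duct; the values are fixture design, not measurements.
#'
#' @param preset One of `"quiet_inshore"`, `"noisy_strait"`, `"toy3band"`.
#' @param seed Integer seed; the whole scenario regenerates bit-identically
#'   from `(preset, seed, season)`.
#' @param season `"summer"` (default) or `"winter"`.
#' @param n_minutes Override the preset's number of noise minutes.
#' @return An object of class `site_scenario`: list with `scheme`,
#'   `noise`, `pl_samples`, `pl_fit`, `sl_spec`, `depth_params`, `truth`
#'   and `seed`.
#' @export
gen_site_scenario <- function(preset = c("quiet_inshore", "noisy_strait",
                                         "toy3band"),
                              seed = 1L, season = c("summer", "winter"),
                              n_minutes = NULL) {
  preset <- match.arg(preset)
  season <- match.arg(season)
  seed <- as.integer(seed)
  winter <- season == "winter"

  if (preset == "toy3band") {
    scheme <- make_band_scheme(1000, 1900, 300)
    nmin <- if (is.null(n_minutes)) 60L else n_minutes
    noise_args <- list(base_level_at_f_low = 85 + if (winter) 5 else 0,
                       spectral_decay = 1, temporal_sd = 2, ar1_coeff = 0.6,
                       event_rate = 1, event_gain = 8)
    A_of <- function(b, z) (if (winter) 4 else 2) - 0.01 * z - 0.5 * b
    n_of <- function(b, z) 14 + 0.3 * b + if (winter) 0.002 * z else 0
    depth_grid <- seq(0, 200, by = 50)
    ranges <- 10^seq(1, 4.3, length.out = 15)
    residual_sd <- 0.5
  } else {
    scheme <- make_band_scheme(1000, 14800, 300)
    nmin <- if (is.null(n_minutes)) 360L else n_minutes
    if (preset == "quiet_inshore") {
      noise_args <- list(base_level_at_f_low = 82, spectral_decay = 0.35,
                         temporal_sd = 3, ar1_coeff = 0.7,
                         event_rate = 1, event_gain = 10)
      nf <- 15
    } else {
      noise_args <- list(base_level_at_f_low = 92, spectral_decay = 0.30,
                         temporal_sd = 4, ar1_coeff = 0.75,
                         event_rate = 4, event_gain = 12)
      nf <- 16.5
    }
    if (winter) {
      # +5 dB at low frequencies, tapering off by mid-scheme
      noise_args$base_level_at_f_low <- noise_args$base_level_at_f_low + 5
      noise_args$spectral_decay <- noise_args$spectral_decay + 5 / scheme$n_bands
    }
    A_of <- function(b, z) {
      duct <- if (winter) 3 * exp(-z / 20) else 0   # shallow winter duct
      1 - 0.005 * z - 0.04 * b + duct
    }
    n_of <- function(b, z) nf + 0.02 * b
    depth_grid <- seq(0, 200, by = 20)
    ranges <- 10^seq(1, 4.7, length.out = 25)
    residual_sd <- 1
  }

  noise <- do.call(gen_ambient_series, c(
    list(scheme = scheme, n_minutes = nmin, seed = seed,
         site_label = preset, season_label = season), noise_args))
  pls <- gen_pl_samples(scheme, depth_grid, A_of, n_of, ranges,
                        residual_sd = residual_sd, seed = seed + 1L)
  pl_fit <- suppressWarnings(
    fit_pl_loglaw(pls, scheme, depth_bins = seq(0, 200, by = 10)))
  sl_spec <- sl_preset("SRKW")
  depth_params <- depth_model()

  structure(list(
    scheme = scheme, noise = noise, pl_samples = pls, pl_fit = pl_fit,
    sl_spec = sl_spec, depth_params = depth_params,
    truth = list(preset = preset, season = season, seed = seed,
                 n_minutes = nmin, noise_args = noise_args,
                 depth_grid = depth_grid, ranges = ranges,
                 residual_sd = residual_sd),
    seed = seed
  ), class = "site_scenario")
}

#' @export
print.site_scenario <- function(x, ...) {
  cat(sprintf("<site_scenario> preset '%s' (%s), seed %d\n",
              x$truth$preset, x$truth$season, x$seed))
  print(x$noise)
  print(x$sl_spec)
  print(x$depth_params)
  invisible(x)
}

#' Write a scenario directory
#'
#' Materializes a [gen_site_scenario()] as the plain-text inputs the CLI
#' consumes: `ambient.csv`, `pl_samples.csv`, a ready-to-run `config.yaml`
#' and a `truth.json` record of the generating parameters.
#'
#' @param scenario A [gen_site_scenario()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_scenario <- function(scenario, dir) {
  stopifnot(inherits(scenario, "site_scenario"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_ambient_csv(scenario$noise, file.path(dir, "ambient.csv"))
  write_pl_csv(scenario$pl_samples, file.path(dir, "pl_samples.csv"))
  cfg <- list(
    site = list(name = scenario$truth$preset,
                season = scenario$truth$season),
    inputs = list(ambient_csv = "ambient.csv", pl_csv = "pl_samples.csv"),
    band_scheme = list(f_low_hz = scenario$scheme$f_low,
                       f_high_hz = scenario$scheme$f_high,
                       width_hz = scenario$scheme$width),
    source_level = list(mean_db = scenario$sl_spec$mean_bb,
                        sd_db = scenario$sl_spec$sd_bb,
                        slope_db_per_band = scenario$sl_spec$slope,
                        label = scenario$sl_spec$label),
    depth_model = list(mu = scenario$depth_params$mu,
                       sigma = scenario$depth_params$sigma,
                       z_max_m = scenario$depth_params$z_max),
    detection = list(dt_db = 5, n_sl = 100, n_depth = 100,
                     grid = list(min_m = 10, max_m = 1e5, n = 200),
                     percentiles = c(25, 50, 75),
                     probability_marks = c(0.1, 0.5, 0.9)),
    seed = scenario$seed,
    output_dir = "out")
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  truth <- scenario$truth
  truth$A_of <- NULL; truth$n_of <- NULL
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
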