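#' Monte Carlo detection configuration
#'
#' Bundles the tunables of the detection-range Monte Carlo. Defaults are
#' the standard analysis settings: detection threshold 5 dB (the
#' signal-to-noise ratio above which automated pulsed-call detectors
#' perform reliably), pools of 100 source levels x 100 depths crossed into
#' 10,000 realizations, a 200-point log-spaced range grid from 10 m to
#' 100 km, percentile envelopes at 25/50/75 and median-range marks at
#' P = 0.1/0.5/0.9.
#'
#' @param dt Detection threshold (dB), non-negative.
#' @param n_sl Source-level pool size.
#' @param n_depth Depth pool size.
#' @param range_grid Strictly increasing positive ranges (m) on which
#'   curves are sampled.
#' @param percentiles Summary quantiles (percent) for the curve envelope.
#' @param probability_marks Detection probabilities at which median ranges
#'   are reported.
#' @param seed Integer seed; all randomness in a run flows from it.
#' @param independent_resampling If `TRUE`, draw `n_sl * n_depth`
#'   independent (source level, depth) pairs instead of crossing the two
#'   pools (the cross product is the default and reproduces the
#'   10,000-realization design exactly).
#' @param median_method How the reported median ranges invert the ensemble:
#'   `"percentile"` (default) inverts the median percentile curve;
#'   `"per_realization"` inverts every realization's curve and takes the
#'   median of the resulting ranges.
#' @param store_curves Keep the full realization-by-range matrix in the
#'   result (default `TRUE`; ~16 MB at default sizes).
#' @return An object of class `detection_config`.
#' @export
detection_config <- function(dt = 5, n_sl = 100, n_depth = 100,
                             range_grid = 10^seq(1, 5, length.out = 200),
                             percentiles = c(25, 50, 75),
                             probability_marks = c(0.1, 0.5, 0.9),
                             seed = 1L,
                             independent_resampling = FALSE,
                             median_method = c("percentile", "per_realization"),
                             store_curves = TRUE) {
  median_method <- match.arg(median_method)
  if (dt < 0) stop("detection threshold must be non-negative")
  if (n_sl < 1 || n_depth < 1) stop("pool sizes must be at least 1")
  if (any(range_grid <= 0) || any(diff(range_grid) <= 0))
    stop("range_grid must be strictly increasing and positive")
  if (any(probability_marks <= 0 | probability_marks >= 1))
    stop("probability_marks must lie strictly inside (0, 1)")
  structure(list(dt = dt, n_sl = as.integer(n_sl),
                 n_depth = as.integer(n_depth),
                 range_grid = range_grid, percentiles = percentiles,
                 probability_marks = probability_marks,
                 seed = as.integer(seed),
                 independent_resampling = independent_resampling,
                 median_method = median_method,
                 store_curves = store_curves),
            class = "detection_config")
}

#' Per-band detection range (closed form)
#'
#' The range at which a call's received level in one band drops to exactly
#' `dt` dB above the ambient level in that band. With the fitted
#' propagation law `pl(R) = A - n * log10(R)` and received level
#' `SL + pl(R)`, the detection condition `SL + pl(R) >= NL + dt` inverts to
#' \deqn{R = 10^{(A + SL - NL - dt)/n}.}
#' The result is strictly increasing in `A` and `sl_band`, strictly
#' decreasing in `nl_band` and `dt`, and raising the noise by `n` dB
#' divides the range by exactly 10.
#'
#' All arguments may be vectors (recycled as usual).
#'
#' @param A Propagation intercept at 1 m (dB).
#' @param n Spreading coefficient (dB per decade), strictly positive.
#' @param sl_band Band source level (dB re 1 uPa m).
#' @param nl_band Band noise level (dB re 1 uPa).
#' @param dt Detection threshold (dB).
#' @return Detection range (m).
#' @examples
#' detection_range_band(A = 0, n = 20, sl_band = 155, nl_band = 100, dt = 5)
#' # 316.2278 = 10^(50/20)
#' @export
detection_range_band <- function(A, n, sl_band, nl_band, dt = 5) {
  if (any(n <= 0))
    stop("spreading coefficient n must be positive (filter unusable fits upstream)")
  10^((A + sl_band - nl_band - dt) / n)
}

#' Maximum detection range over bands
#'
#' The maximum of the per-band detection ranges and the (1-based) band
#' achieving it; ties break toward the lowest band index. Bands excluded
#' by `usable` never win.
#'
#' @param per_band_ranges Numeric vector of per-band ranges (m).
#' @param usable Logical mask, recycled to the vector length; default all.
#' @return List with `r_max` (m) and `band_index`.
#' @export
max_detection_range <- function(per_band_ranges,
                                usable = rep(TRUE, length(per_band_ranges))) {
  usable <- rep_len(usable, length(per_band_ranges))
  if (!any(usable)) stop("no usable band")
  r <- per_band_ranges
  r[!usable] <- -Inf
  i <- which.max(r)  # first maximum: ties go to the lowest band
  list(r_max = r[i], band_index = i)
}

#' Empirical detection-probability curve
#'
#' Converts per-minute maximum detection ranges into the survival-type
#' probability curve `P(r) = #\{minutes : Rmax >= r\} / n_minutes`,
#' sampled on a range grid. The curve is non-increasing and right
#' continuous (a minute whose `Rmax` equals a grid point counts as
#' detected there).
#'
#' @param r_max_per_minute Per-minute maximum detection ranges (m),
#'   non-empty.
#' @param range_grid Ranges (m) at which to sample the curve.
#' @return Probability vector of `length(range_grid)`.
#' @export
detection_curve <- function(r_max_per_minute, range_grid) {
  n <- length(r_max_per_minute)
  if (n == 0L) stop("need at least one minute")
  s <- sort(r_max_per_minute)
  (n - findInterval(range_grid, s, left.open = TRUE)) / n
}

# Same computation in log10-range space (used internally to avoid 10^x
# overflow for extreme synthetic draws).
curve_from_exponents <- function(sorted_ex, log10_grid) {
  n <- length(sorted_ex)
  (n - findInterval(log10_grid, sorted_ex, left.open = TRUE)) / n
}

#' Invert a detection-probability curve at a target probability
#'
#' Finds the largest range at which the curve is still at least `p`:
#' the largest grid point with `curve >= p`, refined by linear
#' interpolation in `log10(range)` toward the first grid point below `p`.
#' Returns 0 when the curve starts below `p`; when the curve never falls
#' below `p` the grid maximum is returned flagged unbounded.
#'
#' @param curve Non-increasing probability vector.
#' @param range_grid Matching ranges (m).
#' @param p Target probability in (0, 1).
#' @return List with `range_m` and logical `unbounded`.
#' @export
invert_detection_curve <- function(curve, range_grid, p) {
  stopifnot(length(curve) == length(range_grid))
  if (p <= 0 || p >= 1) stop("p must lie strictly inside (0, 1)")
  if (curve[1] < p) return(list(range_m = 0, unbounded = FALSE))
  if (curve[length(curve)] >= p)
    return(list(range_m = range_grid[length(range_grid)], unbounded = TRUE))
  i <- max(which(curve >= p))
  lg <- log10(range_grid)
  # curve[i] >= p > curve[i + 1]; interpolate in log-range
  frac <- (curve[i] - p) / (curve[i] - curve[i + 1L])
  list(range_m = 10^(lg[i] + frac * (lg[i + 1L] - lg[i])), unbounded = FALSE)
}

# Resolve usable bands and their depth-interpolated coefficients.
usable_bands_of <- function(pl) {
  sort(unique(pl$band_index[pl$usable]))
}

#' Detection-range Monte Carlo
#'
#' The central simulation. A pool of `n_sl` broadband source levels
#' (Gaussian) and a pool of `n_depth` caller depths (truncated
#' log-logistic) are drawn once; their full cross product yields
#' `n_sl * n_depth` realizations (10,000 at the defaults). Each
#' realization fixes one hypothetical caller -- its broadband level spread
#' across bands by the spectral slope (power-conserving), and the
#' propagation coefficients `(A, n)` interpolated at its depth -- and
#' computes, for every noise minute, the per-band detection ranges in
#' closed form, their maximum `Rmax` and the winning band. The fraction of
#' minutes with `Rmax >= r` is that realization's detection-probability
#' curve. The ensemble of curves is summarized by percentile envelopes,
#' a histogram of which band set `Rmax` (over realizations x minutes), and
#' median ranges at the configured probability marks.
#'
#' The engine never loops over grid ranges: `Rmax` is computed per
#' (band, realization, minute) from the closed form, and the grid is only
#' used to sample and invert curves.
#'
#' @param noise An [ambient_series()].
#' @param pl A [fit_pl_loglaw()] table on the same band scheme.
#' @param sl_spec A [source_level_spec()].
#' @param depth_params A [depth_model()].
#' @param config A [detection_config()].
#' @param pools Optional list with pre-drawn `sl` and `depth` vectors
#'   (used by [run_stratified()] and [run_sensitivity()] to share draws
#'   across runs); lengths must be `n_sl` and `n_depth`.
#' @param sl_anchor Band-allocation anchor passed to
#'   [allocate_band_levels()].
#' @return An object of class `detection_ensemble`: list with
#'   `range_grid`, `curves` (realizations x ranges, when stored),
#'   `percentile_curves` (percentiles x ranges), `argmax_band_share`
#'   (per-band fraction of realization-minutes, sums to 1),
#'   `median_ranges` (data.frame `p`, `range_m`, `unbounded`, `method`),
#'   `pools`, `n_minutes`, `usable_bands` and the `config`.
#' @export
run_monte_carlo <- function(noise, pl, sl_spec, depth_params,
                            config = detection_config(), pools = NULL,
                            sl_anchor = c("power", "first_band")) {
  sl_anchor <- match.arg(sl_anchor)
  stopifnot(inherits(noise, "ambient_series"), inherits(pl, "pl_fit_table"),
            inherits(sl_spec, "source_level_spec"),
            inherits(depth_params, "depth_model"),
            inherits(config, "detection_config"))
  scheme <- noise$scheme
  if (!same_scheme(scheme, attr(pl, "scheme")))
    stop("noise and propagation table use different band schemes")
  usable <- usable_bands_of(pl)
  if (length(usable) == 0L) stop("all bands unusable in the propagation table")

  set.seed(config$seed)
  if (is.null(pools)) {
    pools <- list(sl = sample_broadband_sl(sl_spec, config$n_sl),
                  depth = sample_depths(depth_params, config$n_depth))
  }
  stopifnot(length(pools$sl) == config$n_sl,
            length(pools$depth) == config$n_depth)

  if (config$independent_resampling) {
    n_real <- config$n_sl * config$n_depth
    sl_ix <- sample.int(config$n_sl, n_real, replace = TRUE)
    dp_ix <- sample.int(config$n_depth, n_real, replace = TRUE)
  } else {
    # cross product, depth-major: realization (d, s)
    dp_ix <- rep(seq_len(config$n_depth), each = config$n_sl)
    sl_ix <- rep(seq_len(config$n_sl), times = config$n_depth)
    n_real <- length(dp_ix)
  }

  # band-level offsets for a 0 dB broadband draw; adding sl_bb shifts the
  # power sum to sl_bb exactly
  sl_base <- allocate_band_levels(0, sl_spec$slope, scheme, anchor = sl_anchor)
  NL <- noise$spl[, usable, drop = FALSE]
  n_min <- nrow(NL)
  grid <- config$range_grid
  lgrid <- log10(grid)

  curves <- matrix(NA_real_, n_real, length(grid))
  band_counts <- numeric(scheme$n_bands)
  row_ix <- seq_len(n_min)

  k <- 0L
  for (d in unique(dp_ix)) {
    co <- lapply(usable, function(b) pl_coeffs_at(pl, b, pools$depth[d]))
    A_vec <- vapply(co, function(x) x$A, numeric(1))
    n_vec <- vapply(co, function(x) x$n, numeric(1))
    NLdiv <- sweep(NL, 2L, n_vec, "/")
    base_b <- (A_vec + sl_base[usable] - config$dt) / n_vec
    for (s in sl_ix[dp_ix == d]) {
      k <- k + 1L
      c_b <- base_b + pools$sl[s] / n_vec
      # E[m, b] = log10 of the per-band detection range
      E <- matrix(c_b, n_min, length(usable), byrow = TRUE) - NLdiv
      win <- max.col(E, ties.method = "first")
      ex <- E[cbind(row_ix, win)]
      band_counts[usable] <- band_counts[usable] +
        tabulate(win, nbins = length(usable))
      curves[k, ] <- curve_from_exponents(sort(ex), lgrid)
    }
  }

  pct <- apply(curves, 2L, stats::quantile, probs = config$percentiles / 100,
               names = FALSE, type = 7)
  if (is.null(dim(pct))) pct <- matrix(pct, nrow = 1L)
  rownames(pct) <- paste0("p", config$percentiles)

  median_ranges <- ensemble_median_ranges(
    curves, pct, grid, config$probability_marks, config$median_method)
  unb <- median_ranges$unbounded
  if (any(unb))
    warning("median range unbounded within the range grid at P = ",
            paste(median_ranges$p[unb], collapse = ", "), call. = FALSE)

  structure(list(
    range_grid = grid,
    curves = if (config$store_curves) curves else NULL,
    percentile_curves = pct,
    argmax_band_share = band_counts / (n_real * n_min),
    median_ranges = median_ranges,
    pools = pools,
    n_realizations = n_real,
    n_minutes = n_min,
    usable_bands = usable,
    scheme = scheme,
    config = config
  ), class = "detection_ensemble")
}

ensemble_median_ranges <- function(curves, pct, grid, p_marks, method) {
  if (method == "percentile") {
    med_row <- if ("p50" %in% rownames(pct)) "p50" else
      rownames(pct)[which.min(abs(as.numeric(sub("^p", "", rownames(pct))) - 50))]
    res <- lapply(p_marks, function(p)
      invert_detection_curve(pct[med_row, ], grid, p))
    data.frame(p = p_marks,
               range_m = vapply(res, `[[`, 0, "range_m"),
               unbounded = vapply(res, `[[`, TRUE, "unbounded"),
               method = method)
  } else {
    data.frame(p = p_marks, range_m = vapply(p_marks, function(p) {
      stats::median(apply(curves, 1L, function(cv)
        invert_detection_curve(cv, grid, p)$range_m))
    }, numeric(1)),
    unbounded = FALSE, method = method)
  }
}

#' @export
print.detection_ensemble <- function(x, ...) {
  cat(sprintf(
    "<detection_ensemble> %d realizations x %d minutes, %d usable bands\n",
    x$n_realizations, x$n_minutes, length(x$usable_bands)))
  mr <- x$median_ranges
  for (i in seq_len(nrow(mr)))
    cat(sprintf("  P = %.2f: median range %.0f m%s\n", mr$p[i], mr$range_m[i],
                if (mr$unbounded[i]) " (unbounded: grid maximum)" else ""))
  invisible(x)
}

#' Median range at a detection probability
#'
#' Inverts one of an ensemble's percentile curves (the median curve by
#' default) at probability `p`; see [invert_detection_curve()] for the
#' interpolation and boundary rules.
#'
#' @param ensemble A [run_monte_carlo()] result.
#' @param p Target probability in (0, 1).
#' @param which Percentile curve to invert: a row label such as `"p50"`
#'   (default) or a numeric percentile.
#' @return Range in m, with attribute `unbounded`.
#' @export
median_range_at_probability <- function(ensemble, p, which = "p50") {
  stopifnot(inherits(ensemble, "detection_ensemble"))
  if (is.numeric(which)) which <- paste0("p", which)
  if (!which %in% rownames(ensemble$percentile_curves))
    stop("no percentile curve ", which, "; available: ",
         paste(rownames(ensemble$percentile_curves), collapse = ", "))
  res <- invert_detection_curve(ensemble$percentile_curves[which, ],
                                ensemble$range_grid, p)
  structure(res$range_m, unbounded = res$unbounded)
}

#' Monte Carlo per noise stratum
#'
#' Re-runs [run_monte_carlo()] restricted to each stratum's minutes while
#' sharing one source-level pool and one depth pool (drawn once under the
#' config seed) across strata, so differences between the per-stratum
#' ensembles isolate the noise effect.
#'
#' @param noise An [ambient_series()].
#' @param strata A [stratify_by_broadband()] partition of its minutes.
#' @param pl,sl_spec,depth_params,config As in [run_monte_carlo()].
#' @return Named list of `detection_ensemble`s (`low`, `medium`, `high`)
#'   with the strata attached as an attribute.
#' @export
run_stratified <- function(noise, strata, pl, sl_spec, depth_params,
                           config = detection_config()) {
  stopifnot(inherits(strata, "noise_strata"))
  sizes <- lengths(strata$members)
  if (any(sizes == 0L))
    stop("empty stratum: ", paste(names(sizes)[sizes == 0L], collapse = ", "))
  set.seed(config$seed)
  pools <- list(sl = sample_broadband_sl(sl_spec, config$n_sl),
                depth = sample_depths(depth_params, config$n_depth))
  out <- lapply(strata$members, function(idx)
    run_monte_carlo(subset_minutes(noise, idx), pl, sl_spec, depth_params,
                    config, pools = pools))
  attr(out, "strata") <- strata
  out
}

#' Factor-swap sensitivity analysis
#'
#' Reruns the Monte Carlo swapping exactly one factor at a time --
#' `sl_spec` (source-level spec, e.g. slope), `noise` (ambient series),
#' `pl` (propagation table) or `depth_params` (depth distribution) --
#' under a shared seed, and reports the difference of the median detection
#' range at `p_mark` between the swapped and the baseline scenario.
#'
#' @param base Named list with elements `noise`, `pl`, `sl_spec`,
#'   `depth_params` and `config` (a baseline scenario).
#' @param swaps List of swaps; each swap is a single-element named list,
#'   e.g. `list(sl_spec = other_spec)`. A swap naming zero or several
#'   factors is an error.
#' @param p_mark Probability at which the medians are compared
#'   (default 0.5).
#' @return data.frame with columns `factor`, `median_a` (swapped, m),
#'   `median_b` (baseline, m), `difference` (`median_a - median_b`) and
#'   `p_mark`.
#' @export
run_sensitivity <- function(base, swaps, p_mark = 0.5) {
  need <- c("noise", "pl", "sl_spec", "depth_params", "config")
  miss <- setdiff(need, names(base))
  if (length(miss)) stop("base scenario missing: ", paste(miss, collapse = ", "))
  swappable <- c("noise", "pl", "sl_spec", "depth_params")
  for (sw in swaps) {
    if (!is.list(sw) || length(sw) != 1L || !all(names(sw) %in% swappable))
      stop("each swap must replace exactly one of: ",
           paste(swappable, collapse = ", "))
  }
  run1 <- function(sc) {
    ens <- run_monte_carlo(sc$noise, sc$pl, sc$sl_spec, sc$depth_params,
                           sc$config)
    as.numeric(median_range_at_probability(ens, p_mark))
  }
  median_b <- run1(base)
  rows <- lapply(swaps, function(sw) {
    sc <- base
    sc[[names(sw)]] <- sw[[1L]]
    data.frame(factor = names(sw), median_a = run1(sc), median_b = median_b,
               difference = NA_real_, p_mark = p_mark)
  })
  out <- do.call(rbind, rows)
  out$difference <- out$median_a - out$median_b
  rownames(out) <- NULL
  out
}

#' Write ensemble summaries as CSV
#'
#' Three small plain-text outputs: the percentile envelope
#' (`range_m, p25, p50, p75`), the median-range table
#' (`p_mark, percentile, range_m, unbounded_flag`) and the argmax-band
#' histogram (`band_low_hz, band_high_hz, share`).
#'
#' @param ensemble A [run_monte_carlo()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_ensemble_csv <- function(ensemble, dir) {
  stopifnot(inherits(ensemble, "detection_ensemble"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sch <- ensemble$scheme
  env <- data.frame(range_m = ensemble$range_grid,
                    t(ensemble$percentile_curves))
  f1 <- file.path(dir, "ensemble_summary.csv")
  utils::write.csv(env, f1, row.names = FALSE, quote = FALSE)
  mr <- ensemble$median_ranges
  f2 <- file.path(dir, "median_ranges.csv")
  utils::write.csv(
    data.frame(p_mark = mr$p, percentile = "p50",
               range_m = round(mr$range_m, 1), unbounded_flag = mr$unbounded),
    f2, row.names = FALSE, quote = FALSE)
  f3 <- file.path(dir, "argmax_bands.csv")
  utils::write.csv(
    data.frame(band_low_hz = sch$edges[-(sch$n_bands + 1L)],
               band_high_hz = sch$edges[-1L],
               share = ensemble$argmax_band_share),
    f3, row.names = FALSE, quote = FALSE)
  invisible(c(f1, f2, f3))
}
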