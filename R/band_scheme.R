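#' Contiguous frequency-band tiling
#'
#' Builds the frequency-band scheme shared by ambient-noise series,
#' call band spectra and propagation-loss tables: contiguous,
#' non-overlapping bands of equal width covering `[f_low, f_high]`.
#' Band membership is half-open `[low, high)` except for the final band,
#' which is closed at `f_high`, so the tiling covers the span without
#' double counting.
#'
#' The default analysis scheme for killer whale pulsed calls spans
#' 1000--14800 Hz in 300 Hz bands (46 bands), the narrowest bandwidth an
#' automated pulsed-call detector is assumed to accept.
#'
#' @param f_low Lower edge of the first band (Hz).
#' @param f_high Upper edge of the last band (Hz). `f_high - f_low` must be
#'   an exact multiple of `width`.
#' @param width Band width (Hz), strictly positive.
#'
#' @return An object of class `band_scheme`: a list with elements `f_low`,
#'   `f_high`, `width`, `n_bands`, `edges` (length `n_bands + 1`, strictly
#'   increasing) and `centers`.
#'
#' @examples
#' sch <- make_band_scheme(1000, 14800, 300)
#' sch$n_bands  # 46
#' @export
make_band_scheme <- function(f_low, f_high, width) {
  stopifnot(is.numeric(f_low), is.numeric(f_high), is.numeric(width),
            length(f_low) == 1L, length(f_high) == 1L, length(width) == 1L)
  if (width <= 0)
    stop("band width must be positive, got ", width)
  if (f_low >= f_high)
    stop("f_low (", f_low, ") must be below f_high (", f_high, ")")
  span <- f_high - f_low
  rem <- span %% width
  if (abs(rem) > 1e-9 && abs(rem - width) > 1e-9)
    stop(sprintf(
      "span %g Hz (%g to %g) is not an integer multiple of width %g Hz (remainder %g Hz)",
      span, f_low, f_high, width, rem))
  n_bands <- as.integer(round(span / width))
  edges <- f_low + width * (0:n_bands)
  structure(list(
    f_low = f_low,
    f_high = f_high,
    width = width,
    n_bands = n_bands,
    edges = edges,
    centers = (edges[-1L] + edges[-(n_bands + 1L)]) / 2
  ), class = "band_scheme")
}

#' @export
print.band_scheme <- function(x, ...) {
  cat(sprintf("<band_scheme> %g-%g Hz, %d bands of %g Hz\n",
              x$f_low, x$f_high, x$n_bands, x$width))
  invisible(x)
}

#' Default column names for band columns in CSV files
#' @noRd
band_colnames <- function(scheme) {
  sprintf("spl_%d_%d",
          as.integer(round(scheme$edges[-(scheme$n_bands + 1L)])),
          as.integer(round(scheme$edges[-1L])))
}

same_scheme <- function(a, b) {
  isTRUE(all.equal(a$edges, b$edges, tolerance = 1e-9))
}

#' Power sum of band sound pressure levels
#'
#' Reduces per-band SPLs (dB re 1 uPa) to one broadband level by summing
#' mean-square pressures: `10 * log10(sum(10^(spl/10)))`. The result is
#' always at least the loudest band, is invariant to band order, and
#' strictly increases when any band level is raised.
#'
#' @param band_spls Numeric vector of band levels (dB). Must be non-empty
#'   and finite.
#' @return Broadband level (dB), a single number.
#' @examples
#' broadband_level(c(90, 90))  # 93.0103
#' @export
broadband_level <- function(band_spls) {
  if (length(band_spls) == 0L)
    stop("broadband_level: need at least one band level")
  if (!all(is.finite(band_spls)))
    stop("broadband_level: all band levels must be finite")
  10 * log10(sum(10^(band_spls / 10)))
}

#' Minutes-by-bands ambient noise series
#'
#' Container for the per-minute ambient band levels NL(f, t): a matrix of
#' SPL (dB re 1 uPa) with one row per minute (or averaging window) and one
#' column per band of the attached scheme. Timestamps are carried as opaque
#' ordered labels; no timezone logic is applied.
#'
#' @param spl Numeric matrix, `n_minutes x scheme$n_bands`, finite.
#' @param scheme A [make_band_scheme()] object.
#' @param timestamps Optional character vector of unique labels (ISO-8601
#'   recommended), one per row; generated as `min_000001, ...` if omitted.
#' @param site_label,season_label Free-text metadata.
#' @return An object of class `ambient_series`.
#' @export
ambient_series <- function(spl, scheme, timestamps = NULL,
                           site_label = "", season_label = "") {
  spl <- as.matrix(spl)
  if (!inherits(scheme, "band_scheme")) stop("scheme must be a band_scheme")
  if (ncol(spl) != scheme$n_bands)
    stop(sprintf("spl has %d columns but scheme has %d bands",
                 ncol(spl), scheme$n_bands))
  if (!all(is.finite(spl))) stop("all SPL values must be finite")
  if (is.null(timestamps))
    timestamps <- sprintf("min_%06d", seq_len(nrow(spl)))
  timestamps <- as.character(timestamps)
  if (length(timestamps) != nrow(spl))
    stop("timestamps length must match number of rows")
  if (anyDuplicated(timestamps))
    stop("timestamps must be unique")
  colnames(spl) <- band_colnames(scheme)
  structure(list(timestamps = timestamps, spl = spl, scheme = scheme,
                 site_label = site_label, season_label = season_label),
            class = "ambient_series")
}

#' @export
print.ambient_series <- function(x, ...) {
  cat(sprintf("<ambient_series> %d minutes x %d bands (%g-%g Hz)",
              nrow(x$spl), x$scheme$n_bands, x$scheme$f_low, x$scheme$f_high))
  if (nzchar(x$site_label)) cat(" site:", x$site_label)
  if (nzchar(x$season_label)) cat(" season:", x$season_label)
  cat("\n")
  invisible(x)
}

#' Restrict an ambient series to a subset of minutes
#' @noRd
subset_minutes <- function(series, idx) {
  ambient_series(series$spl[idx, , drop = FALSE], series$scheme,
                 timestamps = series$timestamps[idx],
                 site_label = series$site_label,
                 season_label = series$season_label)
}

#' Per-minute broadband levels of an ambient series
#'
#' @param series An [ambient_series()].
#' @return Numeric vector, one broadband level (dB) per minute.
#' @export
series_broadband <- function(series) {
  stopifnot(inherits(series, "ambient_series"))
  10 * log10(rowSums(10^(series$spl / 10)))
}

#' Stratify minutes into low / medium / high noise conditions
#'
#' Partitions the minutes of an ambient series by their broadband level
#' using empirical quantiles (by default the 33rd and 66th percentiles, so
#' each condition is represented equally). Minutes strictly below the lower
#' threshold are "low", strictly above the upper threshold "high", and the
#' closed middle interval "medium" -- ties therefore land in the middle
#' stratum.
#'
#' @param series An [ambient_series()] with at least 3 minutes.
#' @param probs Two quantile fractions, `lower <= upper`.
#' @return An object of class `noise_strata`: list with `thresholds`
#'   (lower, upper broadband dB), `members` (list of index vectors `low`,
#'   `medium`, `high`) and `broadband` (the per-minute levels).
#' @export
stratify_by_broadband <- function(series, probs = c(1/3, 2/3)) {
  stopifnot(inherits(series, "ambient_series"), length(probs) == 2L)
  if (probs[1] > probs[2]) stop("probs must be non-decreasing")
  n <- nrow(series$spl)
  if (n < 3L)
    stop("need at least 3 minutes to form 3 strata, got ", n)
  bb <- series_broadband(series)
  thr <- stats::quantile(bb, probs, names = FALSE, type = 7)
  members <- list(
    low = which(bb < thr[1]),
    medium = which(bb >= thr[1] & bb <= thr[2]),
    high = which(bb > thr[2])
  )
  structure(list(thresholds = thr, members = members, broadband = bb),
            class = "noise_strata")
}

#' @export
print.noise_strata <- function(x, ...) {
  cat(sprintf(
    "<noise_strata> low/medium/high = %d/%d/%d minutes, thresholds %.2f / %.2f dB\n",
    length(x$members$low), length(x$members$medium), length(x$members$high),
    x$thresholds[1], x$thresholds[2]))
  invisible(x)
}

#' Read / write ambient band-level CSV
#'
#' The on-disk format is one row per minute: first column `timestamp`
#' (ISO-8601 text), then one column per band named `spl_<lowHz>_<highHz>`.
#' Leading comment lines prefixed `#` carry `site:` and `season:` metadata.
#' Levels are written with 4 decimal places, so a write/read round trip is
#' lossless to 1e-4 dB.
#'
#' @param path File path.
#' @param scheme Optional [make_band_scheme()]; when given, the file's band
#'   columns must match it exactly (an error names expected vs found
#'   band counts otherwise). When omitted the scheme is reconstructed from
#'   the column names.
#' @return `read_ambient_csv` returns an [ambient_series()];
#'   `write_ambient_csv` invisibly returns `path`.
#' @export
read_ambient_csv <- function(path, scheme = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  head_lines <- readLines(path, n = 50L)
  meta <- grep("^#", head_lines, value = TRUE)
  get_meta <- function(key) {
    m <- grep(paste0("^#\\s*", key, ":"), meta, value = TRUE)
    if (length(m) == 0L) return("")
    trimws(sub(paste0("^#\\s*", key, ":"), "", m[1]))
  }
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  if (!"timestamp" %in% names(df))
    stop("malformed header: missing 'timestamp' column in ", path)
  band_cols <- grep("^spl_\\d+_\\d+$", names(df), value = TRUE)
  if (length(band_cols) == 0L)
    stop("malformed header: no spl_<low>_<high> band columns in ", path)
  lows <- as.numeric(sub("^spl_(\\d+)_(\\d+)$", "\\1", band_cols))
  highs <- as.numeric(sub("^spl_(\\d+)_(\\d+)$", "\\2", band_cols))
  ord <- order(lows)
  band_cols <- band_cols[ord]; lows <- lows[ord]; highs <- highs[ord]
  widths <- unique(highs - lows)
  if (length(widths) != 1L || any(highs[-length(highs)] != lows[-1]))
    stop("malformed header: band columns are not a contiguous equal-width tiling")
  file_scheme <- make_band_scheme(lows[1], highs[length(highs)], widths)
  if (!is.null(scheme)) {
    if (!same_scheme(scheme, file_scheme))
      stop(sprintf("band scheme mismatch: expected %d bands (%g-%g Hz), found %d bands (%g-%g Hz)",
                   scheme$n_bands, scheme$f_low, scheme$f_high,
                   file_scheme$n_bands, file_scheme$f_low, file_scheme$f_high))
    file_scheme <- scheme
  }
  ambient_series(as.matrix(df[band_cols]), file_scheme,
                 timestamps = as.character(df$timestamp),
                 site_label = get_meta("site"),
                 season_label = get_meta("season"))
}

#' @param series An [ambient_series()] to write.
#' @rdname read_ambient_csv
#' @export
write_ambient_csv <- function(series, path) {
  stopifnot(inherits(series, "ambient_series"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("# site:", series$site_label),
               paste("# season:", series$season_label),
               paste("# units: dB re 1 uPa")), con)
  df <- data.frame(timestamp = series$timestamps,
                   round(series$spl, 4), check.names = FALSE)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
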