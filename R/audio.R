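#' Per-band SPL from a calibrated pressure waveform
#'
#' Converts a single-channel time series into an [ambient_series()] of
#' band sound pressure levels, one row per full averaging window. The
#' spectral estimate is a Welch average of Hann-windowed 1-second
#' periodograms with 50% overlap; the one-sided power spectral density is
#' integrated across each band's edges (half-open `[low, high)` bins, last
#' band closed), so the band SPL is `10*log10` of the mean-square pressure
#' contributed by that band. Partial trailing windows are discarded.
#'
#' @param waveform Numeric vector. If `sensitivity` is `NULL` the samples
#'   are taken to be pressure in micropascal; otherwise they are voltages
#'   and are converted with `p = v * 10^(-(sensitivity + gain)/20)`.
#' @param sample_rate Sampling rate (Hz); must exceed `2 * scheme$f_high`.
#' @param scheme A [make_band_scheme()].
#' @param window Averaging window length in seconds (default 60, i.e.
#'   1-minute levels). Must be at least 1 s.
#' @param sensitivity Optional hydrophone sensitivity, dB re 1 V/uPa
#'   (e.g. -165).
#' @param gain Additional gain applied during recording, dB (default 0).
#' @param silence How to treat windows with zero in-band power:
#'   `"error"` (default) aborts; `"floor"` emits a -120 dB floor instead,
#'   avoiding silent propagation of `-Inf`.
#' @param site_label,season_label Metadata carried into the result.
#'
#' @return An [ambient_series()] with one row per full window. Row labels
#'   are the window start offsets in seconds.
#' @export
band_spl_from_audio <- function(waveform, sample_rate, scheme, window = 60,
                                sensitivity = NULL, gain = 0,
                                silence = c("error", "floor"),
                                site_label = "", season_label = "") {
  silence <- match.arg(silence)
  stopifnot(inherits(scheme, "band_scheme"), is.numeric(waveform))
  if (length(waveform) == 0L) stop("zero-length audio")
  if (sample_rate <= 2 * scheme$f_high)
    stop(sprintf(
      "Nyquist violation: sample rate %g Hz must exceed 2 x %g Hz",
      sample_rate, scheme$f_high))
  if (window < 1) stop("averaging window must be at least 1 second")
  if (!is.null(sensitivity))
    waveform <- waveform * 10^(-(sensitivity + gain) / 20)

  fs <- sample_rate
  nseg <- as.integer(round(fs))           # 1 s analysis segments
  wlen <- as.integer(round(window * fs))
  n_win <- length(waveform) %/% wlen
  if (n_win < 1L)
    stop(sprintf("recording (%.2f s) shorter than one %g s window",
                 length(waveform) / fs, window))

  w <- 0.5 - 0.5 * cos(2 * pi * (0:(nseg - 1L)) / nseg)  # periodic Hann
  U <- sum(w^2)
  half <- nseg %/% 2L
  freqs <- (0:half) * fs / nseg
  df <- fs / nseg
  # one-sided scaling: double everything but DC (and Nyquist when present)
  one_sided <- rep(2, half + 1L)
  one_sided[1L] <- 1
  if (nseg %% 2L == 0L) one_sided[half + 1L] <- 1

  edges <- scheme$edges
  band_of_bin <- findInterval(freqs, edges, left.open = FALSE)
  # half-open [low, high) membership; final band closed at f_high
  band_of_bin[freqs >= scheme$f_high] <- NA_integer_
  band_of_bin[abs(freqs - scheme$f_high) < df / 2] <- scheme$n_bands
  band_of_bin[freqs < scheme$f_low] <- NA_integer_
  band_of_bin[band_of_bin %in% 0L] <- NA_integer_

  spl <- matrix(NA_real_, n_win, scheme$n_bands)
  for (k in seq_len(n_win)) {
    x <- waveform[((k - 1L) * wlen + 1L):(k * wlen)]
    starts <- seq(1L, wlen - nseg + 1L, by = max(1L, half))
    psd <- numeric(half + 1L)
    for (s in starts) {
      X <- stats::fft(w * x[s:(s + nseg - 1L)])
      psd <- psd + one_sided * Mod(X[1:(half + 1L)])^2 / (fs * U)
    }
    psd <- psd / length(starts)
    band_power <- vapply(seq_len(scheme$n_bands), function(b) {
      sum(psd[which(band_of_bin == b)]) * df
    }, numeric(1))
    if (any(band_power <= 0)) {
      if (silence == "error")
        stop("digital silence: zero in-band power in window ", k,
             " (use silence = \"floor\" to emit a -120 dB floor)")
      band_power[band_power <= 0] <- 10^(-12)
    }
    spl[k, ] <- 10 * log10(band_power)
  }
  ambient_series(spl, scheme,
                 timestamps = sprintf("%.0fs", (seq_len(n_win) - 1L) * window),
                 site_label = site_label, season_label = season_label)
}

#' Minimal mono WAV reader
#'
#' Reads single-channel RIFF/WAVE audio: 16-bit integer PCM (format 1) or
#' 32-bit IEEE float (format 3). Integer samples are normalized to the
#' range \[-1, 1) full scale. This is deliberately minimal plumbing for
#' feeding [band_spl_from_audio()]; multi-channel or other encodings are
#' rejected with an explanatory error.
#'
#' @param path Path to a `.wav` file.
#' @return List with `samples` (numeric, full-scale units) and
#'   `sample_rate` (Hz).
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)
  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- list(
        format = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
        channels = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
        sample_rate = readBin(con, "integer", 1, 4, endian = "little"),
        byte_rate = readBin(con, "integer", 1, 4, endian = "little"),
        block_align = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
        bits = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE))
      extra <- sz - 16L
      if (extra > 0L) invisible(readBin(con, "raw", extra))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
      if (sz %% 2L == 1L) invisible(readBin(con, "raw", 1))
    } else {
      invisible(readBin(con, "raw", sz + sz %% 2L))
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stop("missing fmt/data chunk in ", path)
  if (fmt$channels != 1L)
    stop("only single-channel WAV is supported, file has ", fmt$channels)
  if (fmt$format == 1L && fmt$bits == 16L) {
    samples <- readBin(data_raw, "integer", length(data_raw) %/% 2L, 2L,
                       signed = TRUE, endian = "little") / 32768
  } else if (fmt$format == 3L && fmt$bits == 32L) {
    samples <- readBin(data_raw, "double", length(data_raw) %/% 4L, 4L,
                       endian = "little")
  } else {
    stop(sprintf("unsupported WAV encoding: format %d, %d bits",
                 fmt$format, fmt$bits))
  }
  list(samples = samples, sample_rate = fmt$sample_rate)
}
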