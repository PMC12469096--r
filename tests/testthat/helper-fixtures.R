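# Shared fixture builders. Everything is generated in code; no data files.

# A constant-noise ambient series (every minute identical).
flat_noise <- function(scheme, n_minutes, level) {
  ambient_series(matrix(level, n_minutes, scheme$n_bands), scheme)
}

# A propagation fit table recovered exactly from noiseless synthetic
# samples generated by depth-independent rules.
exact_pl_table <- function(scheme, A_vals, n_vals,
                           depth_grid = c(5, 15),
                           depth_bins = c(0, 10, 20),
                           ranges = c(10, 100, 1000, 10000)) {
  stopifnot(length(A_vals) == scheme$n_bands,
            length(n_vals) == scheme$n_bands)
  s <- gen_pl_samples(scheme, depth_grid,
                      A_of = function(b, z) A_vals[b],
                      n_of = function(b, z) n_vals[b],
                      ranges = ranges, residual_sd = 0)
  fit_pl_loglaw(s, scheme, depth_bins = depth_bins)
}

# Brute-force detection oracle: loops over every
# (realization, minute, band, grid range) and tests
# SL(band) + pl_at(range) >= NL(minute, band) + DT directly.
# Realization order matches the engine's depth-major cross product.
oracle_curves <- function(noise, pl, sl_spec, depth_params, config, pools) {
  scheme <- noise$scheme
  usable <- sort(unique(pl$band_index[pl$usable]))
  grid <- config$range_grid
  n_min <- nrow(noise$spl)
  curves <- matrix(NA_real_, config$n_sl * config$n_depth, length(grid))
  k <- 0L
  for (d in seq_len(config$n_depth)) {
    for (s in seq_len(config$n_sl)) {
      k <- k + 1L
      slb <- allocate_band_levels(pools$sl[s], sl_spec$slope, scheme)
      for (gi in seq_along(grid)) {
        hits <- 0L
        for (m in seq_len(n_min)) {
          detected <- FALSE
          for (b in usable) {
            rl_rel <- slb[b] + pl_at(pl, b, pools$depth[d], grid[gi])
            if (rl_rel >= noise$spl[m, b] + config$dt) {
              detected <- TRUE
              break
            }
          }
          if (detected) hits <- hits + 1L
        }
        curves[k, gi] <- hits / n_min
      }
    }
  }
  curves
}

# A random small instance for oracle-equivalence checks:
# <= 5 bands, <= 20 minutes, <= 9 realizations, noiseless PL fits.
random_small_instance <- function(seed) {
  set.seed(seed)
  nb <- sample(1:5, 1)
  scheme <- make_band_scheme(1000, 1000 + nb * 300, 300)
  n_min <- sample(2:20, 1)
  noise <- ambient_series(
    matrix(stats::rnorm(n_min * nb, 90, 6), n_min, nb), scheme)
  A_vals <- stats::runif(nb, -5, 5)
  n_vals <- stats::runif(nb, 10, 20)
  pl <- exact_pl_table(scheme, A_vals, n_vals,
                       depth_grid = c(5, 15, 25),
                       depth_bins = c(0, 10, 20, 30))
  n_sl <- sample(1:3, 1)
  n_depth <- sample(1:3, 1)
  config <- detection_config(
    dt = 5, n_sl = n_sl, n_depth = n_depth,
    range_grid = 10^seq(0.5, 5, length.out = sample(5:12, 1)),
    seed = seed)
  sl_spec <- source_level_spec(stats::runif(1, 140, 160),
                               stats::runif(1, 0, 8),
                               stats::runif(1, -1, 0.3))
  depth_params <- depth_model()
  list(noise = noise, pl = pl, sl_spec = sl_spec,
       depth_params = depth_params, config = config)
}

# Write a mono 16-bit PCM WAV from samples in [-1, 1).
write_test_wav <- function(path, samples, sample_rate) {
  pcm <- as.integer(pmax(-32768, pmin(32767, round(samples * 32768))))
  con <- file(path, "wb")
  on.exit(close(con))
  data_size <- length(pcm) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")          # PCM
  writeBin(1L, con, size = 2, endian = "little")          # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * 2L), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
}
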