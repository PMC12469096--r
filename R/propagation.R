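#' Propagation-loss sample table
#'
#' Validates a table of band-averaged propagation samples exported from an
#' external propagation model (one row per modeled point). Required
#' columns: `range_m` (> 0), `source_depth_m`, `band_index` (valid for
#' `scheme`), `pl_db` (finite). An optional `transect_id` column labels the
#' modeled radial the sample came from.
#'
#' The stored quantity follows the fitted law `pl = A - n * log10(range)`:
#' the level change between 1 m and the receiver, so the received level of
#' a call is `SL + pl` (see [detection_range_band()]).
#'
#' @param df A data.frame with the columns above.
#' @param scheme A [make_band_scheme()].
#' @return An object of class `pl_samples` (the validated data.frame with
#'   the scheme attached as an attribute).
#' @export
pl_samples <- function(df, scheme) {
  stopifnot(is.data.frame(df), inherits(scheme, "band_scheme"))
  need <- c("range_m", "source_depth_m", "band_index", "pl_db")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("pl_samples: missing columns: ",
                         paste(miss, collapse = ", "))
  if (nrow(df) == 0L) stop("pl_samples: empty table")
  if (any(df$range_m <= 0)) stop("pl_samples: all ranges must be positive")
  if (!all(is.finite(df$pl_db))) stop("pl_samples: pl_db must be finite")
  if (any(df$band_index < 1L | df$band_index > scheme$n_bands))
    stop("pl_samples: band_index outside 1..", scheme$n_bands)
  if (!"transect_id" %in% names(df)) df$transect_id <- "all"
  structure(df, scheme = scheme, class = c("pl_samples", "data.frame"))
}

#' Fit the log-range propagation law per band and source-depth bin
#'
#' For every (band, depth-bin) cell with data, fits ordinary least squares
#' of `pl_db` on `log10(range_m)`:
#' \deqn{pl \approx A - n \log_{10} R}
#' so `A` is the level at 1 m and `n` the geometric spreading coefficient
#' (dB per decade of range). Cells with fewer than 2 distinct ranges are
#' flagged unusable rather than fitted; fitted cells with `n <= 0` or
#' `r2` below `r2_floor` are kept in the table but flagged unusable, and a
#' one-time warning lists them.
#'
#' @param samples A [pl_samples()] table.
#' @param scheme A [make_band_scheme()]; must match the table's.
#' @param depth_bins Bin edges (m) for grouping source depths; default
#'   0--200 m in 10 m bins. Depths outside the edges fall into the nearest
#'   end bin.
#' @param pooling `"pooled"` (default) fits each cell on all transects
#'   together; `"per_transect"` fits each transect separately and takes the
#'   per-cell median of the coefficients. With a single transect the two
#'   are identical.
#' @param r2_floor Minimum coefficient of determination for a cell to be
#'   usable (default 0.5).
#'
#' @return An object of class `pl_fit_table`: a data.frame with one row per
#'   fitted cell and columns `band_index`, `depth_bin_center`, `A`, `n`,
#'   `r2`, `rmse`, `n_samples`, `usable`; the scheme and bin edges are
#'   attached as attributes.
#' @export
fit_pl_loglaw <- function(samples, scheme = attr(samples, "scheme"),
                          depth_bins = seq(0, 200, by = 10),
                          pooling = c("pooled", "per_transect"),
                          r2_floor = 0.5) {
  pooling <- match.arg(pooling)
  stopifnot(inherits(samples, "pl_samples"))
  if (!same_scheme(scheme, attr(samples, "scheme")))
    stop("scheme does not match the sample table's scheme")
  if (nrow(samples) == 0L) stop("empty sample table")
  db <- sort(unique(depth_bins))
  if (length(db) < 2L) stop("need at least 2 depth bin edges")
  centers <- (db[-1L] + db[-length(db)]) / 2
  bin_of <- findInterval(samples$source_depth_m, db,
                         rightmost.closed = TRUE, all.inside = TRUE)

  fit_one <- function(r, pl) {
    if (length(unique(r)) < 2L)
      return(list(A = NA_real_, n = NA_real_, r2 = NA_real_,
                  rmse = NA_real_, ok = FALSE))
    fit <- stats::lm.fit(cbind(1, log10(r)), pl)
    A <- fit$coefficients[1]
    n <- -fit$coefficients[2]
    res <- fit$residuals
    sst <- sum((pl - mean(pl))^2)
    r2 <- if (sst > 0) 1 - sum(res^2) / sst else 1
    list(A = unname(A), n = unname(n), r2 = r2,
         rmse = sqrt(mean(res^2)), ok = TRUE)
  }

  rows <- list()
  for (b in sort(unique(samples$band_index))) {
    for (k in sort(unique(bin_of[samples$band_index == b]))) {
      sel <- samples$band_index == b & bin_of == k
      r <- samples$range_m[sel]; pl <- samples$pl_db[sel]
      if (pooling == "pooled") {
        f <- fit_one(r, pl)
      } else {
        tid <- samples$transect_id[sel]
        fits <- lapply(split(seq_along(r), tid), function(i)
          fit_one(r[i], pl[i]))
        fits <- Filter(function(f) f$ok, fits)
        if (length(fits) == 0L) {
          f <- list(A = NA_real_, n = NA_real_, r2 = NA_real_,
                    rmse = NA_real_, ok = FALSE)
        } else {
          f <- list(A = stats::median(vapply(fits, `[[`, 0, "A")),
                    n = stats::median(vapply(fits, `[[`, 0, "n")),
                    r2 = stats::median(vapply(fits, `[[`, 0, "r2")),
                    rmse = stats::median(vapply(fits, `[[`, 0, "rmse")),
                    ok = TRUE)
        }
      }
      usable <- f$ok && is.finite(f$n) && f$n > 0 &&
        is.finite(f$r2) && f$r2 >= r2_floor
      rows[[length(rows) + 1L]] <- data.frame(
        band_index = b, depth_bin_center = centers[k],
        A = f$A, n = f$n, r2 = f$r2, rmse = f$rmse,
        n_samples = sum(sel), usable = usable)
    }
  }
  out <- do.call(rbind, rows)
  flagged <- out[!out$usable, , drop = FALSE]
  if (nrow(flagged) > 0L)
    warning(sprintf(
      "%d propagation cell(s) flagged unusable (bands: %s); they are excluded from the band argmax",
      nrow(flagged),
      paste(sort(unique(flagged$band_index)), collapse = ", ")),
      call. = FALSE)
  structure(out, scheme = scheme, depth_bins = db, r2_floor = r2_floor,
            class = c("pl_fit_table", "data.frame"))
}

#' Propagation coefficients at an arbitrary source depth
#'
#' Linearly interpolates the fitted `A` and `n` of one band between
#' depth-bin centers; outside the fitted span the nearest bin's values are
#' used (clamping). Only usable cells participate.
#'
#' @param table A [fit_pl_loglaw()] result.
#' @param band_index Band (1-based).
#' @param z Source depth (m); may be a vector.
#' @return List with numeric vectors `A` and `n` of `length(z)`.
#' @export
pl_coeffs_at <- function(table, band_index, z) {
  stopifnot(inherits(table, "pl_fit_table"))
  cells <- table[table$band_index == band_index & table$usable, , drop = FALSE]
  if (nrow(cells) == 0L)
    stop("band ", band_index, " has no usable propagation fit")
  if (nrow(cells) == 1L)
    return(list(A = rep(cells$A, length(z)), n = rep(cells$n, length(z))))
  cells <- cells[order(cells$depth_bin_center), ]
  list(
    A = stats::approx(cells$depth_bin_center, cells$A, xout = z, rule = 2)$y,
    n = stats::approx(cells$depth_bin_center, cells$n, xout = z, rule = 2)$y
  )
}

#' Evaluate the fitted propagation law
#'
#' Returns `A - n * log10(R)` for one band at source depth `z`, using
#' depth-interpolated coefficients from [pl_coeffs_at()]. By construction
#' the value drops by exactly `n` dB per decade of range.
#'
#' @param table A [fit_pl_loglaw()] result.
#' @param band_index Band (1-based).
#' @param z Source depth (m).
#' @param R Range (m), strictly positive; may be a vector.
#' @return Propagation level offset (dB), `length(R)`.
#' @export
pl_at <- function(table, band_index, z, R) {
  if (any(R <= 0)) stop("range must be positive")
  co <- pl_coeffs_at(table, band_index, z)
  co$A - co$n * log10(R)
}

#' Read / write propagation tables as CSV
#'
#' Sample CSV columns: `range_m, source_depth_m, band_low_hz, band_high_hz,
#' pl_db[, transect_id]`. Fit-table CSV columns: `band_low_hz,
#' band_high_hz, depth_bin_center_m, A_db, n, r2, rmse_db, n_samples,
#' usable`.
#'
#' @param path File path.
#' @param scheme A [make_band_scheme()] used to map band edges to indices.
#' @return `read_pl_csv` returns a [pl_samples()] table.
#' @export
read_pl_csv <- function(path, scheme) {
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("range_m", "source_depth_m", "band_low_hz", "band_high_hz", "pl_db")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("PL CSV missing columns: ", paste(miss, collapse = ", "))
  idx <- match(df$band_low_hz, scheme$edges[-(scheme$n_bands + 1L)])
  if (anyNA(idx))
    stop("PL CSV contains band edges not in the scheme")
  df$band_index <- idx
  keep <- c("range_m", "source_depth_m", "band_index", "pl_db",
            intersect("transect_id", names(df)))
  pl_samples(df[keep], scheme)
}

#' @param samples A [pl_samples()] table to write.
#' @rdname read_pl_csv
#' @export
write_pl_csv <- function(samples, path) {
  stopifnot(inherits(samples, "pl_samples"))
  scheme <- attr(samples, "scheme")
  df <- data.frame(
    range_m = samples$range_m,
    source_depth_m = samples$source_depth_m,
    band_low_hz = scheme$edges[samples$band_index],
    band_high_hz = scheme$edges[samples$band_index + 1L],
    pl_db = round(samples$pl_db, 4),
    transect_id = samples$transect_id)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @param table A [fit_pl_loglaw()] result to write.
#' @rdname read_pl_csv
#' @export
write_pl_fit_csv <- function(table, path) {
  stopifnot(inherits(table, "pl_fit_table"))
  scheme <- attr(table, "scheme")
  df <- data.frame(
    band_low_hz = scheme$edges[table$band_index],
    band_high_hz = scheme$edges[table$band_index + 1L],
    depth_bin_center_m = table$depth_bin_center,
    A_db = table$A, n = table$n, r2 = table$r2, rmse_db = table$rmse,
    n_samples = table$n_samples, usable = table$usable)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
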