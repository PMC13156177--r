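# Time-varying RSA: cubic-spline resampling of the IBI series to a uniform
# grid, then multitaper short-time spectral band power in the respiration
# band, one estimate per second at the centre of each rolling window.

#' Estimator configuration for time-varying RSA
#'
#' @param resample_hz Uniform sampling rate for the resampled IBI series
#'   (samples/s). Default 4.
#' @param window_s Rolling window length in seconds. Default 32; the RSA
#'   value for second t uses samples in `[t - window_s/2, t + window_s/2)`.
#' @param band_lo,band_hi Respiration band edges in Hz. Defaults are the
#'   adult band 0.12-0.40 Hz. There is no safe default for children: supply
#'   an age-appropriate band explicitly (e.g. 0.24-1.04 Hz for upper
#'   childhood).
#' @param taper Taper family: `"dpss"` (discrete prolate spheroidal, a
#'   multitaper set) or `"hann"` (single Hann window fallback).
#' @param n_tapers Number of DPSS tapers averaged (ignored for `"hann"`).
#' @param nw Time-bandwidth product for the DPSS construction. The default
#'   2 keeps the spectral concentration half-bandwidth (`nw / window_s` =
#'   0.0625 Hz at 32-s windows) below the margin between slow drift and the
#'   0.12 Hz band edge, so out-of-band energy does not smear into the band.
#' @param detrend Linearly detrend each window before tapering (in addition
#'   to demeaning). Default `TRUE`: keeps slow drift out of the band.
#' @param log_floor Minimum band power (ms^2) before taking the log; guards
#'   against `-Inf` on pathological constant input.
#' @param log_output If `TRUE` (default) RSA values are `ln(band power)` in
#'   ln(ms^2); if `FALSE`, raw band power in ms^2.
#' @return A list with class `estimator_config`.
#' @export
estimator_config <- function(resample_hz = 4, window_s = 32,
                             band_lo = 0.12, band_hi = 0.40,
                             taper = c("dpss", "hann"), n_tapers = 3,
                             nw = 2, detrend = TRUE, log_floor = 1e-8,
                             log_output = TRUE) {
  taper <- match.arg(taper)
  if (!(band_lo > 0))
    stop("invalid estimator config: band_lo must be > 0")
  if (!(band_lo < band_hi))
    stop("invalid estimator config: band_lo must be < band_hi")
  if (!(band_hi < resample_hz / 2))
    stop("invalid estimator config: band_hi must be below the Nyquist ",
         "frequency resample_hz/2 = ", resample_hz / 2)
  n_win <- window_s * resample_hz
  if (abs(n_win - round(n_win)) > 1e-9 || n_win < 64)
    stop("invalid estimator config: window_s * resample_hz must be an ",
         "integer >= 64")
  if (taper == "dpss" && (n_tapers < 1 || n_tapers > 2 * nw - 1))
    stop("invalid estimator config: n_tapers must be in [1, 2*nw - 1]")
  if (log_floor <= 0)
    stop("invalid estimator config: log_floor must be > 0")
  structure(list(resample_hz = resample_hz, window_s = window_s,
                 band_lo = band_lo, band_hi = band_hi, taper = taper,
                 n_tapers = n_tapers, nw = nw, detrend = detrend,
                 log_floor = log_floor, log_output = log_output),
            class = "estimator_config")
}

# cache of DPSS taper matrices keyed by (n, nw, k); the eigen decomposition
# is cheap but is reused thousands of times in simulation studies
.taper_cache <- new.env(parent = emptyenv())

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computed as eigenvectors of the standard symmetric tridiagonal matrix
#' whose top eigenvectors are the DPSS sequences (Slepian's tridiagonal
#' formulation). Tapers are unit-energy (`sum(w^2) = 1`) and sign-fixed so
#' each taper has non-negative mean (even orders) or positive initial slope.
#'
#' @param n Window length in samples.
#' @param nw Time-bandwidth product.
#' @param k Number of tapers (k <= 2*nw - 1 for well-concentrated tapers).
#' @return An `n` x `k` matrix, one taper per column.
#' @export
dpss_tapers <- function(n, nw = 3, k = 5) {
  key <- paste(n, nw, k, sep = "_")
  hit <- .taper_cache[[key]]
  if (!is.null(hit)) return(hit)
  w <- nw / n
  t0 <- 0:(n - 1)
  diag_main <- ((n - 1 - 2 * t0) / 2)^2 * cos(2 * pi * w)
  diag_off <- (1:(n - 1)) * (n - (1:(n - 1))) / 2
  m <- matrix(0, n, n)
  m[cbind(1:n, 1:n)] <- diag_main
  m[cbind(1:(n - 1), 2:n)] <- diag_off
  m[cbind(2:n, 1:(n - 1))] <- diag_off
  eg <- eigen(m, symmetric = TRUE)
  tap <- eg$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    tap[, j] <- tap[, j] / sqrt(sum(tap[, j]^2))
    s <- sum(tap[, j])
    flip <- if (abs(s) > 1e-8) s < 0 else
      sum(tap[seq_len(min(5, n)), j]) < 0  # odd taper: fix initial sign
    if (flip) tap[, j] <- -tap[, j]
  }
  .taper_cache[[key]] <- tap
  tap
}

taper_matrix <- function(n, cfg) {
  if (cfg$taper == "hann") {
    w <- 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1)))
    matrix(w / sqrt(sum(w^2)), ncol = 1)
  } else {
    dpss_tapers(n, cfg$nw, cfg$n_tapers)
  }
}

#' Resample an IBI series to a uniform grid by cubic spline
#'
#' Interpolates interval value (ms) against beat time with a cubic spline
#' and evaluates it on the uniform grid `0, 1/hz, 2/hz, ...`. Grid points
#' outside the span of observed beats are not extrapolated: they are marked
#' invalid.
#'
#' @param ibi An [ibi_series()] spanning at least one window.
#' @param cfg An [estimator_config()].
#' @return A list with class `uniform_ibi`: `t` (grid times, s), `values`
#'   (ms, `NA` where invalid), `valid`, `hz`.
#' @export
resample_ibi <- function(ibi, cfg = estimator_config()) {
  stopifnot(inherits(ibi, "ibi_series"))
  if (length(ibi$beat_times) < 4) stop("need at least 4 beats")
  span <- ibi$beat_times[length(ibi$beat_times)] - ibi$beat_times[1]
  if (span < cfg$window_s)
    stop("task too short: beat span ", round(span, 1),
         " s is below one window (", cfg$window_s, " s)")
  hz <- cfg$resample_hz
  t_end <- ibi$beat_times[length(ibi$beat_times)]
  tg <- seq(0, floor(t_end * hz) / hz, by = 1 / hz)
  sf <- stats::splinefun(ibi$beat_times, ibi$intervals, method = "fmm")
  valid <- tg >= ibi$beat_times[1] & tg <= t_end
  vals <- rep(NA_real_, length(tg))
  vals[valid] <- sf(tg[valid])
  structure(list(t = tg, values = vals, valid = valid, hz = hz),
            class = "uniform_ibi")
}

#' Construct a per-second RSA series
#'
#' @param person_id Identifier.
#' @param values Per-second RSA values (ln(ms^2) by convention), `NA` where
#'   invalid.
#' @param valid Logical validity mask, same length.
#' @return An object of class `rsa_series` with `mean` and `sd` summaries
#'   over valid seconds.
#' @export
rsa_series <- function(person_id, values, valid = is.finite(values)) {
  stopifnot(length(values) == length(valid))
  values[!valid] <- NA_real_
  v <- values[valid]
  structure(list(person_id = person_id, values = values, valid = valid,
                 mean = if (length(v)) mean(v) else NA_real_,
                 sd = if (length(v) > 1) stats::sd(v) else NA_real_),
            class = "rsa_series")
}

#' @export
print.rsa_series <- function(x, ...) {
  cat(sprintf("<rsa_series %s: %d s (%d valid), mean %.2f sd %.2f>\n",
              x$person_id, length(x$values), sum(x$valid), x$mean, x$sd))
  invisible(x)
}

#' Estimate time-varying RSA by multitaper short-time band power
#'
#' For every second t with a full surrounding window
#' `[t - window_s/2, t + window_s/2)` of valid samples, the windowed
#' segment is demeaned (and linearly detrended by default), multiplied by
#' each taper, and the tapered periodograms are averaged into a power
#' spectral density. Band power is the PSD integrated over
#' `[band_lo, band_hi]` (one-sided), in ms^2; the RSA value for second t is
#' `ln(max(band power, log_floor))`. Seconds without a full valid window
#' are invalid (in particular the first and last `window_s/2` seconds).
#'
#' @param us A `uniform_ibi` from [resample_ibi()].
#' @param cfg An [estimator_config()].
#' @param person_id Identifier for the output series.
#' @return An [rsa_series()] with one value per whole task second.
#' @export
estimate_tv_rsa <- function(us, cfg = estimator_config(),
                            person_id = "person") {
  stopifnot(inherits(us, "uniform_ibi"))
  hz <- us$hz
  n_win <- as.integer(round(cfg$window_s * hz))
  half_s <- cfg$window_s / 2
  task_s <- floor(max(us$t)) + 1L
  n_samp <- length(us$values)

  secs <- 0:(task_s - 1L)
  start_idx <- as.integer(round((secs - half_s) * hz)) + 1L  # 1-based
  ok <- start_idx >= 1L & (start_idx + n_win - 1L) <= n_samp
  # windows containing any invalid sample are themselves invalid
  cs <- cumsum(c(0L, as.integer(us$valid)))
  ok[ok] <- (cs[start_idx[ok] + n_win] - cs[start_idx[ok]]) == n_win

  values <- rep(NA_real_, task_s)
  if (any(ok)) {
    idx <- outer(0:(n_win - 1L), start_idx[ok], `+`)
    X <- matrix(us$values[idx], nrow = n_win)
    # demean / detrend each column against [1, t]
    d <- cbind(1, seq_len(n_win))
    if (cfg$detrend) {
      X <- X - d %*% qr.coef(qr(d), X)
    } else {
      X <- sweep(X, 2, colMeans(X))
    }
    tap <- taper_matrix(n_win, cfg)
    psd <- 0
    for (j in seq_len(ncol(tap)))
      psd <- psd + Mod(stats::mvfft(X * tap[, j]))^2 / hz
    psd <- psd / ncol(tap)
    freqs <- (0:(n_win - 1)) * hz / n_win
    in_band <- freqs >= cfg$band_lo & freqs <= cfg$band_hi
    df <- hz / n_win
    bp <- 2 * df * colSums(psd[in_band, , drop = FALSE])  # one-sided, ms^2
    values[ok] <- if (cfg$log_output) log(pmax(bp, cfg$log_floor)) else bp
  }
  rsa_series(person_id, values, ok)
}

#' Remove within-person RSA outliers
#'
#' Marks invalid any second whose RSA value deviates from the person's mean
#' by `k` or more within-task standard deviations, then recomputes the mean
#' and SD on the survivors. The default reading of the cleaning rule is
#' two-sided; set `two_sided = FALSE` for removal of high values only.
#' A single pass is made (the rule is not iterated).
#'
#' @param rsa An [rsa_series()] with at least 2 valid seconds.
#' @param k SD multiplier (default 3).
#' @param two_sided Remove deviations in both directions (default `TRUE`).
#' @return A new [rsa_series()]; the input is not modified.
#' @export
remove_rsa_outliers <- function(rsa, k = 3, two_sided = TRUE) {
  stopifnot(inherits(rsa, "rsa_series"))
  if (sum(rsa$valid) < 2) stop("need >= 2 valid seconds")
  if (!is.finite(k)) return(rsa)
  dev <- rsa$values - rsa$mean
  out <- if (two_sided) abs(dev) >= k * rsa$sd else dev >= k * rsa$sd
  out[is.na(out)] <- FALSE
  valid <- rsa$valid & !out
  if (!any(valid)) stop("degenerate RSA series: all seconds removed")
  rsa_series(rsa$person_id, ifelse(valid, rsa$values, NA_real_), valid)
}

#' First-difference an RSA series
#'
#' `d(t) = value(t) - value(t - 1)`, defined only where both seconds are
#' valid; removes linear trends so that downstream synchrony reflects
#' reactive second-to-second changes rather than shared drift.
#'
#' @param rsa An [rsa_series()] with at least 2 valid seconds.
#' @return An [rsa_series()] of the same length holding the differences
#'   (second 0 and any second following a gap are invalid).
#' @export
first_difference <- function(rsa) {
  stopifnot(inherits(rsa, "rsa_series"))
  if (sum(rsa$valid) < 2) stop("need >= 2 valid seconds")
  n <- length(rsa$values)
  d <- c(NA_real_, diff(rsa$values))
  valid <- c(FALSE, rsa$valid[-1] & rsa$valid[-n])
  d[!valid] <- NA_real_
  rsa_series(rsa$person_id, d, valid)
}

#' Full per-person RSA pipeline
#'
#' Convenience wrapper: resample, estimate time-varying RSA, remove within
#' person outliers, first-difference.
#'
#' @inheritParams resample_ibi
#' @param outlier_sd SD multiplier for [remove_rsa_outliers()].
#' @return List with elements `rsa` (cleaned [rsa_series()]) and `diff`
#'   (its first difference).
#' @export
rsa_pipeline <- function(ibi, cfg = estimator_config(), outlier_sd = 3) {
  us <- resample_ibi(ibi, cfg)
  tv <- estimate_tv_rsa(us, cfg, person_id = ibi$person_id)
  cl <- remove_rsa_outliers(tv, k = outlier_sd)
  list(rsa = cl, diff = first_difference(cl))
}
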