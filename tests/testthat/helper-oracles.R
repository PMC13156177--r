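# Independent oracles and fixture builders. These deliberately avoid the
# package's estimation code paths: plain-fft periodogram, loop tallies,
# grid scans.

# whole-series periodogram band power (ms^2), linear-detrended
oracle_band_power <- function(x, fs, lo, hi) {
  n <- length(x)
  tt <- seq_len(n)
  x <- stats::residuals(stats::lm(x ~ tt))
  psd <- Mod(stats::fft(x))^2 / (fs * n)
  freqs <- (0:(n - 1)) * fs / n
  sel <- freqs >= lo & freqs <= hi
  2 * sum(psd[sel]) * fs / n
}

# deterministic beat emission for an analytically known modulated IBI;
# the interval value is the modulation evaluated exactly at the beat time
# (fixed-point solve), so (beat_time, interval) pairs lie on the analytic
# curve and spline output can be compared to it directly
make_sine_ibi <- function(f, A, base = 850, ts = 300, phase = 0,
                          id = "sine") {
  t <- 0; bt <- numeric(0); iv <- numeric(0)
  repeat {
    ibi <- base
    for (k in 1:8) ibi <- base + A * sin(2 * pi * f * (t + ibi / 1000) +
                                           phase)
    tn <- t + ibi / 1000
    if (tn > ts) break
    bt <- c(bt, tn); iv <- c(iv, ibi); t <- tn
  }
  ibi_series(id, beat_times = bt, intervals = iv)
}

# beats whose interval is exactly linear in the beat's own time
make_linear_ibi <- function(base = 700, slope = 2, ts = 300, id = "lin") {
  t <- 0; bt <- numeric(0); iv <- numeric(0)
  repeat {
    ibi <- base
    for (k in 1:8) ibi <- base + slope * (t + ibi / 1000)
    tn <- t + ibi / 1000
    if (tn > ts) break
    bt <- c(bt, tn); iv <- c(iv, ibi); t <- tn
  }
  ibi_series(id, beat_times = bt, intervals = iv)
}

# brute-force Cohen's kappa from two code vectors (loops, no factors)
oracle_kappa <- function(a, b) {
  keep <- a != "uncodable" & b != "uncodable"
  a <- a[keep]; b <- b[keep]
  lev <- unique(c(a, b))
  k <- length(lev)
  tab <- matrix(0, k, k, dimnames = list(lev, lev))
  for (i in seq_along(a)) tab[a[i], b[i]] <- tab[a[i], b[i]] + 1
  n <- sum(tab)
  p_o <- sum(diag(tab)) / n
  p_e <- 0
  for (i in seq_len(k)) p_e <- p_e + sum(tab[i, ]) * sum(tab[, i]) / n^2
  (p_o - p_e) / (1 - p_e)
}

# grid scan of |t(m)| for the Johnson-Neyman boundary
oracle_region_scan <- function(b_f, b_i, v_ff, v_fi, v_ii, crit, lo, hi,
                               step) {
  m <- seq(lo, hi, by = step)
  tval <- (b_f + m * b_i) / sqrt(v_ff + 2 * m * v_fi + m^2 * v_ii)
  sig <- abs(tval) > crit
  list(m = m, sig = sig)
}

# quick affect stream from explicit codes
astream <- function(codes, role = "parent", id = role)
  coded_stream(id, role = role, stream_kind = "affect", codes = codes)

estream <- function(codes, id = "parent")
  coded_stream(id, role = "parent", stream_kind = "ersb", codes = codes)

# rsa_series directly from values (all valid unless NA)
rser <- function(values, id = "p") rsa_series(id, values)
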