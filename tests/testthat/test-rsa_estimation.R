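# rsa_estimation: spline resampling, multitaper band power, cleaning,
# differencing

test_that("estimator_config enforces its schema naming the field", {
  expect_error(estimator_config(band_hi = 2.5), "band_hi")
  expect_error(estimator_config(band_lo = 0.5, band_hi = 0.3), "band_lo")
  expect_error(estimator_config(window_s = 10), "window_s")
  expect_s3_class(estimator_config(band_lo = 0.24, band_hi = 1.04),
                  "estimator_config")
})

test_that("resample_ibi is exact on constant and linear data", {
  cfg <- estimator_config()
  tt <- seq(0.8, 300, by = 0.8)
  s <- resample_ibi(ibi_series("c", beat_times = tt,
                               intervals = rep(800, length(tt))), cfg)
  expect_equal(unique(round(s$values[s$valid], 9)), 800)

  lin <- make_linear_ibi(base = 700, slope = 2)
  s2 <- resample_ibi(lin, cfg)
  truth_line <- function(t) 700 + 2 * t  # interval at its own beat time
  # data really are collinear
  expect_lt(max(abs(lin$intervals - truth_line(lin$beat_times))), 1e-9)
  ok <- s2$valid
  expect_lt(max(abs(s2$values[ok] - truth_line(s2$t[ok]))), 1e-6)

  expect_error(resample_ibi(ibi_series("s", intervals = rep(800, 20)),
                            cfg), "task too short")
})

test_that("resample_ibi tracks a sinusoidal modulation to < 0.5 ms RMSE", {
  cfg <- estimator_config()
  ib <- make_sine_ibi(f = 0.25, A = 40)
  s <- resample_ibi(ib, cfg)
  truth <- 850 + 40 * sin(2 * pi * 0.25 * s$t[s$valid])
  expect_lt(sqrt(mean((s$values[s$valid] - truth)^2)), 0.5)
})

test_that("time-varying band power matches the whole-series periodogram
           oracle and respects out-of-band bounds", {
  cfg <- estimator_config()
  ib <- make_sine_ibi(f = 0.25, A = 40)
  us <- resample_ibi(ib, cfg)
  rsa <- estimate_tv_rsa(us, cfg, "p")
  p_tv <- exp(rsa$values[rsa$valid])
  p_or <- oracle_band_power(us$values[us$valid], cfg$resample_hz,
                            cfg$band_lo, cfg$band_hi)
  expect_true(all(abs(p_tv / p_or - 1) < 0.10))

  # same-amplitude modulation below the band leaks <= 5%
  ib_lo <- make_sine_ibi(f = 0.05, A = 40)
  rsa_lo <- estimate_tv_rsa(resample_ibi(ib_lo, cfg), cfg, "p")
  expect_lt(mean(exp(rsa_lo$values[rsa_lo$valid])) / mean(p_tv), 0.05)

  # constant series bottoms out at the log floor
  tt <- seq(0.8, 300, by = 0.8)
  cs <- resample_ibi(ibi_series("c", beat_times = tt,
                                intervals = rep(800, length(tt))), cfg)
  rc <- estimate_tv_rsa(cs, cfg, "c")
  expect_equal(unique(rc$values[rc$valid]), log(cfg$log_floor))

  # edge invalidity: no value without a full surrounding window
  expect_false(any(rsa$valid[1:(cfg$window_s / 2)]))
  expect_equal(length(rsa$values), 300)
})

test_that("windows containing invalid samples are themselves invalid", {
  cfg <- estimator_config()
  us <- resample_ibi(make_sine_ibi(0.25, 30), cfg)
  us$valid[600:604] <- FALSE  # ~150 s into the task
  us$values[600:604] <- NA
  r <- estimate_tv_rsa(us, cfg, "p")
  gap_s <- floor((599:603) / cfg$resample_hz)  # 0-based seconds touched
  affected <- (min(gap_s) - cfg$window_s / 2 + 1):(max(gap_s) +
                                                     cfg$window_s / 2)
  expect_false(any(r$valid[affected + 1]))
  expect_true(r$valid[min(affected)])  # just outside the reach
})

test_that("adding a constant to all IBI values leaves RSA unchanged", {
  cfg <- estimator_config()
  ib <- make_sine_ibi(f = 0.25, A = 30)
  us1 <- resample_ibi(ib, cfg)
  us2 <- us1
  us2$values <- us2$values + 150
  r1 <- estimate_tv_rsa(us1, cfg, "p")
  r2 <- estimate_tv_rsa(us2, cfg, "p")
  expect_equal(r1$values, r2$values, tolerance = 1e-9)
})

test_that("band power scales ~4x when modulation amplitude doubles", {
  cfg <- estimator_config()
  p1 <- exp(estimate_tv_rsa(resample_ibi(make_sine_ibi(0.25, 20), cfg),
                            cfg)$values)
  p2 <- exp(estimate_tv_rsa(resample_ibi(make_sine_ibi(0.25, 40), cfg),
                            cfg)$values)
  ratio <- mean(p2, na.rm = TRUE) / mean(p1, na.rm = TRUE)
  expect_lt(abs(ratio / 4 - 1), 0.15)
})

test_that("remove_rsa_outliers applies the +-k SD rule", {
  r <- rser(c(0, 0, 0, 0, 10))
  # sd ~ 4.47: |10 - 2| = 8 < 3 sd, nothing removed
  expect_equal(remove_rsa_outliers(r, k = 3)$valid, rep(TRUE, 5))

  set.seed(311)
  vals <- rnorm(300, 6, 0.2)
  vals[151] <- 6 + 5 * 0.2  # plant a clear deviant
  r2 <- remove_rsa_outliers(rser(vals), k = 3)
  # brute-force re-implementation of the rule over the mask
  m <- mean(vals); s <- sd(vals)
  expect_identical(r2$valid, !(abs(vals - m) >= 3 * s))
  expect_false(r2$valid[151])
  # survivors' summary recomputed
  expect_equal(r2$mean, mean(vals[r2$valid]))

  expect_identical(remove_rsa_outliers(rser(vals), k = Inf)$valid,
                   rep(TRUE, 300))
  expect_error(remove_rsa_outliers(rser(c(5, 5)), k = 0), "degenerate")
})

test_that("first_difference propagates the validity mask", {
  d <- first_difference(rser(c(5, 6, 6.5)))
  expect_equal(d$values, c(NA, 1, 0.5))
  expect_equal(d$valid, c(FALSE, TRUE, TRUE))

  v <- rnorm(30)
  base <- first_difference(rser(v))$values
  trended <- first_difference(rser(v + 0.3 * seq_along(v)))$values
  expect_equal(trended - base, rep(c(NA, 0.3), c(1, 29)))

  gap <- c(rnorm(10), NA, rnorm(9))  # second index 10 (0-based) invalid
  dg <- first_difference(rser(gap))
  expect_false(dg$valid[11])  # d(10): value(10) missing
  expect_false(dg$valid[12])  # d(11): value(10) missing
  expect_true(dg$valid[10])
})

test_that("dpss tapers are orthonormal and well-concentrated", {
  tap <- dpss_tapers(128, 2, 3)
  gram <- crossprod(tap)
  expect_equal(gram, diag(3), tolerance = 1e-8)
  # leading taper concentrates energy in |f| <= nw/n
  h <- Mod(fft(c(tap[, 1], rep(0, 1024 - 128))))^2
  f <- (0:1023) / 1024
  inside <- sum(h[f <= 2 / 128 | f >= 1 - 2 / 128])
  expect_gt(inside / sum(h), 0.999)
})
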