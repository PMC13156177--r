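# synthetic_data: determinism, planted structure, marginal targets

test_that("same seed reproduces the study byte-for-byte; seeds differ", {
  s1 <- simulate_study(sim_config(n_dyads = 6, seed = 42))
  s2 <- simulate_study(sim_config(n_dyads = 6, seed = 42))
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$dyads[[1]]$parent_ibi$intervals,
                   s2$dyads[[1]]$parent_ibi$intervals)
  s3 <- simulate_study(sim_config(n_dyads = 6, seed = 43))
  expect_false(identical(s1$truth$z_true, s3$truth$z_true))
})

test_that("generated series satisfy the io invariants", {
  set.seed(351)
  g <- gen_ibi_dyad(sim_config(), "d")
  for (s in list(g$parent, g$child)) {
    expect_true(all(s$intervals > 0))
    expect_true(all(diff(s$beat_times) > 0))
    expect_lt(max(abs(diff(s$beat_times) * 1000 - s$intervals[-1])), 1e-6)
  }
  a <- gen_affect_dyad(sim_config(), "d")
  expect_true(all(a$parent$codes %in% affect_codes))
  e <- gen_ersb_stream(sim_config(), "d")
  expect_true(all(e$stream$codes %in% ersb_codes))
})

test_that("null envelope coupling yields pipeline synchrony centered at 0", {
  set.seed(352)
  cfg <- sim_config(rho = 0)
  cfgp <- estimator_config()
  cfgc <- estimator_config(band_lo = 0.24, band_hi = 1.04)
  n <- 60
  z <- numeric(n)
  for (i in seq_len(n)) {
    g <- gen_ibi_dyad(cfg, "d")
    z[i] <- rsa_synchrony(rsa_pipeline(g$parent, cfgp)$diff,
                          rsa_pipeline(g$child, cfgc)$diff)$z
  }
  expect_lt(abs(mean(z, na.rm = TRUE)), 3 * sd(z, na.rm = TRUE) / sqrt(n))
})

test_that("doubling the envelope level raises mean RSA by ~ 2 ln 2", {
  set.seed(353)
  cfg1 <- sim_config()
  cfg2 <- sim_config(ibi = list(envelope = list(mean_log = log(70))))
  m <- function(cfg, n = 12) {
    v <- numeric(n)
    for (i in seq_len(n)) {
      g <- gen_ibi_dyad(cfg, "d")
      v[i] <- rsa_pipeline(g$parent, estimator_config())$rsa$mean
    }
    mean(v)
  }
  shift <- m(cfg2) - m(cfg1)
  expect_lt(abs(shift / (2 * log(2)) - 1), 0.15)
})

test_that("independent affect chains co-occur at the product of marginals", {
  set.seed(354)
  cfg <- sim_config(affect = list(boost = 1, uncodable_rate = 0))
  n <- 300
  pos_p <- pos_c <- shared <- 0
  secs <- 0
  for (i in seq_len(n)) {
    g <- gen_affect_dyad(cfg, "d")
    pp <- g$parent$codes == "positive_warm"
    cc <- g$child$codes == "positive_warm"
    pos_p <- pos_p + sum(pp); pos_c <- pos_c + sum(cc)
    shared <- shared + sum(pp & cc)
    secs <- secs + length(pp)
  }
  expected <- (pos_p / secs) * (pos_c / secs)
  observed <- shared / secs
  # persistence inflates co-occurrence variance; compare at loose MC scale
  expect_lt(abs(observed - expected), 5 * sqrt(expected / secs) + 0.002)
})

test_that("calibrated boost lands the any-shared-positive rate near 54.5%", {
  set.seed(355)
  n <- 400
  any_v <- replicate(n, gen_affect_dyad(sim_config(), "d")$truth$shared_any)
  expect_lt(abs(mean(any_v) - 0.545), 0.05)
})

test_that("heavy uncodable injection makes affect synchrony missing", {
  set.seed(356)
  cfg <- sim_config()
  miss <- replicate(50, {
    g <- gen_affect_dyad(cfg, "d", uncodable_rate = 0.55)
    shared_positive(g$parent, g$child)$missing
  })
  expect_gte(mean(miss), 0.9)
})

test_that("outcome generator is identifiable: noiseless coefficients are
           recovered exactly and nulls stay within 2 SE", {
  set.seed(357)
  n <- 400
  summ <- data.frame(dyad_id = sprintf("d%03d", 1:n),
                     affect_sync_any = rbinom(n, 1, 0.545),
                     rsa_sync_z = rnorm(n, 0.02, 0.21),
                     ersb_any = rbinom(n, 1, 0.425))
  # affect-side interactions zeroed so the fitted model spans the
  # generating one exactly
  cfg0 <- sim_config(outcome = list(residual_sd = 0, coef = c(
    intercept = 56.8, parent_dep = 0.18, ersb_any = 1.22,
    affect_sync = -2.83, rsa_sync = -8.03, affect_x_ersb = 0,
    affect_x_pdep = 0, rsa_x_pdep = -2.37, rsa_x_ersb = 5.73,
    medication = 0, pubertal = 0, pandemic = 0)))
  tab <- gen_outcome_table(cfg0, summ)
  d <- cbind(tab, summ[-1])
  d$pdep_c <- d$parent_dep_T - 55.54  # generator's centering
  f <- suppressWarnings(  # lm flags the (intended) perfect fit
    fit_interaction_model(d, "child_dep_T", "rsa_sync_z",
                          c("pdep_c", "ersb_any"),
                          covariates = "affect_sync_any",
                          center = FALSE))
  expect_equal(unname(f$coef["rsa_sync_z:pdep_c"]), -2.37,
               tolerance = 1e-8)
  expect_equal(unname(f$coef["pdep_c"]), 0.18, tolerance = 1e-8)

  # all-zero coefficients: estimates stay within 2 SE of zero
  set.seed(358)
  zero <- sim_config(outcome = list(coef = c(
    intercept = 57, parent_dep = 0, ersb_any = 0, affect_sync = 0,
    rsa_sync = 0, affect_x_ersb = 0, affect_x_pdep = 0, rsa_x_pdep = 0,
    rsa_x_ersb = 0, medication = 0, pubertal = 0, pandemic = 0)))
  ok <- replicate(40, {
    tab <- gen_outcome_table(zero, summ)
    d <- cbind(tab, summ[-1])
    f <- fit_interaction_model(d, "child_dep_T", "rsa_sync_z",
                               c("parent_dep_T", "ersb_any"))
    int <- "rsa_sync_z:parent_dep_T"
    abs(f$coef[int]) < 2 * sqrt(f$vcov[int, int])
  })
  expect_gte(mean(ok), 0.85)
})

test_that("planted interaction of -2.37 is recovered within 2 SE at n=400", {
  set.seed(359)
  n <- 400
  summ <- data.frame(dyad_id = sprintf("d%03d", 1:n),
                     affect_sync_any = rbinom(n, 1, 0.545),
                     rsa_sync_z = rnorm(n, 0.02, 0.21),
                     ersb_any = rbinom(n, 1, 0.425))
  tab <- gen_outcome_table(sim_config(), summ)
  d <- cbind(tab, summ[-1])
  f <- fit_interaction_model(d, "child_dep_T", "rsa_sync_z",
                             c("parent_dep_T", "ersb_any"))
  int <- "rsa_sync_z:parent_dep_T"
  expect_lt(abs(f$coef[int] - (-2.37)), 2 * sqrt(f$vcov[int, int]))
})
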