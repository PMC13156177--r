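# moderation_analysis: interaction fits, simple slopes, J-N regions

sim_moderation_data <- function(n, b_int = -2.37, sd_resid = 5,
                                b_focal = -8, b_mod = 0.2) {
  pdep <- rnorm(n, 55.5, 7.6)
  sync <- rnorm(n, 0.02, 0.21)
  ersb <- rbinom(n, 1, 0.4)
  pdep_c <- pdep - mean(pdep)
  y <- 57 + b_focal * sync + b_mod * pdep_c + 1.2 * ersb +
    b_int * sync * pdep_c + rnorm(n, 0, sd_resid)
  data.frame(child_dep_T = y, rsa_sync_z = sync, parent_dep_T = pdep,
             ersb_any = ersb)
}

test_that("fit_interaction_model recovers planted coefficients at n=400", {
  set.seed(341)
  d <- sim_moderation_data(400)
  f <- fit_interaction_model(d, "child_dep_T", "rsa_sync_z",
                             c("parent_dep_T", "ersb_any"))
  int <- "rsa_sync_z:parent_dep_T"
  se <- sqrt(diag(f$vcov))
  expect_lt(abs(f$coef[int] - (-2.37)), 2 * se[int])
  expect_lt(abs(f$coef["rsa_sync_z"] - (-8)), 2 * se["rsa_sync_z"])
  expect_equal(f$n_used, 400)
  # centered continuous predictors have mean ~ 0 on the analysis sample
  expect_true(all(c("rsa_sync_z", "parent_dep_T") %in%
                    names(f$centering)))
  expect_equal(f$term_stats$parent_dep_T$mean, 0, tolerance = 1e-10)
})

test_that("rank deficiency and degenerate inputs raise named errors", {
  set.seed(342)
  d <- sim_moderation_data(50)
  d$zero_mod <- 1  # zero variance
  expect_error(fit_interaction_model(d, "child_dep_T", "rsa_sync_z",
                                     "zero_mod"),
               "collinear|rank")
  expect_error(fit_interaction_model(d[1:5, ], "child_dep_T",
                                     "rsa_sync_z", "parent_dep_T"),
               "complete cases")
})

test_that("logistic null fits keep coefficients within 2 SE almost always", {
  set.seed(343)
  reps <- 60
  ok <- replicate(reps, {
    n <- 120
    pdep <- rnorm(n, 55.5, 7.6)
    y <- rbinom(n, 1, 0.5)  # planted log-odds 0 for parent depression
    d <- data.frame(sync_any = y, parent_dep_T = pdep,
                    ersb_any = rbinom(n, 1, 0.4))
    f <- fit_interaction_model(d, "sync_any", "parent_dep_T", "ersb_any",
                               family = "logistic")
    se <- sqrt(f$vcov["parent_dep_T", "parent_dep_T"])
    abs(f$coef["parent_dep_T"]) < 2 * se
  })
  expect_gte(mean(ok), 0.85)  # nominal ~0.95
})

test_that("simple_slope reproduces the conditional-effect algebra", {
  fit <- moderation_fit(
    coef = c(ersb_any = -3.00, affect_sync = -2.83,
             "ersb_any:affect_sync" = 8.45),
    focal = "ersb_any", moderators = "affect_sync")
  expect_equal(simple_slope(fit, 1)$slope_est, 5.45)
  expect_equal(simple_slope(fit, 0)$slope_est, -3.00)
  # probing from the other side of the interaction
  expect_equal(simple_slope(fit, 1, focal = "affect_sync")$slope_est, 5.62)

  rsa_fit <- moderation_fit(
    coef = c(parent_dep = 0.18, rsa_sync = -8.03,
             "parent_dep:rsa_sync" = -2.37),
    focal = "parent_dep", moderators = "rsa_sync")
  expect_equal(round(simple_slope(rsa_fit, -0.21)$slope_est, 2), 0.68)
  expect_equal(round(simple_slope(rsa_fit, +0.21)$slope_est, 2), -0.32)

  # b_int = 0: slope constant in the moderator
  flat <- moderation_fit(coef = c(x = 1.5, m = 2, "x:m" = 0),
                         focal = "x", moderators = "m")
  expect_equal(simple_slope(flat, -3)$slope_est,
               simple_slope(flat, 7)$slope_est)
  expect_error(simple_slope(flat, Inf), "finite")
})

test_that("recoding a binary moderator satisfies b(1) = b(0) + b_int", {
  set.seed(344)
  d <- sim_moderation_data(150)
  f1 <- fit_interaction_model(d, "child_dep_T", "rsa_sync_z", "ersb_any",
                              covariates = "parent_dep_T")
  d2 <- d; d2$ersb_any <- 1 - d2$ersb_any
  f2 <- fit_interaction_model(d2, "child_dep_T", "rsa_sync_z", "ersb_any",
                              covariates = "parent_dep_T")
  b1 <- simple_slope(f1, 1)$slope_est
  b0_recoded <- simple_slope(f2, 0)$slope_est
  expect_equal(b1, b0_recoded, tolerance = 1e-10)
  expect_equal(simple_slope(f1, 0)$slope_est +
                 f1$coef[["rsa_sync_z:ersb_any"]],
               simple_slope(f1, 1)$slope_est, tolerance = 1e-10)
})

test_that("region_of_significance matches a brute-force grid scan", {
  set.seed(345)
  for (rep in 1:25) {
    d <- sim_moderation_data(60, b_int = runif(1, -4, 4),
                             sd_resid = runif(1, 2, 8),
                             b_focal = runif(1, -10, 10),
                             b_mod = runif(1, -0.5, 0.5))
    f <- fit_interaction_model(d, "child_dep_T", "rsa_sync_z",
                               "parent_dep_T")
    reg <- region_of_significance(f, moderator = "parent_dep_T")
    st <- f$term_stats$parent_dep_T
    step <- 1e-4 * st$sd
    scan <- oracle_region_scan(
      f$coef[["rsa_sync_z"]], f$coef[["rsa_sync_z:parent_dep_T"]],
      f$vcov["rsa_sync_z", "rsa_sync_z"],
      f$vcov["rsa_sync_z", "rsa_sync_z:parent_dep_T"],
      f$vcov["rsa_sync_z:parent_dep_T", "rsa_sync_z:parent_dep_T"],
      reg$crit, reg$range[1], reg$range[2], step)
    inside <- vapply(scan$m, function(m)
      any(vapply(reg$region_bounds, function(b)
        m >= b[1] - step / 2 && m <= b[2] + step / 2, TRUE)), TRUE)
    # boundary discrepancy below 1e-3 SD units: disagreements only within
    # a grid step of a boundary
    mismatch <- scan$m[inside != scan$sig]
    if (length(mismatch)) {
      near_root <- vapply(mismatch, function(m)
        any(abs(m - reg$roots) < 1e-3 * st$sd), TRUE)
      expect_true(all(near_root))
    } else succeed()
  }
})

test_that("an empty significance region is a valid result", {
  v <- diag(c(4, 1, 4)) # huge uncertainty: nothing significant anywhere
  dimnames(v) <- rep(list(c("x", "m", "x:m")), 2)
  f <- moderation_fit(coef = c(x = 0.1, m = 0, "x:m" = 0.05), vcov = v,
                      focal = "x", moderators = "m", df_residual = 40)
  reg <- region_of_significance(f, moderator_mean = 0, moderator_sd = 1)
  expect_length(reg$region_bounds, 0)
})

test_that("region topology: zero interaction and the buffering pattern", {
  # b_int = 0 with a significant focal effect: whole range significant
  v <- diag(c(0.25, 0.3, 0.01)) * 0.01
  dimnames(v) <- rep(list(c("x", "m", "x:m")), 2)
  f0 <- moderation_fit(coef = c(x = 2, m = 0.5, "x:m" = 0), vcov = v,
                       focal = "x", moderators = "m", df_residual = 50)
  reg0 <- region_of_significance(f0, moderator_mean = 0, moderator_sd = 1)
  expect_length(reg0$region_bounds, 1)
  expect_equal(reg0$region_bounds[[1]], reg0$range)

  # positive slope at low moderator, negative interaction: the significant
  # region sits at or below a finite boundary
  set.seed(346)
  n <- 300
  m <- rnorm(n, 0, 0.21)
  x <- rnorm(n, 55, 7.6)
  y <- 57 + 0.18 * (x - 55) - 2.37 * m * (x - 55) - 8 * m + rnorm(n, 0, 4)
  d <- data.frame(y = y, x = x, m = m)
  f <- fit_interaction_model(d, "y", "x", "m")
  reg <- region_of_significance(f, moderator = "m")
  expect_gte(length(reg$region_bounds), 1)
  lowest <- reg$region_bounds[[1]]
  expect_equal(lowest[1], reg$range[1])      # extends to the low edge
  expect_lt(lowest[2], reg$range[2])         # finite upper boundary
  # slope is positive below the boundary
  expect_gt(simple_slope(f, lowest[1], moderator = "m")$slope_est, 0)
})
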