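# Interaction (moderation) models of child symptom T-scores, with simple
# slope probing and Johnson-Neyman regions of significance.

interaction_name <- function(coef_names, a, b) {
  cand <- c(paste(a, b, sep = ":"), paste(b, a, sep = ":"))
  hit <- cand[cand %in% coef_names]
  if (!length(hit))
    stop("no interaction term between '", a, "' and '", b, "' in fit")
  hit[1]
}

#' Construct a moderation fit
#'
#' Container for the coefficients (and optionally their covariance) of an
#' interaction model, supporting [simple_slope()] and
#' [region_of_significance()]. Normally produced by
#' [fit_interaction_model()], but can be built directly from published
#' coefficient sets for worked-example probing (then `vcov` may be `NULL`
#' and probes carry no standard errors).
#'
#' @param coef Named numeric vector of estimates; interaction terms named
#'   `"a:b"`.
#' @param vcov Covariance matrix with identical dimnames, or `NULL`.
#' @param focal Name of the focal predictor.
#' @param moderators Character vector of moderator names (each interacting
#'   with `focal`).
#' @param family `"linear"` or `"logistic"`.
#' @param df_residual Residual df for t-based inference (`Inf` gives normal
#'   reference, as for logistic fits).
#' @param n_used Complete cases used.
#' @param centering Named numeric vector of grand means subtracted from
#'   continuous predictors (empty if none).
#' @param term_stats Named list: per-predictor `list(mean, sd)` on the
#'   analysis sample, on the model (centered) scale; used for +-1 SD
#'   probing and region clipping.
#' @param outcome_name Outcome column name.
#' @return An object of class `moderation_fit`.
#' @export
moderation_fit <- function(coef, vcov = NULL, focal, moderators,
                           family = c("linear", "logistic"),
                           df_residual = Inf, n_used = NA_integer_,
                           centering = numeric(), term_stats = list(),
                           outcome_name = "outcome") {
  family <- match.arg(family)
  stopifnot(!is.null(names(coef)))
  if (!is.null(vcov)) {
    stopifnot(is.matrix(vcov), nrow(vcov) == ncol(vcov))
    if (!identical(rownames(vcov), names(coef)))
      stop("vcov dimnames must match coef names")
    ev <- eigen(vcov, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8 * max(abs(ev)))
      stop("vcov is not positive semi-definite")
  }
  for (m in moderators) interaction_name(names(coef), focal, m)
  structure(list(coef = coef, vcov = vcov, focal = focal,
                 moderators = moderators, family = family,
                 df_residual = df_residual, n_used = n_used,
                 centering = centering, term_stats = term_stats,
                 outcome_name = outcome_name),
            class = "moderation_fit")
}

#' @export
print.moderation_fit <- function(x, ...) {
  cat(sprintf("<moderation_fit %s ~ %s x (%s), %s, n=%s>\n",
              x$outcome_name, x$focal, paste(x$moderators, collapse = ", "),
              x$family, x$n_used))
  print(round(x$coef, 4))
  invisible(x)
}

is_binary_col <- function(v) {
  u <- unique(v[!is.na(v)])
  length(u) <= 2 && all(u %in% c(0, 1))
}

#' Fit an interaction model by maximum likelihood
#'
#' Fits `outcome ~ focal * moderator(s) + covariates` by least squares
#' (linear family) or logistic regression, on complete cases, with
#' continuous predictors grand-mean-centered on the analysis sample
#' (binary 0/1 predictors are left as is, so conditional effects are
#' evaluated at their observed levels).
#'
#' @param data data.frame of dyad-level variables.
#' @param outcome Outcome column (numeric, or 0/1 for logistic).
#' @param focal Focal predictor column.
#' @param moderator Moderator column name, or a character vector: each
#'   moderator gets a `focal x moderator` interaction term.
#' @param covariates Additional main-effect columns.
#' @param family `"linear"` or `"logistic"`.
#' @param center Grand-mean-center continuous predictors (default `TRUE`).
#' @param min_n Minimum complete cases (default 10).
#' @return A [moderation_fit()].
#' @export
fit_interaction_model <- function(data, outcome, focal, moderator,
                                  covariates = character(),
                                  family = c("linear", "logistic"),
                                  center = TRUE, min_n = 10) {
  family <- match.arg(family)
  vars <- c(outcome, focal, moderator, covariates)
  miss <- setdiff(vars, names(data))
  if (length(miss)) stop("columns not in data: ", paste(miss, collapse = ", "))
  d <- data[stats::complete.cases(data[vars]), vars, drop = FALSE]
  n <- nrow(d)
  if (n < min_n)
    stop("only ", n, " complete cases (need >= ", min_n, ")")

  preds <- c(focal, moderator, covariates)
  centering <- numeric()
  for (p in preds) {
    if (!is.numeric(d[[p]])) stop("predictor '", p, "' must be numeric")
    if (center && !is_binary_col(d[[p]])) {
      centering[p] <- mean(d[[p]])
      d[[p]] <- d[[p]] - centering[p]
    }
  }
  if (family == "logistic" && !is_binary_col(d[[outcome]]))
    stop("logistic family requires a 0/1 outcome")

  rhs <- paste(c(preds, paste(focal, moderator, sep = ":")), collapse = " + ")
  fml <- stats::as.formula(paste(outcome, "~", rhs))
  fit <- if (family == "linear") stats::lm(fml, data = d)
         else stats::glm(fml, data = d, family = stats::binomial())
  cf <- stats::coef(fit)
  if (anyNA(cf))
    stop("rank-deficient model; collinear column(s): ",
         paste(names(cf)[is.na(cf)], collapse = ", "))
  term_stats <- lapply(d[preds], function(v) list(mean = mean(v),
                                                  sd = stats::sd(v)))
  moderation_fit(
    coef = cf, vcov = stats::vcov(fit), focal = focal,
    moderators = moderator, family = family,
    df_residual = if (family == "linear") stats::df.residual(fit) else Inf,
    n_used = n, centering = centering, term_stats = term_stats,
    outcome_name = outcome)
}

#' Simple slope (conditional effect) of a focal predictor
#'
#' The conditional effect of `focal` when `moderator` is held at
#' `at_value`: `slope = b_focal + at_value * b_interaction`, an exact
#' algebraic identity on the fitted coefficients. With a covariance matrix
#' available, `se = sqrt(v_ff + at^2 * v_ii + 2 * at * v_fi)` and the slope
#' is tested against a t (linear) or normal (logistic) reference.
#'
#' @param fit A [moderation_fit()].
#' @param at_value Moderator value (on the model scale, i.e. centered if
#'   the fit centered it). Finite.
#' @param focal Predictor whose conditional effect is probed; defaults to
#'   the fit's focal term. May also be one of the moderators (probing the
#'   interaction from the other side).
#' @param moderator The conditioning variable; defaults to the fit's first
#'   moderator (or to the fit's focal term when `focal` is a moderator).
#' @return A list with class `probe_result`: `focal`, `moderator`,
#'   `at_value`, `slope_est`, `slope_se`, `statistic`, `p`.
#' @export
simple_slope <- function(fit, at_value, focal = NULL, moderator = NULL) {
  stopifnot(inherits(fit, "moderation_fit"))
  if (!is.finite(at_value)) stop("at_value must be finite")
  if (is.null(focal)) focal <- fit$focal
  if (is.null(moderator))
    moderator <- if (focal %in% fit$moderators) fit$focal
                 else fit$moderators[1]
  if (!focal %in% names(fit$coef)) stop("no coefficient for '", focal, "'")
  int <- interaction_name(names(fit$coef), focal, moderator)
  slope <- unname(fit$coef[focal] + at_value * fit$coef[int])
  se <- stat <- p <- NA_real_
  if (!is.null(fit$vcov)) {
    v <- fit$vcov
    se <- sqrt(v[focal, focal] + at_value^2 * v[int, int] +
                 2 * at_value * v[focal, int])
    stat <- slope / se
    p <- if (is.finite(fit$df_residual))
      2 * stats::pt(-abs(stat), fit$df_residual)
    else 2 * stats::pnorm(-abs(stat))
  }
  structure(list(focal = focal, moderator = moderator, at_value = at_value,
                 slope_est = slope, slope_se = se, statistic = stat, p = p),
            class = "probe_result")
}

#' @export
print.probe_result <- function(x, ...) {
  cat(sprintf("<probe: %s at %s = %.4g: Est = %.4g, SE = %.4g, p = %.3g>\n",
              x$focal, x$moderator, x$at_value, x$slope_est, x$slope_se,
              x$p))
  if (!is.null(x$region_bounds)) {
    if (length(x$region_bounds))
      cat("  significant for moderator in",
          paste(vapply(x$region_bounds, function(b)
            sprintf("[%.4g, %.4g]", b[1], b[2]), ""), collapse = " U "),
          "\n")
    else cat("  no significant region within the probed range\n")
  }
  invisible(x)
}

#' Johnson-Neyman region of significance for a continuous moderator
#'
#' Solves `|slope(m)| / se(m) = critical value` -- a quadratic in the
#' moderator value m -- and reports the sub-interval(s) of
#' `mean +- range_sd * SD` of the moderator in which the conditional effect
#' of `focal` differs significantly from zero. An empty region is a valid
#' result.
#'
#' @param fit A [moderation_fit()] with a covariance matrix.
#' @param alpha Two-sided significance level (default 0.05).
#' @param range_sd Interpretation range half-width in moderator SDs
#'   (default 2).
#' @param focal,moderator As in [simple_slope()].
#' @param moderator_mean,moderator_sd Mean and SD of the moderator on the
#'   model scale; default to the fit's stored analysis-sample statistics.
#' @return A `probe_result` evaluated at the moderator mean, with extra
#'   fields `region_bounds` (list of `c(lo, hi)` intervals where the slope
#'   is significant, clipped to the probed range), `roots` (real boundary
#'   solutions), `crit` (critical value) and `range` (probed interval).
#' @export
region_of_significance <- function(fit, alpha = 0.05, range_sd = 2,
                                   focal = NULL, moderator = NULL,
                                   moderator_mean = NULL,
                                   moderator_sd = NULL) {
  stopifnot(inherits(fit, "moderation_fit"))
  if (is.null(fit$vcov)) stop("region of significance requires vcov")
  if (is.null(focal)) focal <- fit$focal
  if (is.null(moderator))
    moderator <- if (focal %in% fit$moderators) fit$focal
                 else fit$moderators[1]
  if (is.null(moderator_mean))
    moderator_mean <- fit$term_stats[[moderator]]$mean
  if (is.null(moderator_sd))
    moderator_sd <- fit$term_stats[[moderator]]$sd
  if (is.null(moderator_mean) || is.null(moderator_sd) ||
      !is.finite(moderator_sd))
    stop("moderator mean/sd unavailable; supply moderator_mean/moderator_sd")

  int <- interaction_name(names(fit$coef), focal, moderator)
  b_f <- fit$coef[[focal]]; b_i <- fit$coef[[int]]
  v <- fit$vcov
  v_ff <- v[focal, focal]; v_ii <- v[int, int]; v_fi <- v[focal, int]
  crit <- if (is.finite(fit$df_residual))
    stats::qt(1 - alpha / 2, fit$df_residual) else stats::qnorm(1 - alpha / 2)

  # g(m) = slope(m)^2 - crit^2 * se(m)^2 > 0  <=>  significant
  A <- b_i^2 - crit^2 * v_ii
  B <- 2 * (b_f * b_i - crit^2 * v_fi)
  C <- b_f^2 - crit^2 * v_ff
  g <- function(m) (b_f + m * b_i)^2 - crit^2 * (v_ff + 2 * m * v_fi +
                                                   m^2 * v_ii)
  roots <- numeric()
  if (abs(A) > .Machine$double.eps * max(abs(B), abs(C), 1)) {
    disc <- B^2 - 4 * A * C
    if (disc >= 0) roots <- sort((-B + c(-1, 1) * sqrt(disc)) / (2 * A))
  } else if (abs(B) > 0) {
    roots <- -C / B
  }
  lo <- moderator_mean - range_sd * moderator_sd
  hi <- moderator_mean + range_sd * moderator_sd
  pts <- sort(unique(c(lo, roots[roots > lo & roots < hi], hi)))
  bounds <- list()
  for (i in seq_len(length(pts) - 1)) {
    mid <- (pts[i] + pts[i + 1]) / 2
    if (g(mid) > 0) {
      # merge adjacent significant panels (root tangent to zero)
      if (length(bounds) && abs(bounds[[length(bounds)]][2] - pts[i]) < 1e-12)
        bounds[[length(bounds)]][2] <- pts[i + 1]
      else bounds[[length(bounds) + 1]] <- c(pts[i], pts[i + 1])
    }
  }
  res <- simple_slope(fit, moderator_mean, focal = focal,
                      moderator = moderator)
  res$region_bounds <- bounds
  res$roots <- roots
  res$crit <- crit
  res$range <- c(lo, hi)
  res
}
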