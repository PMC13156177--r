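# Dyadic RSA synchrony: lag-0 Pearson correlation of paired first
# differenced per-second RSA, Fisher transformed.

#' Fisher z transform of a correlation
#'
#' `z = atanh(r) = 0.5 * ln((1 + r) / (1 - r))`, the variance-stabilizing
#' transform that makes correlation estimates suitable for linear modelling.
#'
#' @param r Correlation(s), `|r| < 1`.
#' @return z value(s).
#' @export
fisher_z <- function(r) {
  if (any(!is.na(r) & abs(r) >= 1))
    stop("fisher_z requires |r| < 1")
  atanh(r)
}

#' Dyadic RSA synchrony from differenced series
#'
#' Pearson correlation over seconds where both the child value at t and the
#' parent value at t + `lag_s` are valid, Fisher transformed. The estimate
#' is missing (with a reason) when overlap falls below `min_overlap`, when
#' either series is constant over the overlap, or when r is exactly +-1
#' (an infinite z cannot be carried into regression).
#'
#' @param parent_diff,child_diff Differenced [rsa_series()] on the same
#'   task clock (see [first_difference()]).
#' @param dyad_id Identifier for the output.
#' @param lag_s Integer lag in seconds applied to the parent series
#'   (0 for concurrent synchrony, the primary definition).
#' @param min_overlap Minimum jointly valid seconds (default 30, bounding
#'   the correlation SE below about 0.19).
#' @return An object of class `synchrony_estimate`: `dyad_id`, `r`, `z`,
#'   `n_pairs`, `lag_s`, `reason` (`NA` when estimable).
#' @export
rsa_synchrony <- function(parent_diff, child_diff, dyad_id = "dyad",
                          lag_s = 0, min_overlap = 30) {
  stopifnot(inherits(parent_diff, "rsa_series"),
            inherits(child_diff, "rsa_series"))
  lag_s <- as.integer(lag_s)
  n <- min(length(child_diff$values), length(parent_diff$values) - lag_s)
  t_child <- seq_len(n)
  t_parent <- t_child + lag_s
  keep <- t_parent >= 1 & t_parent <= length(parent_diff$values)
  t_child <- t_child[keep]; t_parent <- t_parent[keep]
  ok <- child_diff$valid[t_child] & parent_diff$valid[t_parent]
  x <- child_diff$values[t_child][ok]
  y <- parent_diff$values[t_parent][ok]
  est <- function(r, z, reason) {
    structure(list(dyad_id = dyad_id, r = r, z = z, n_pairs = length(x),
                   lag_s = lag_s, reason = reason),
              class = "synchrony_estimate")
  }
  if (length(x) < min_overlap)
    return(est(NA_real_, NA_real_,
               sprintf("insufficient overlap (%d < %d)", length(x),
                       min_overlap)))
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(est(NA_real_, NA_real_, "constant reactivity"))
  r <- stats::cor(x, y)
  if (abs(r) >= 1)
    return(est(r, NA_real_, sprintf("degenerate r=%+d", as.integer(sign(r)))))
  est(r, fisher_z(r), NA_character_)
}

#' @export
print.synchrony_estimate <- function(x, ...) {
  if (is.na(x$z))
    cat(sprintf("<synchrony %s: missing (%s), n_pairs=%d>\n",
                x$dyad_id, x$reason, x$n_pairs))
  else
    cat(sprintf("<synchrony %s: r=%.3f z=%.3f n_pairs=%d lag=%ds>\n",
                x$dyad_id, x$r, x$z, x$n_pairs, x$lag_s))
  invisible(x)
}

#' Tabulate synchrony estimates
#'
#' @param estimates List of `synchrony_estimate` objects.
#' @return data.frame with columns `dyad_id`, `r`, `z`, `n_pairs`, `lag_s`,
#'   `reason`.
#' @export
synchrony_table <- function(estimates) {
  do.call(rbind, lapply(estimates, function(e)
    data.frame(dyad_id = e$dyad_id, r = e$r, z = e$z, n_pairs = e$n_pairs,
               lag_s = e$lag_s, reason = e$reason,
               stringsAsFactors = FALSE)))
}

#' Flag dyad-level synchrony outliers
#'
#' Excludes dyads whose Fisher-z synchrony deviates from the sample mean by
#' strictly more than `threshold_sd` sample standard deviations (default
#' 3.92, the threshold used to restore normality in the motivating sample).
#' Mean and SD are computed over non-missing z.
#'
#' @param estimates data.frame with columns `dyad_id` and `z` (e.g. from
#'   [synchrony_table()]), or a list of `synchrony_estimate`s.
#' @param threshold_sd SD multiplier; `Inf` excludes nothing.
#' @return The data.frame with added columns `excluded` (logical; `FALSE`
#'   for missing z) and `exclude_reason`.
#' @export
flag_outlier_dyads <- function(estimates, threshold_sd = 3.92) {
  if (!is.data.frame(estimates)) estimates <- synchrony_table(estimates)
  z <- estimates$z
  if (sum(!is.na(z)) < 3) stop("need >= 3 synchrony estimates")
  m <- mean(z, na.rm = TRUE)
  s <- stats::sd(z, na.rm = TRUE)
  excl <- !is.na(z) & is.finite(s) & s > 0 & abs(z - m) > threshold_sd * s
  estimates$excluded <- excl
  estimates$exclude_reason <- ifelse(
    excl, sprintf("synchrony outlier (> %.2f SD from mean)", threshold_sd),
    NA_character_)
  estimates
}
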