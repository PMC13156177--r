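# Dyad-level behavioral indicators from per-second code streams, and
# coder-reliability statistics.

#' Shared positive affect between two coded streams
#'
#' Counts seconds in which both members show `positive_warm` affect. If
#' more than `uncodable_max` of either stream is uncodable the dyad is
#' treated as missing on affect synchrony (the strict "> 50%" rule by
#' default). The proportion denominator is the number of jointly codable
#' seconds, mirroring the exclusion of uncodable epochs.
#'
#' @param parent,child Affect [coded_stream()]s of equal length.
#' @param uncodable_max Maximum tolerated uncodable fraction (strict
#'   inequality), default 0.5.
#' @return A list: `prop` (proportion of jointly codable seconds with
#'   shared positive affect), `any` (0/1: any shared positive), `missing`
#'   (logical), `reason`, `codable_frac_parent`, `codable_frac_child`.
#' @export
shared_positive <- function(parent, child, uncodable_max = 0.5) {
  stopifnot(inherits(parent, "coded_stream"), inherits(child, "coded_stream"))
  if (parent$stream_kind != "affect" || child$stream_kind != "affect")
    stop("shared_positive requires affect streams")
  if (parent$task_length_s != child$task_length_s)
    stop("stream length mismatch: ", parent$task_length_s, " vs ",
         child$task_length_s)
  unc_p <- mean(parent$codes == "uncodable")
  unc_c <- mean(child$codes == "uncodable")
  out <- list(prop = NA_real_, any = NA_integer_, missing = TRUE,
              reason = NA_character_,
              codable_frac_parent = 1 - unc_p,
              codable_frac_child = 1 - unc_c)
  if (unc_p > uncodable_max || unc_c > uncodable_max) {
    out$reason <- sprintf("uncodable fraction > %.0f%% (parent %.2f, child %.2f)",
                          100 * uncodable_max, unc_p, unc_c)
    return(out)
  }
  joint <- parent$codes != "uncodable" & child$codes != "uncodable"
  if (!any(joint)) {
    out$reason <- "no jointly codable seconds"
    return(out)
  }
  shared <- parent$codes == "positive_warm" & child$codes == "positive_warm"
  out$prop <- sum(shared & joint) / sum(joint)
  out$any <- as.integer(out$prop > 0)
  out$missing <- FALSE
  out
}

#' Unsupportive parenting indicator from an ERSB stream
#'
#' Proportion of codable seconds spent in any unsupportive code
#' (dismissing, mild rejection, firm rejection), and its dichotomization
#' (any vs. none) -- the usable form when the proportion is heavily skewed.
#'
#' @param ersb An ERSB [coded_stream()].
#' @return A list: `prop`, `any` (0/1), `missing`, `codable_frac`.
#' @export
unsupportive_indicator <- function(ersb) {
  stopifnot(inherits(ersb, "coded_stream"))
  if (ersb$stream_kind != "ersb")
    stop("unsupportive_indicator requires an ersb stream")
  codable <- ersb$codes != "uncodable"
  if (!any(codable))
    return(list(prop = NA_real_, any = NA_integer_, missing = TRUE,
                codable_frac = 0))
  prop <- sum(ersb$codes %in% unsupportive_codes) / sum(codable)
  list(prop = prop, any = as.integer(prop > 0), missing = FALSE,
       codable_frac = mean(codable))
}

#' Time-unit Cohen's kappa between two coders
#'
#' Chance-corrected per-second agreement: seconds either coder marked
#' uncodable are excluded pairwise, a confusion matrix over the remaining
#' seconds is tallied, and kappa = (p_o - p_e) / (1 - p_e) with p_e from
#' the marginal products. Unweighted.
#'
#' @param coder_a,coder_b [coded_stream()]s of the same kind and length.
#' @return Kappa, or `NA` with a warning when chance agreement is 1 (both
#'   coders confined to a single shared category).
#' @export
timeunit_kappa <- function(coder_a, coder_b) {
  stopifnot(inherits(coder_a, "coded_stream"),
            inherits(coder_b, "coded_stream"))
  if (coder_a$stream_kind != coder_b$stream_kind)
    stop("streams must have the same kind (alphabet)")
  if (coder_a$task_length_s != coder_b$task_length_s)
    stop("stream length mismatch")
  keep <- coder_a$codes != "uncodable" & coder_b$codes != "uncodable"
  a <- coder_a$codes[keep]
  b <- coder_b$codes[keep]
  if (!length(a)) {
    warning("no jointly codable seconds; kappa undefined")
    return(NA_real_)
  }
  lev <- setdiff(code_alphabet(coder_a$stream_kind), "uncodable")
  tab <- table(factor(a, levels = lev), factor(b, levels = lev))
  n <- sum(tab)
  p_o <- sum(diag(tab)) / n
  p_e <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (1 - p_e < .Machine$double.eps^0.5) {
    warning("chance agreement is 1 (single shared category); ",
            "kappa undefined")
    return(NA_real_)
  }
  (p_o - p_e) / (1 - p_e)
}

#' Dyad-level behavior summary
#'
#' Bundles [shared_positive()] and [unsupportive_indicator()] for one dyad.
#' Any absent stream yields missing fields.
#'
#' @param parent_affect,child_affect Affect [coded_stream()]s or `NULL`.
#' @param parent_ersb ERSB [coded_stream()] or `NULL`.
#' @param uncodable_max Passed to [shared_positive()].
#' @return One-row data.frame: `shared_positive_prop`, `shared_positive_any`,
#'   `unsupportive_prop`, `unsupportive_any`, `codable_frac_parent`,
#'   `codable_frac_child`, `affect_missing_reason`.
#' @export
behavior_summary <- function(parent_affect = NULL, child_affect = NULL,
                             parent_ersb = NULL, uncodable_max = 0.5) {
  sp <- list(prop = NA_real_, any = NA_integer_, reason = "stream absent",
             codable_frac_parent = NA_real_, codable_frac_child = NA_real_)
  if (!is.null(parent_affect) && !is.null(child_affect))
    sp <- shared_positive(parent_affect, child_affect, uncodable_max)
  un <- list(prop = NA_real_, any = NA_integer_)
  if (!is.null(parent_ersb)) un <- unsupportive_indicator(parent_ersb)
  data.frame(shared_positive_prop = sp$prop,
             shared_positive_any = sp$any,
             unsupportive_prop = un$prop,
             unsupportive_any = un$any,
             codable_frac_parent = sp$codable_frac_parent,
             codable_frac_child = sp$codable_frac_child,
             affect_missing_reason = if (is.null(sp$reason)) NA_character_
                                     else as.character(sp$reason),
             stringsAsFactors = FALSE)
}
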