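# Coupled-dyad simulator. Generates respiratory-band-modulated IBI series
# whose per-second RSA changes are cross-correlated within dyads at a
# planted level, coupled Markov affect streams, unsupportive-ERSB streams,
# and child symptom T-scores from a linear model with synchrony x parent
# factor interactions. The defaults state one fixed synthetic world whose
# marginals mirror the motivating sample; see the methods vignette.

#' Simulation configuration
#'
#' All tunables of the synthetic world, with defaults fixed to emulate the
#' motivating study: 80 dyads, 300 s conflict discussions, parent/child
#' respiration at 0.25/0.50 Hz, log-amplitude AR(1) respiratory envelopes
#' whose increments are correlated across dyad members at `rho`, sparse
#' positive affect with a calibrated shared-positive boost, a 42.5%
#' any-unsupportive-ERSB rate, and an outcome model whose interaction
#' coefficients mirror the published estimates.
#'
#' @param n_dyads Number of dyads.
#' @param seed Integer seed consumed once by [simulate_study()].
#' @param task_s Task length in seconds.
#' @param rho Cross-member correlation of envelope innovations (the
#'   planted RSA-change coupling), `|rho| < 1`.
#' @param ibi List of physiological settings: per-role `base_ms`,
#'   `resp_hz`, `band`; shared `noise_sd_ms` (per-beat white noise) and
#'   `envelope` (`phi`, `mean_log` in log-ms, `innov_sd`).
#' @param affect List: `p_enter_pos`, `p_stay_pos`, `boost` (multiplier on
#'   the partner-driven entry probability; calibrated so ~54.5% of codable
#'   dyads show any shared positive affect over 300 s), `nonpos_w`
#'   (weights over neutral/dysphoric/angry), `uncodable_rate`,
#'   `high_uncodable_rate` (rate used for dyads planted as mostly
#'   uncodable).
#' @param ersb List: `p_any` (proportion of dyads with any unsupportive
#'   second), `mean_unsup_s` (mean unsupportive seconds given any; capped
#'   at `max_unsup_s`), `p_supportive` (rate of supportive codes among the
#'   remaining seconds).
#' @param outcome List: `coef` (named: `intercept`, `parent_dep` (per
#'   centered T-unit), `ersb_any`, `affect_sync`, `rsa_sync`,
#'   `affect_x_ersb`, `affect_x_pdep`, `rsa_x_pdep`, `rsa_x_ersb`,
#'   `medication`, `pubertal`, `pandemic`), `residual_sd`, `parent_dep`
#'   (`mean`, `sd`, `floor`), covariate prevalences `p_medication`,
#'   `p_pubertal`, `p_pandemic`.
#' @param missing List of dyad-level missingness probabilities:
#'   `ibi` (ECG pair unusable), `video` (no affect streams),
#'   `high_uncodable` (video present but mostly uncodable), `ersb`,
#'   `parent_dep`, `child_dep`.
#' @return A list with class `sim_config`.
#' @export
sim_config <- function(n_dyads = 80, seed = 1, task_s = 300, rho = 0.1,
                       ibi = list(), affect = list(), ersb = list(),
                       outcome = list(), missing = list()) {
  defaults <- list(
    ibi = list(
      parent = list(base_ms = 850, resp_hz = 0.25, band = c(0.12, 0.40)),
      child = list(base_ms = 650, resp_hz = 0.50, band = c(0.24, 1.04)),
      noise_sd_ms = 2,
      envelope = list(phi = 0.8, mean_log = log(35), innov_sd = 0.15)),
    affect = list(p_enter_pos = 0.01, p_stay_pos = 0.7, boost = 6,
                  nonpos_w = c(neutral = 0.90, dysphoric = 0.06,
                               angry_aggressive = 0.04),
                  uncodable_rate = 0.08, high_uncodable_rate = 0.65),
    ersb = list(p_any = 0.425, mean_unsup_s = 7, max_unsup_s = 60,
                p_supportive = 0.15),
    outcome = list(
      coef = c(intercept = 56.8, parent_dep = 0.18, ersb_any = 1.22,
               affect_sync = -2.83, rsa_sync = -8.03, affect_x_ersb = 8.45,
               affect_x_pdep = -0.13, rsa_x_pdep = -2.37, rsa_x_ersb = 5.73,
               medication = 0, pubertal = 0, pandemic = 0),
      residual_sd = 6.5,
      parent_dep = list(mean = 55.54, sd = 7.64, floor = 50),
      p_medication = 0.25, p_pubertal = 0.45, p_pandemic = 0.637),
    missing = list(ibi = 0.275, video = 0.1375, high_uncodable = 0.20,
                   ersb = 0.0875, parent_dep = 0.1375, child_dep = 0.025))
  merge2 <- function(def, user) {
    for (nm in names(user))
      def[[nm]] <- if (is.list(def[[nm]]) && is.list(user[[nm]]))
        merge2(def[[nm]], user[[nm]]) else user[[nm]]
    def
  }
  cfg <- list(n_dyads = n_dyads, seed = seed, task_s = task_s, rho = rho,
              ibi = merge2(defaults$ibi, ibi),
              affect = merge2(defaults$affect, affect),
              ersb = merge2(defaults$ersb, ersb),
              outcome = merge2(defaults$outcome, outcome),
              missing = merge2(defaults$missing, missing))
  if (abs(cfg$rho) >= 1) stop("|rho| must be < 1")
  if (cfg$outcome$residual_sd < 0) stop("residual_sd must be >= 0")
  if (cfg$task_s < 64) stop("task_s too short for RSA estimation")
  structure(cfg, class = "sim_config")
}

# integrate instantaneous IBI to beat times: next beat follows the current
# one after the instantaneous interval, so the respiratory modulation is
# visible to the spline-resampling stage as in real data
emit_beats <- function(amp_by_second, base_ms, resp_hz, noise_sd_ms,
                       task_s, person_id, phase = 0) {
  max_beats <- ceiling(task_s * 1000 / (base_ms - 100)) + 8
  noise <- stats::rnorm(max_beats, 0, noise_sd_ms)
  times <- numeric(max_beats)
  ivals <- numeric(max_beats)
  t <- 0; k <- 0
  while (TRUE) {
    s <- min(floor(t), task_s - 1)
    ibi <- base_ms + amp_by_second[s + 1] *
      sin(2 * pi * resp_hz * t + phase) + noise[k + 1]
    t_next <- t + ibi / 1000
    if (t_next > task_s || k + 1 > max_beats) break
    k <- k + 1
    times[k] <- t_next
    ivals[k] <- ibi
    t <- t_next
  }
  ibi_series(person_id, beat_times = times[1:k], intervals = ivals[1:k])
}

#' Generate a coupled dyad of IBI series
#'
#' Per role, the per-second log-amplitude of the respiratory modulation
#' follows an AR(1) whose innovations are correlated at `rho` across
#' members; the instantaneous IBI is
#' `base + exp(envelope) * sin(2 pi f_resp t) + noise`, and beats are
#' emitted by integrating the instantaneous interval. The realized
#' envelopes are returned so ground-truth synchrony is available to
#' oracles.
#'
#' @param cfg A [sim_config()]. Uses the current RNG state (seed upstream).
#' @param dyad_id Identifier used for the member person_ids.
#' @return List: `parent`, `child` ([ibi_series()]), `truth` (per-second
#'   `env_parent`, `env_child` log-amplitudes, planted `rho`, and `z_true`,
#'   the Fisher z of the correlation of envelope increments).
#' @export
gen_ibi_dyad <- function(cfg, dyad_id = "dyad") {
  env_cfg <- cfg$ibi$envelope
  n <- cfg$task_s
  zp <- stats::rnorm(n)
  zc <- cfg$rho * zp + sqrt(1 - cfg$rho^2) * stats::rnorm(n)
  ar1 <- function(z) {
    sd_stat <- env_cfg$innov_sd / sqrt(1 - env_cfg$phi^2)
    e <- numeric(n)
    e[1] <- env_cfg$mean_log + sd_stat * z[1]
    for (s in 2:n)
      e[s] <- env_cfg$mean_log + env_cfg$phi * (e[s - 1] -
        env_cfg$mean_log) + env_cfg$innov_sd * z[s]
    e
  }
  ep <- ar1(zp); ec <- ar1(zc)
  # random respiration phase per person: without it, window-alignment
  # ripple in the estimated RSA would be phase-locked across all dyads
  parent <- emit_beats(exp(ep), cfg$ibi$parent$base_ms,
                       cfg$ibi$parent$resp_hz, cfg$ibi$noise_sd_ms,
                       n, paste0(dyad_id, "_parent"),
                       phase = stats::runif(1, 0, 2 * pi))
  child <- emit_beats(exp(ec), cfg$ibi$child$base_ms,
                      cfg$ibi$child$resp_hz, cfg$ibi$noise_sd_ms,
                      n, paste0(dyad_id, "_child"),
                      phase = stats::runif(1, 0, 2 * pi))
  r_true <- stats::cor(diff(ep), diff(ec))
  list(parent = parent, child = child,
       truth = list(env_parent = ep, env_child = ec, rho = cfg$rho,
                    z_true = atanh(r_true)))
}

sample_code <- function(w) sample(names(w), 1, prob = w)

#' Generate a coupled dyad of affect streams
#'
#' Coupled Markov chains over the affect alphabet: each member enters
#' `positive_warm` with baseline probability `p_enter_pos`, multiplied by
#' `boost` when the partner was positive in the previous second, and stays
#' positive with probability `p_stay_pos`; non-positive seconds are drawn
#' from `nonpos_w`. Uncodable seconds are injected i.i.d. at
#' `uncodable_rate` per member.
#'
#' @param cfg A [sim_config()].
#' @param dyad_id Identifier.
#' @param uncodable_rate Per-second uncodable probability (defaults to the
#'   config rate; [simulate_study()] raises it for planted high-uncodable
#'   dyads).
#' @return List: `parent`, `child` ([coded_stream()]s), `truth`
#'   (`shared_any`, `shared_prop` computed before uncodable injection).
#' @export
gen_affect_dyad <- function(cfg, dyad_id = "dyad",
                            uncodable_rate = cfg$affect$uncodable_rate) {
  a <- cfg$affect
  n <- cfg$task_s
  p <- character(n); ch <- character(n)
  p[1] <- sample_code(a$nonpos_w); ch[1] <- sample_code(a$nonpos_w)
  for (s in 2:n) {
    step <- function(prev_self, prev_partner) {
      if (prev_self == "positive_warm") {
        if (stats::runif(1) < a$p_stay_pos) return("positive_warm")
        return(sample_code(a$nonpos_w))
      }
      p_enter <- a$p_enter_pos *
        if (prev_partner == "positive_warm") a$boost else 1
      if (stats::runif(1) < min(1, p_enter)) return("positive_warm")
      sample_code(a$nonpos_w)
    }
    p[s] <- step(p[s - 1], ch[s - 1])
    ch[s] <- step(ch[s - 1], p[s - 1])
  }
  shared <- p == "positive_warm" & ch == "positive_warm"
  truth <- list(shared_any = as.integer(any(shared)),
                shared_prop = mean(shared))
  p[stats::runif(n) < uncodable_rate] <- "uncodable"
  ch[stats::runif(n) < uncodable_rate] <- "uncodable"
  list(parent = coded_stream(paste0(dyad_id, "_parent"), "parent",
                             "affect", p),
       child = coded_stream(paste0(dyad_id, "_child"), "child",
                            "affect", ch),
       truth = truth)
}

#' Generate a parent ERSB stream
#'
#' With probability `p_any` the parent emits unsupportive behavior: a
#' geometric number of seconds (mean `mean_unsup_s`, capped at
#' `max_unsup_s`) placed as a contiguous run at a random position and split
#' among the three unsupportive codes. Remaining seconds are `none` or
#' `supportive`.
#'
#' @param cfg A [sim_config()].
#' @param dyad_id Identifier.
#' @return List: `stream` ([coded_stream()]), `truth` (`any_unsupportive`,
#'   `n_unsup_s`).
#' @export
gen_ersb_stream <- function(cfg, dyad_id = "dyad") {
  e <- cfg$ersb
  n <- cfg$task_s
  codes <- ifelse(stats::runif(n) < e$p_supportive, "supportive", "none")
  n_unsup <- 0L
  if (stats::runif(1) < e$p_any) {
    n_unsup <- min(e$max_unsup_s,
                   1L + stats::rgeom(1, 1 / e$mean_unsup_s))
    start <- sample.int(n - n_unsup + 1L, 1)
    codes[start:(start + n_unsup - 1L)] <-
      sample(unsupportive_codes, n_unsup, replace = TRUE,
             prob = c(0.5, 0.35, 0.15))
  }
  list(stream = coded_stream(paste0(dyad_id, "_parent"), "parent", "ersb",
                             codes),
       truth = list(any_unsupportive = as.integer(n_unsup > 0),
                    n_unsup_s = n_unsup))
}

#' Generate the dyad-level outcome and covariate table
#'
#' Draws parent depressive-symptom T-scores and binary covariates from the
#' configured marginals, then generates the child depressive-symptom
#' T-score from the linear outcome model (parent depression centered at
#' its population mean) plus Gaussian residual noise. Predictor columns
#' present in `summaries` enter with their configured coefficients; absent
#' columns contribute nothing.
#'
#' @param cfg A [sim_config()].
#' @param summaries data.frame with one row per dyad: `dyad_id` and any of
#'   `affect_sync_any`, `rsa_sync_z`, `ersb_any`.
#' @return data.frame with `dyad_id`, covariates, `parent_dep_T`,
#'   `child_dep_T`, plus a `truth` attribute holding the generating
#'   coefficients.
#' @export
gen_outcome_table <- function(cfg, summaries) {
  oc <- cfg$outcome
  n <- nrow(summaries)
  pdep <- pmax(oc$parent_dep$floor,
               round(stats::rnorm(n, oc$parent_dep$mean, oc$parent_dep$sd)))
  med <- stats::rbinom(n, 1, oc$p_medication)
  pub <- stats::rbinom(n, 1, oc$p_pubertal)
  pan <- stats::rbinom(n, 1, oc$p_pandemic)
  pdep_c <- pdep - oc$parent_dep$mean
  col0 <- function(nm) {
    v <- if (nm %in% names(summaries)) summaries[[nm]] else rep(0, n)
    ifelse(is.na(v), 0, v)
  }
  aff <- col0("affect_sync_any"); rsa <- col0("rsa_sync_z")
  erb <- col0("ersb_any")
  b <- oc$coef
  mu <- b["intercept"] + b["parent_dep"] * pdep_c + b["ersb_any"] * erb +
    b["affect_sync"] * aff + b["rsa_sync"] * rsa +
    b["affect_x_ersb"] * aff * erb + b["affect_x_pdep"] * aff * pdep_c +
    b["rsa_x_pdep"] * rsa * pdep_c + b["rsa_x_ersb"] * rsa * erb +
    b["medication"] * med + b["pubertal"] * pub + b["pandemic"] * pan
  cdep <- as.numeric(mu) + stats::rnorm(n, 0, oc$residual_sd)
  out <- data.frame(dyad_id = summaries$dyad_id,
                    child_medication = med, pubertal_status = pub,
                    pandemic_cohort = pan, parent_dep_T = pdep,
                    child_dep_T = cdep, stringsAsFactors = FALSE)
  attr(out, "truth") <- list(coef = b, residual_sd = oc$residual_sd,
                             parent_dep_mean = oc$parent_dep$mean)
  out
}

#' Simulate a full study
#'
#' Generates `n_dyads` dyads under one seed: coupled IBI series, affect and
#' ERSB streams, covariates and outcomes, with dyad-level missingness
#' injected at the configured rates (ECG pair unusable, video absent,
#' video mostly uncodable, ERSB uncoded, questionnaires unreturned).
#' Outcomes are generated from the dyads' latent ground-truth synchrony,
#' so the planted coefficients are the estimand regardless of measurement
#' missingness.
#'
#' @param cfg A [sim_config()]. `cfg$seed` is consumed here: all
#'   randomness downstream is reproducible from the config alone.
#' @return List with class `sim_study`: `dyads` (list of [dyad_record()]),
#'   `truth` (data.frame per dyad: `z_true`, `affect_any_true`,
#'   `ersb_any`, flags for injected missingness; attribute carries the
#'   outcome-model truth), `envelopes` (per-dyad list of realized
#'   log-amplitude envelopes), `config`.
#' @export
simulate_study <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_dyads
  ids <- sprintf("d%03d", seq_len(n))
  ms <- cfg$missing
  miss_ibi <- stats::runif(n) < ms$ibi
  miss_video <- stats::runif(n) < ms$video
  high_unc <- !miss_video & stats::runif(n) < ms$high_uncodable
  miss_ersb <- stats::runif(n) < ms$ersb
  miss_pdep <- stats::runif(n) < ms$parent_dep
  miss_cdep <- stats::runif(n) < ms$child_dep

  dyads <- vector("list", n)
  envelopes <- vector("list", n)
  tr <- data.frame(dyad_id = ids, z_true = NA_real_,
                   affect_any_true = NA_integer_,
                   affect_prop_true = NA_real_, ersb_any = NA_integer_,
                   miss_ibi = miss_ibi, miss_video = miss_video,
                   high_uncodable = high_unc, miss_ersb = miss_ersb,
                   miss_parent_dep = miss_pdep, miss_child_dep = miss_cdep,
                   stringsAsFactors = FALSE)
  pre <- vector("list", n)
  for (i in seq_len(n)) {
    phys <- gen_ibi_dyad(cfg, ids[i])
    tr$z_true[i] <- phys$truth$z_true
    envelopes[[i]] <- phys$truth[c("env_parent", "env_child")]
    rate <- if (high_unc[i]) cfg$affect$high_uncodable_rate
            else cfg$affect$uncodable_rate
    aff <- gen_affect_dyad(cfg, ids[i], uncodable_rate = rate)
    tr$affect_any_true[i] <- aff$truth$shared_any
    tr$affect_prop_true[i] <- aff$truth$shared_prop
    ers <- gen_ersb_stream(cfg, ids[i])
    tr$ersb_any[i] <- ers$truth$any_unsupportive
    pre[[i]] <- list(phys = phys, aff = aff, ers = ers)
  }
  summaries <- data.frame(dyad_id = ids,
                          affect_sync_any = tr$affect_any_true,
                          rsa_sync_z = tr$z_true,
                          ersb_any = tr$ersb_any)
  outc <- gen_outcome_table(cfg, summaries)
  for (i in seq_len(n)) {
    dyads[[i]] <- dyad_record(
      dyad_id = ids[i],
      parent_ibi = if (miss_ibi[i]) NULL else pre[[i]]$phys$parent,
      child_ibi = if (miss_ibi[i]) NULL else pre[[i]]$phys$child,
      parent_affect = if (miss_video[i]) NULL else pre[[i]]$aff$parent,
      child_affect = if (miss_video[i]) NULL else pre[[i]]$aff$child,
      parent_ersb = if (miss_ersb[i]) NULL else pre[[i]]$ers$stream,
      covariates = list(child_medication = outc$child_medication[i],
                        pubertal_status = outc$pubertal_status[i],
                        pandemic_cohort = outc$pandemic_cohort[i]),
      parent_dep_T = if (miss_pdep[i]) NA else outc$parent_dep_T[i],
      child_dep_T = if (miss_cdep[i]) NA else outc$child_dep_T[i])
  }
  attr(tr, "outcome_truth") <- attr(outc, "truth")
  structure(list(dyads = dyads, truth = tr, envelopes = envelopes,
                 config = cfg),
            class = "sim_study")
}

#' Write a simulated study to disk in the pipeline's input formats
#'
#' Writes per-dyad IBI and code-stream CSVs, `manifest.csv`,
#' `covariates.csv` and `ground_truth.json` under `dir`, in exactly the
#' formats [assemble_dyads()] consumes.
#'
#' @param sim A `sim_study` from [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- length(sim$dyads)
  man <- data.frame(dyad_id = character(n), parent_ibi = NA_character_,
                    child_ibi = NA_character_, parent_affect = NA_character_,
                    child_affect = NA_character_,
                    parent_ersb = NA_character_, stringsAsFactors = FALSE)
  cov <- data.frame(dyad_id = character(n), child_medication = NA_integer_,
                    pubertal_status = NA_integer_,
                    pandemic_cohort = NA_integer_, parent_dep_T = NA_real_,
                    child_dep_T = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    d <- sim$dyads[[i]]
    man$dyad_id[i] <- d$dyad_id
    put <- function(obj, suffix, writer) {
      if (is.null(obj)) return(NA_character_)
      fn <- paste0(d$dyad_id, "_", suffix, ".csv")
      writer(obj, file.path(dir, fn))
      fn
    }
    man$parent_ibi[i] <- put(d$parent_ibi, "parent_ibi", write_ibi)
    man$child_ibi[i] <- put(d$child_ibi, "child_ibi", write_ibi)
    man$parent_affect[i] <- put(d$parent_affect, "parent_affect",
                                write_coded_stream)
    man$child_affect[i] <- put(d$child_affect, "child_affect",
                               write_coded_stream)
    man$parent_ersb[i] <- put(d$parent_ersb, "parent_ersb",
                              write_coded_stream)
    cov$dyad_id[i] <- d$dyad_id
    cov$child_medication[i] <- d$covariates$child_medication
    cov$pubertal_status[i] <- d$covariates$pubertal_status
    cov$pandemic_cohort[i] <- d$covariates$pandemic_cohort
    cov$parent_dep_T[i] <- d$parent_dep_T
    cov$child_dep_T[i] <- d$child_dep_T
  }
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  utils::write.csv(cov, file.path(dir, "covariates.csv"), row.names = FALSE)
  ot <- attr(sim$truth, "outcome_truth")
  jsonlite::write_json(
    list(seed = sim$config$seed, rho = sim$config$rho,
         outcome_coef = as.list(ot$coef), residual_sd = ot$residual_sd,
         dyads = sim$truth[, c("dyad_id", "z_true", "affect_any_true",
                               "ersb_any")]),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
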