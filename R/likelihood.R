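# Simulation-based likelihood of observed (choice, RT) pairs.
#
# For each trial the candidate model is simulated n_sims times; the
# likelihood of a responded observation is the simulated frequency of its
# choice class times a Gaussian KDE (over that class's simulated RTs,
# bandwidth = half of Silverman's rule of thumb) evaluated at the observed
# RT.  Missed observations are scored by the simulated missed frequency.
# Everything is floored at a small eps so the log-likelihood is finite over
# the whole parameter box.

LIK_EPS <- 1e-10
FALLBACK_BW <- 0.010  # s; used when a class has < 2 distinct RTs

#' Halved Silverman rule-of-thumb bandwidth
#'
#' `0.5 * 0.9 * min(sd, IQR/1.34) * n^(-1/5)`.  The halving preserves the
#' disjointed, multi-modal RT densities produced by gaze-contingent drift
#' switches.  With fewer than two distinct values (or a degenerate spread
#' measure) the fixed fallback bandwidth is returned.
#'
#' @param rts Numeric vector of simulated RTs in seconds.
#' @param fallback Fallback bandwidth in seconds (default 0.010).
#' @return The bandwidth in seconds.
#' @examples
#' silverman_bandwidth(rnorm(1000))  # ~ 0.5 * 0.9 * 1000^(-0.2)
#' @export
silverman_bandwidth <- function(rts, fallback = FALLBACK_BW) {
  n <- length(rts)
  if (n < 2 || length(unique(rts)) < 2) return(fallback)
  a <- min(sd(rts), (quantile(rts, 0.75, names = FALSE) -
                       quantile(rts, 0.25, names = FALSE)) / 1.34)
  h <- 0.5 * 0.9 * a * n^(-1 / 5)
  if (!is.finite(h) || h <= 0) fallback else h
}

#' Simulate the predictive (choice, RT) distribution of one trial
#'
#' @param params An [addm_params()] or [static_params()] object for the
#'   trial's condition.
#' @param self,other Proposal amounts in dollars.
#' @param condition `"HIGH"` or `"LOW"`.
#' @param timeline Gaze timeline (gaze model only).
#' @param n_sims Number of simulations (default 10000).
#' @param settings A [sim_settings()] object.
#' @return A list with class `"predictive_sample"`: `accept_rts`,
#'   `reject_rts`, `n_missed`, `n_total`.
#' @export
draw_predictive <- function(params, self, other, condition, timeline = NULL,
                            n_sims = 10000, settings = sim_settings()) {
  stopifnot(n_sims >= 1)
  sims <- if (inherits(params, "addm_params")) {
    simulate_trial(params, self, other, condition, timeline, settings,
                   n_sims = n_sims)
  } else {
    simulate_trial_static(params, self, other, condition, settings,
                          n_sims = n_sims)
  }
  structure(list(accept_rts = sims$rt[sims$choice == "ACCEPT"],
                 reject_rts = sims$rt[sims$choice == "REJECT"],
                 n_missed = sum(sims$choice == "MISSED"),
                 n_total = n_sims),
            class = "predictive_sample")
}

#' Likelihood of one observed trial under a predictive sample
#'
#' Responded observations score
#' `(class count / n_total) * KDE_class(rt)` with the class-specific
#' [silverman_bandwidth()]; missed observations score
#' `n_missed / n_total`.  The result is floored at `eps`.
#'
#' @param sample A `"predictive_sample"` from [draw_predictive()].
#' @param choice Observed choice: `"ACCEPT"`, `"REJECT"` or `"MISSED"`.
#' @param rt Observed RT in seconds (ignored for missed trials).
#' @param eps Likelihood floor (default `1e-10`).
#' @param fallback_bw Fallback KDE bandwidth in seconds.
#' @return The likelihood (a density for responded trials, a probability
#'   mass for missed ones).
#' @export
trial_likelihood <- function(sample, choice, rt = NA, eps = LIK_EPS,
                             fallback_bw = FALLBACK_BW) {
  choice <- toupper(choice)
  stopifnot(choice %in% CHOICE_LEVELS)
  if (choice == "MISSED") {
    return(max(sample$n_missed / sample$n_total, eps))
  }
  rts <- if (choice == "ACCEPT") sample$accept_rts else sample$reject_rts
  if (length(rts) == 0) return(eps)
  h <- silverman_bandwidth(rts, fallback_bw)
  dens <- mean(dnorm(rt, mean = rts, sd = h))
  max((length(rts) / sample$n_total) * dens, eps)
}

# internal: trials + timelines -> flattened arrays for the C++ likelihood
prepare_subject_data <- function(trials, timelines, model) {
  tr <- as.data.frame(trials)
  n <- nrow(tr)
  if (model == "gaze") {
    stopifnot(length(timelines) == n)
    dl_ms <- deadline_s(tr$condition) * 1000
    for (i in seq_len(n)) check_timeline_cover(timelines[[i]], dl_ms[i])
    codes <- lapply(timelines, timeline_codes)
    lens <- vapply(codes, function(x) length(x$aoi), integer(1))
    ptr <- c(0L, cumsum(lens))
    seg_aoi <- unlist(lapply(codes, `[[`, "aoi"), use.names = FALSE)
    seg_on <- unlist(lapply(codes, `[[`, "onset"), use.names = FALSE)
    seg_off <- unlist(lapply(codes, `[[`, "offset"), use.names = FALSE)
  } else {
    ptr <- integer(n + 1)
    seg_aoi <- integer(0)
    seg_on <- seg_off <- numeric(0)
  }
  list(self = tr$self, other = tr$other,
       deadline = deadline_s(tr$condition),
       cond = ifelse(toupper(tr$condition) == "HIGH", 1L, -1L),
       obs_choice = match(toupper(tr$choice), CHOICE_LEVELS) - 1L,
       obs_rt = ifelse(is.na(tr$rt), -1, tr$rt),
       gen_dir = generous_direction(tr$self, tr$other),
       seg_aoi = as.integer(seg_aoi), seg_on = seg_on, seg_off = seg_off,
       ptr = as.integer(ptr), n_trials = n)
}

#' Log-likelihood of a subject's data set
#'
#' Sum of log [trial_likelihood()] over all trials (including missed ones),
#' with the predictive samples drawn by `n_sims` fresh simulations per trial
#' under the condition-specific parameters.  Computed in compiled code; the
#' KDE arithmetic is identical to the R-level functions.
#'
#' @param params_high,params_low Parameter objects for the two conditions.
#' @param trials A trials table for one subject (observed choices and RTs).
#' @param timelines List of per-trial gaze timelines (gaze model only).
#' @param n_sims Simulations per trial (default 10000).
#' @param settings A [sim_settings()] object.
#' @param eps Likelihood floor.
#' @param fallback_bw Fallback KDE bandwidth in seconds.
#' @return The log-likelihood (finite for any parameters in the box).
#' @export
dataset_loglik <- function(params_high, params_low, trials, timelines = NULL,
                           n_sims = 10000, settings = sim_settings(),
                           eps = LIK_EPS, fallback_bw = FALLBACK_BW) {
  gaze <- inherits(params_high, "addm_params")
  model <- if (gaze) "gaze" else "static"
  if (nrow(as.data.frame(trials)) == 0) return(0)
  dat <- prepare_subject_data(trials, timelines, model)
  cpp_dataset_loglik(par_vec(params_high), par_vec(params_low), gaze,
                     dat$self, dat$other, dat$deadline, dat$cond,
                     dat$obs_choice, dat$obs_rt, dat$seg_aoi, dat$seg_on,
                     dat$seg_off, dat$ptr, as.integer(n_sims),
                     settings$dt_ms / 1000, settings$noise_sd, eps,
                     fallback_bw, next_seed())
}

#' Per-trial likelihood table
#'
#' Evaluates [trial_likelihood()] for every trial of a subject at fixed
#' parameters, returning one row per trial — useful for debugging which
#' observations drive a fit.
#'
#' @inheritParams dataset_loglik
#' @return A data.frame with the trial identifiers, the observed choice and
#'   RT, the simulated class frequencies, and the (log) likelihood.
#' @export
likelihood_table <- function(params_high, params_low, trials,
                             timelines = NULL, n_sims = 1000,
                             settings = sim_settings()) {
  tr <- as.data.frame(trials)
  gaze <- inherits(params_high, "addm_params")
  rows <- vector("list", nrow(tr))
  for (i in seq_len(nrow(tr))) {
    p <- if (toupper(tr$condition[i]) == "HIGH") params_high else params_low
    ps <- draw_predictive(p, tr$self[i], tr$other[i], tr$condition[i],
                          if (gaze) timelines[[i]] else NULL, n_sims,
                          settings)
    lik <- trial_likelihood(ps, tr$choice[i], tr$rt[i])
    rows[[i]] <- data.frame(
      subject = tr$subject[i], trial = tr$trial[i],
      condition = tr$condition[i], choice = tr$choice[i], rt = tr$rt[i],
      p_accept = length(ps$accept_rts) / ps$n_total,
      p_reject = length(ps$reject_rts) / ps$n_total,
      p_missed = ps$n_missed / ps$n_total,
      likelihood = lik, loglik = log(lik))
  }
  do.call(rbind, rows)
}
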