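# Synthetic study generator: proposals, subject parameters, gaze timelines
# and model-generated choices/RTs, with stored ground truth.
#
# The gaze generator is a two-state alternating renewal process: an initial
# NEITHER latency, then strictly alternating SELF/OTHER fixations with
# log-normal durations.  The first fixated AOI is drawn from a subject- and
# condition-specific probability that is logistic in the subject's
# other-regard weight, with a higher intercept and a steeper (negative)
# slope under high time pressure — emulating early selfish gaze biases that
# strengthen under time pressure and track social preferences.

#' Configuration of the synthetic study generator
#'
#' Defaults reproduce the study conditions: proposals on a $0--$100 grid with
#' self and other amounts on opposite sides of the $50/$50 default, 1.5 s vs
#' 10 s deadlines, 80 trials per condition, and subject-level parameters
#' drawn from the same N(0, 0.5) probit-uniform hyperprior used in fitting.
#'
#' @param n_subjects Number of subjects (default 8).
#' @param trials_per_condition Trials per time-pressure condition (default
#'   80).
#' @param grid_step Proposal grid step in dollars (default 10).
#' @param include_50 Allow amounts equal to $50 (default `FALSE`, so every
#'   proposal pits a loss against a gain).
#' @param hyper_M_mean,hyper_M_sd Named numeric vectors (one entry per model
#'   parameter) giving the population mean and SD of the unconstrained
#'   predispositions M.  The defaults keep the attribute weights and the
#'   attentional discount spread over their full ranges but concentrate the
#'   start biases near zero and the threshold away from zero, so that
#'   generated subjects respond through evidence accumulation rather than
#'   starting on a boundary.
#' @param hyper_delta_mean Named numeric vector of mean time-pressure
#'   effects.  The default shifts only the threshold collapse rate `d`
#'   upwards under high pressure (urgency), reproducing the study pattern of
#'   faster responses under the short deadline.
#' @param hyper_delta_sd SD of the unconstrained time-pressure effects.
#' @param force_M,force_delta Named numeric vectors fixing selected
#'   unconstrained parameters for every subject (e.g.
#'   `force_M = c(theta = 1.5)` for strongly gaze-coupled subjects).
#' @param gaze_intercept,gaze_slope Per-condition logistic coefficients (on
#'   the log-odds scale) of the probability that the first fixation lands on
#'   the Self AOI: `plogis(intercept + slope * w_other / 0.1)`.  Defaults
#'   give an overall selfish first-fixation bias that is stronger, and more
#'   strongly coupled to `w_other`, under high pressure.
#' @param fix_meanlog,fix_sdlog Log-normal fixation-duration parameters in
#'   ms (median 250 ms, sigma 0.4).
#' @param neither_meanlog,neither_sdlog Log-normal initial NEITHER latency
#'   in ms (median 100 ms).
#' @param dt_ms Euler step used when generating choices (default 1 ms).
#' @return A list with class `"generative_config"`.
#' @export
generative_config <- function(n_subjects = 8, trials_per_condition = 80,
                              grid_step = 10, include_50 = FALSE,
                              hyper_M_mean = c(w_self = 0, w_other = 0,
                                               w_fairness = 0, b = 0.4,
                                               d = -0.5, stbias = 0,
                                               genbias = 0, theta = 0),
                              hyper_M_sd = c(w_self = 0.5, w_other = 0.5,
                                             w_fairness = 0.5, b = 0.4,
                                             d = 0.5, stbias = 0.2,
                                             genbias = 0.2, theta = 0.5),
                              hyper_delta_mean = c(w_self = 0, w_other = 0,
                                                   w_fairness = 0, b = 0,
                                                   d = 0.8, stbias = 0,
                                                   genbias = 0, theta = 0),
                              hyper_delta_sd = 0.2, force_M = NULL,
                              force_delta = NULL,
                              gaze_intercept = c(HIGH = 0.8, LOW = 0.2),
                              gaze_slope = c(HIGH = -2.5, LOW = -1.0),
                              fix_meanlog = log(250), fix_sdlog = 0.4,
                              neither_meanlog = log(100),
                              neither_sdlog = 0.3, dt_ms = 1) {
  stopifnot(n_subjects >= 1, trials_per_condition >= 1, grid_step > 0)
  structure(list(n_subjects = n_subjects,
                 trials_per_condition = trials_per_condition,
                 grid_step = grid_step, include_50 = include_50,
                 hyper_M_mean = hyper_M_mean, hyper_M_sd = hyper_M_sd,
                 hyper_delta_mean = hyper_delta_mean,
                 hyper_delta_sd = hyper_delta_sd, force_M = force_M,
                 force_delta = force_delta,
                 gaze_intercept = gaze_intercept, gaze_slope = gaze_slope,
                 fix_meanlog = fix_meanlog, fix_sdlog = fix_sdlog,
                 neither_meanlog = neither_meanlog,
                 neither_sdlog = neither_sdlog, dt_ms = dt_ms),
            class = "generative_config")
}

#' Draw proposal amounts
#'
#' Proposals are drawn uniformly from the grid with self and other amounts
#' on opposite sides of $50 (boundary amounts only when `include_50`).
#'
#' @param n Number of proposals.
#' @param config A [generative_config()].
#' @return A data.frame with columns `self`, `other`.
#' @export
gen_proposals <- function(n, config = generative_config()) {
  grid <- seq(0, 100, by = config$grid_step)
  if (length(grid) < 2) stop("empty proposal grid", call. = FALSE)
  lo <- grid[grid < 50]
  hi <- grid[grid > 50]
  if (config$include_50 && 50 %in% grid) {
    lo <- c(lo, 50)
    hi <- c(hi, 50)
  }
  if (length(lo) == 0 || length(hi) == 0) {
    stop("proposal grid has no amounts on both sides of 50", call. = FALSE)
  }
  self_low <- runif(n) < 0.5
  self <- ifelse(self_low, sample(lo, n, replace = TRUE),
                 sample(hi, n, replace = TRUE))
  other <- ifelse(self_low, sample(hi, n, replace = TRUE),
                  sample(lo, n, replace = TRUE))
  data.frame(self = self, other = other)
}

#' Generate one trial's gaze timeline
#'
#' Initial NEITHER latency, then strictly alternating SELF/OTHER fixations
#' with log-normal durations, extended to cover the condition deadline.
#'
#' @param p_self_first Probability that the first fixation lands on the
#'   Self AOI.
#' @param deadline_ms Coverage required, in ms.
#' @param config A [generative_config()].
#' @return A `"gaze_timeline"` covering `[0, deadline_ms]`.
#' @export
gen_gaze_timeline <- function(p_self_first, deadline_ms,
                              config = generative_config()) {
  t0 <- min(rlnorm(1, config$neither_meanlog, config$neither_sdlog),
            deadline_ms * 0.5)
  aoi <- if (runif(1) < p_self_first) "SELF" else "OTHER"
  aois <- character(0)
  ons <- offs <- numeric(0)
  t <- t0
  while (t < deadline_ms) {
    dur <- rlnorm(1, config$fix_meanlog, config$fix_sdlog)
    aois <- c(aois, aoi)
    ons <- c(ons, t)
    offs <- c(offs, min(t + dur, deadline_ms))
    t <- t + dur
    aoi <- if (aoi == "SELF") "OTHER" else "SELF"
  }
  fx <- data.frame(aoi = aois, onset = ons, offset = offs)
  fx <- fx[fx$offset > fx$onset, ]
  build_timeline(fx, deadline_ms)
}

# subject-level truth: unconstrained draws, per-condition parameters, and
# gaze-coupling probabilities
gen_subject_truth <- function(config) {
  M <- rnorm(8, config$hyper_M_mean[ADDM_PARAMS],
             config$hyper_M_sd[ADDM_PARAMS])
  delta <- rnorm(8, config$hyper_delta_mean[ADDM_PARAMS],
                 config$hyper_delta_sd)
  names(M) <- names(delta) <- ADDM_PARAMS
  if (!is.null(config$force_M)) M[names(config$force_M)] <- config$force_M
  if (!is.null(config$force_delta)) {
    delta[names(config$force_delta)] <- config$force_delta
  }
  params <- list(HIGH = to_model_space(M, delta, "HIGH", "gaze"),
                 LOW = to_model_space(M, delta, "LOW", "gaze"))
  p_self_first <- vapply(c(HIGH = "HIGH", LOW = "LOW"), function(cc) {
    plogis(config$gaze_intercept[[cc]] +
             config$gaze_slope[[cc]] * params[[cc]]$w_other / 0.1)
  }, numeric(1))
  list(M = M, delta = delta, params = params, p_self_first = p_self_first)
}

#' Generate a complete synthetic study
#'
#' For each subject: draws ground-truth parameters from the hyperprior,
#' generates proposals and gaze timelines per trial, and simulates choices
#' and RTs from the gaze-informed ADDM under the condition-specific
#' parameters and deadlines.
#'
#' @param config A [generative_config()].
#' @param seed Optional seed passed to [set.seed()].
#' @return A list with `trials` (an `"addm_trials"` table), `fixations`
#'   (an `"addm_fixations"` table), `timelines` (list in trial row order),
#'   `truth` (per-subject ground truth), and `config`.
#' @examples
#' study <- gen_study(generative_config(n_subjects = 2,
#'                                      trials_per_condition = 4), seed = 1)
#' head(study$trials)
#' @export
gen_study <- function(config = generative_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sim <- sim_settings(dt_ms = config$dt_ms)
  trials <- list()
  fixations <- list()
  timelines <- list()
  truth <- list()
  for (s in seq_len(config$n_subjects)) {
    sid <- sprintf("S%02d", s)
    tru <- gen_subject_truth(config)
    truth[[sid]] <- tru
    trial_no <- 0L
    for (cc in c("HIGH", "LOW")) {
      dl_ms <- deadline_s(cc) * 1000
      props <- gen_proposals(config$trials_per_condition, config)
      for (i in seq_len(config$trials_per_condition)) {
        trial_no <- trial_no + 1L
        tl <- gen_gaze_timeline(tru$p_self_first[[cc]], dl_ms, config)
        out <- simulate_trial(tru$params[[cc]], props$self[i],
                              props$other[i], cc, tl, sim)
        trials[[length(trials) + 1]] <- data.frame(
          subject = sid, trial = trial_no, self = props$self[i],
          other = props$other[i], condition = cc, choice = out$choice,
          rt = out$rt)
        fx <- as.data.frame(tl)
        fx <- fx[fx$aoi != "NEITHER", ]
        if (nrow(fx) > 0) {
          fixations[[length(fixations) + 1]] <- data.frame(
            subject = sid, trial = trial_no, aoi = fx$aoi,
            onset_ms = fx$onset, offset_ms = fx$offset)
        }
        timelines[[length(timelines) + 1]] <- tl
      }
    }
  }
  trials <- addm_trials(do.call(rbind, trials))
  fixations <- addm_fixations(do.call(rbind, fixations))
  list(trials = trials, fixations = fixations, timelines = timelines,
       truth = truth, config = config)
}

#' Ground-truth parameter table of a synthetic study
#'
#' @param study A [gen_study()] result.
#' @return A data.frame with one row per subject x condition and one column
#'   per model parameter.
#' @export
truth_table <- function(study) {
  rows <- list()
  for (sid in names(study$truth)) {
    for (cc in c("HIGH", "LOW")) {
      p <- study$truth[[sid]]$params[[cc]]
      rows[[length(rows) + 1]] <- data.frame(
        subject = sid, condition = cc,
        as.data.frame(p[ADDM_PARAMS]))
    }
  }
  do.call(rbind, rows)
}
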