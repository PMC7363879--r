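# Trial-level simulation of the gaze-informed ADDM and the attention-blind
# multi-attribute DDM.
#
# Evidence x(t) starts at z = stbias +/- genbias and follows
#   dx = V(t) dt + noise_sd dW
# between symmetric collapsing bounds +/- b exp(-d t), integrated by
# Euler-Maruyama on a fixed ms grid.  The diffusion scale is a package
# convention; weights and thresholds are identified relative to it.  The
# default (0.2 per sqrt-second, i.e. 0.02 per 10 ms step, the scale common
# in attentional-DDM implementations) keeps the parameter box in a regime
# where decisions are driven by accumulated evidence rather than by
# pre-fixation noise: under much larger noise the accumulator would cross
# a threshold in the box before the first fixation completes, making the
# attribute weights unidentifiable.

#' Simulation settings
#'
#' @param dt_ms Euler integration step in milliseconds (default 1).
#' @param noise_sd Diffusion noise standard deviation per sqrt(second).
#'   The default 0.2 (equivalently 0.02 per 10 ms step) is the package's
#'   fixed scaling convention; attribute weights and thresholds are
#'   identified relative to it.
#' @return A list with class `"sim_settings"`.
#' @export
sim_settings <- function(dt_ms = 1, noise_sd = 0.2) {
  stopifnot(dt_ms > 0, noise_sd > 0)
  structure(list(dt_ms = dt_ms, noise_sd = noise_sd),
            class = "sim_settings")
}

#' Collapsing decision threshold
#'
#' @param b Initial threshold.
#' @param d Decay rate per second.
#' @param t Time in seconds from trial onset.
#' @return `b * exp(-d * t)`; the accumulator terminates at `+/-` this value.
#' @export
boundary_at <- function(b, d, t) {
  stopifnot(all(t >= 0))
  b * exp(-d * t)
}

#' Accumulator starting point
#'
#' `z = stbias + genbias` when the proposal favours the other party
#' (`self < other`), `stbias - genbias` when it favours self, and `stbias`
#' for equal amounts.  Positive `z` leans towards accepting.
#'
#' @param params An [addm_params()] or [static_params()] object.
#' @param self,other Proposal amounts in dollars.
#' @return The starting point `z`.
#' @export
starting_point <- function(params, self, other) {
  s <- ifelse(self < other, 1, ifelse(self > other, -1, 0))
  params$stbias + s * params$genbias
}

#' Momentary mean drift of the gaze-informed ADDM
#'
#' Outside perceptual-intake windows the mean evidence rate is
#' `A_self w_self Self + A_other w_other Other + w_fairness |Self - Other|`,
#' where attended payoffs get `A = 1` and unattended ones `A = 1 - theta`
#' (the fairness term carries no attention factor), and every term is gated
#' to zero until its information has been acquired.  Inside a percept window
#' only previously acquired information contributes, discounted by
#' `1 - theta`.
#'
#' @param params An [addm_params()] object.
#' @param self,other Proposal amounts in dollars.
#' @param aoi_now Current gaze position: `"SELF"`, `"OTHER"` or `"NEITHER"`.
#' @param seen_self,seen_other Whether each attribute has been acquired (its
#'   percept window completed) before now.
#' @param in_percept Whether now falls inside a perceptual-intake window (at
#'   most one attribute can be already acquired then).
#' @return Mean evidence rate per second.
#' @export
momentary_drift <- function(params, self, other, aoi_now,
                            seen_self, seen_other, in_percept = FALSE) {
  stopifnot(aoi_now %in% AOI_LEVELS)
  th <- params$theta
  if (in_percept) {
    if (seen_self && seen_other) {
      stop("at most one attribute can be acquired during a percept window",
           call. = FALSE)
    }
    if (seen_self) return((1 - th) * params$w_self * self)
    if (seen_other) return((1 - th) * params$w_other * other)
    return(0)
  }
  a_self <- if (aoi_now == "SELF") 1 else 1 - th
  a_other <- if (aoi_now == "OTHER") 1 else 1 - th
  drift <- 0
  if (seen_self) drift <- drift + a_self * params$w_self * self
  if (seen_other) drift <- drift + a_other * params$w_other * other
  if (seen_self && seen_other) {
    drift <- drift + params$w_fairness * abs(self - other)
  }
  drift
}

sim_outcome_frame <- function(res) {
  data.frame(
    choice = c("ACCEPT", "REJECT", "MISSED")[res$choice + 1L],
    rt = res$rt,
    decision_time = res$decision_time,
    n_unique_fixated = res$n_unique,
    stringsAsFactors = FALSE
  )
}

check_timeline_cover <- function(timeline, deadline_ms) {
  tl <- as.data.frame(timeline)
  if (max(tl$offset) < deadline_ms - 1e-9) {
    stop(sprintf(paste0("gaze timeline covers only %g ms but the deadline ",
                        "needs %g ms; extend it (see extend_timeline)"),
                 max(tl$offset), deadline_ms), call. = FALSE)
  }
  invisible(timeline)
}

#' Simulate gaze-informed ADDM trials
#'
#' Runs `n_sims` Euler-Maruyama accumulations of one trial under the gaze
#' model.  An 80 ms perceptual-intake window opens at the first entry into
#' each previously unseen AOI; each opened window adds one `percept` latency
#' to the final RT, and `motor` is added once at threshold crossing.  A
#' simulation is `MISSED` when no threshold is crossed before the deadline or
#' when the assembled RT exceeds it.
#'
#' @param params An [addm_params()] object.
#' @param self,other Proposal amounts in dollars.
#' @param condition `"HIGH"` or `"LOW"` (sets the deadline).
#' @param timeline A gaze timeline covering at least the deadline.
#' @param settings A [sim_settings()] object.
#' @param n_sims Number of simulations (default 1).
#' @return A data.frame with columns `choice`, `rt`, `decision_time`,
#'   `n_unique_fixated`; `rt` satisfies
#'   `rt = decision_time + motor + n_unique_fixated * percept` for responded
#'   simulations and is `NA` for missed ones.
#' @examples
#' set.seed(1)
#' tl <- build_timeline(data.frame(aoi = "SELF", onset = 0, offset = 1500),
#'                      1500)
#' simulate_trial(addm_params(w_self = 0.05, theta = 0), 80, 20, "HIGH", tl)
#' @export
simulate_trial <- function(params, self, other, condition, timeline,
                           settings = sim_settings(), n_sims = 1) {
  stopifnot(inherits(params, "addm_params"))
  condition <- match_condition(condition)
  deadline <- deadline_s(condition)
  check_timeline_cover(timeline, deadline * 1000)
  tc <- timeline_codes(timeline)
  res <- cpp_sim_trial(par_vec(params), TRUE, self, other, deadline,
                       tc$aoi, tc$onset, tc$offset, as.integer(n_sims),
                       settings$dt_ms / 1000, settings$noise_sd,
                       next_seed())
  sim_outcome_frame(res)
}

#' Simulate attention-blind multi-attribute DDM trials
#'
#' As [simulate_trial()] but the drift is constant from trial onset
#' (`w_self Self + w_other Other + w_fairness |Self - Other|`), no gaze
#' information enters, and `rt = decision_time + ndt`.
#'
#' @param params A [static_params()] object.
#' @inheritParams simulate_trial
#' @return A data.frame as in [simulate_trial()] (with
#'   `n_unique_fixated = 0`).
#' @export
simulate_trial_static <- function(params, self, other, condition,
                                  settings = sim_settings(), n_sims = 1) {
  stopifnot(inherits(params, "static_params"))
  condition <- match_condition(condition)
  deadline <- deadline_s(condition)
  res <- cpp_sim_trial(par_vec(params), FALSE, self, other, deadline,
                       integer(0), numeric(0), numeric(0),
                       as.integer(n_sims), settings$dt_ms / 1000,
                       settings$noise_sd, next_seed())
  sim_outcome_frame(res)
}

#' Simulate a full set of trials
#'
#' Vectorised map of [simulate_trial()] (or its static counterpart) over a
#' trials table, drawing one outcome per trial under condition-specific
#' parameters.  Reproducible under `set.seed()`.
#'
#' @param params_high,params_low Parameter objects for the two conditions
#'   (both [addm_params()] or both [static_params()]).
#' @param trials A trials table (the `choice`/`rt` columns are ignored).
#' @param timelines A list of gaze timelines in the row order of `trials`
#'   (required for the gaze model, ignored for the static model).
#' @param settings A [sim_settings()] object.
#' @return A data.frame with one simulated outcome per trial (columns as in
#'   [simulate_trial()]).
#' @export
simulate_dataset <- function(params_high, params_low, trials,
                             timelines = NULL, settings = sim_settings()) {
  gaze <- inherits(params_high, "addm_params")
  stopifnot(class(params_high)[1] == class(params_low)[1])
  tr <- as.data.frame(trials)
  n <- nrow(tr)
  if (n == 0) {
    return(data.frame(choice = character(0), rt = numeric(0),
                      decision_time = numeric(0),
                      n_unique_fixated = integer(0)))
  }
  out <- vector("list", n)
  for (i in seq_len(n)) {
    p <- if (toupper(tr$condition[i]) == "HIGH") params_high else params_low
    out[[i]] <- if (gaze) {
      simulate_trial(p, tr$self[i], tr$other[i], tr$condition[i],
                     timelines[[i]], settings, n_sims = 1)
    } else {
      simulate_trial_static(p, tr$self[i], tr$other[i], tr$condition[i],
                            settings, n_sims = 1)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
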