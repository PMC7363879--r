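# Diffusion-model parameters, their box constraints, and the probit link
# between the unconstrained sampling space and model space.
#
# Each of the 8 per-condition parameters lives on a fixed range and is
# obtained from an unconstrained value u = M + delta * c (condition effect-
# coded c = +1 high pressure, -1 low) by x = pnorm(u) followed by a linear
# scaling f_sc(x) onto its range:
#   weights  x * 0.2 - 0.1   in [-0.1, 0.1]   ($ -> evidence/s per $)
#   b        x * 0.5         in [0, 0.5]      initial threshold
#   d        x * 2.5         in [0, 2.5]      threshold decay rate (1/s)
#   stbias   x - 0.5         in [-0.5, 0.5]   accept/reject start bias
#   genbias  x - 0.5         in [-0.5, 0.5]   generosity start bias
#   theta    x               in [0, 1]        attentional discount (gaze model)
#   ndt      x               in [0, 1]        non-decision time, s (static)
# With M, delta ~ N(0, var 0.5) independently, u ~ N(0, 1) in each condition
# and pnorm(u) is exactly Uniform(0, 1), i.e. the implied prior on every
# model parameter is uniform over its range in both conditions.

ADDM_PARAMS <- c("w_self", "w_other", "w_fairness", "b", "d", "stbias",
                 "genbias", "theta")
STATIC_PARAMS <- c("w_self", "w_other", "w_fairness", "b", "d", "stbias",
                   "genbias", "ndt")

PARAM_BOUNDS <- rbind(
  w_self     = c(-0.1, 0.1),
  w_other    = c(-0.1, 0.1),
  w_fairness = c(-0.1, 0.1),
  b          = c(0, 0.5),
  d          = c(0, 2.5),
  stbias     = c(-0.5, 0.5),
  genbias    = c(-0.5, 0.5),
  theta      = c(0, 1),
  ndt        = c(0, 1)
)
colnames(PARAM_BOUNDS) <- c("min", "max")

#' Parameter box constraints
#'
#' @return A matrix with rows named by parameter and columns `min`, `max`
#'   giving the admissible range of each diffusion-model parameter.
#' @export
param_bounds <- function() PARAM_BOUNDS

#' Map a unit-interval value onto a parameter's range
#'
#' The per-parameter linear scaling from `[0, 1]` to the parameter box
#' (weights onto `[-0.1, 0.1]`, `b` onto `[0, 0.5]`, and so on).
#'
#' @param x Numeric values in `[0, 1]`.
#' @param param Parameter name (one of the rows of [param_bounds()]).
#' @return Scaled values.
#' @export
scale_to_bounds <- function(x, param) {
  b <- PARAM_BOUNDS[param, , drop = FALSE]
  b[, "min"] + x * (b[, "max"] - b[, "min"])
}

check_bounds <- function(value, param) {
  lo <- PARAM_BOUNDS[param, "min"]
  hi <- PARAM_BOUNDS[param, "max"]
  if (any(value < lo - 1e-12) || any(value > hi + 1e-12)) {
    stop(sprintf("%s = %g outside its range [%g, %g]", param, value, lo, hi),
         call. = FALSE)
  }
  invisible(value)
}

#' Gaze-informed ADDM parameters for one condition
#'
#' The eight fitted diffusion parameters plus the two fixed non-decision
#' latencies.  `percept` (default 0.08 s) is added to the RT once per unique
#' AOI fixated before the decision and governs the 80 ms perceptual-intake
#' windows; `motor` (default 0.08 s) is added once at threshold crossing.
#' Both are fixed by design, not fitted, but may be overridden (e.g. set
#' `percept = 0` for diagnostic limits).
#'
#' @param w_self,w_other,w_fairness Attribute weights (evidence/s per $),
#'   each in `[-0.1, 0.1]`.
#' @param b Initial threshold in `[0, 0.5]`.
#' @param d Threshold decay rate per second, `[0, 2.5]`.
#' @param stbias Start bias towards accepting, `[-0.5, 0.5]`.
#' @param genbias Generosity bias whose sign flips with the favoured party,
#'   `[-0.5, 0.5]`.
#' @param theta Attentional discount of unattended payoffs, `[0, 1]`.
#' @param percept,motor Fixed non-decision latencies in seconds.
#' @return A named list with class `"addm_params"`.
#' @examples
#' addm_params(w_other = 0.05, theta = 0.7)
#' @export
addm_params <- function(w_self = 0, w_other = 0, w_fairness = 0, b = 0.25,
                        d = 0.5, stbias = 0, genbias = 0, theta = 0.5,
                        percept = 0.08, motor = 0.08) {
  p <- list(w_self = w_self, w_other = w_other, w_fairness = w_fairness,
            b = b, d = d, stbias = stbias, genbias = genbias, theta = theta,
            percept = percept, motor = motor)
  for (nm in ADDM_PARAMS) check_bounds(p[[nm]], nm)
  stopifnot(percept >= 0, motor >= 0)
  structure(p, class = "addm_params")
}

#' Attention-blind multi-attribute DDM parameters for one condition
#'
#' Identical to [addm_params()] but without the attentional discount or
#' fixation gating; `percept` and `motor` collapse into a single fitted
#' non-decision time `ndt`.
#'
#' @inheritParams addm_params
#' @param ndt Non-decision time in seconds, `[0, 1]`.
#' @return A named list with class `"static_params"`.
#' @export
static_params <- function(w_self = 0, w_other = 0, w_fairness = 0, b = 0.25,
                          d = 0.5, stbias = 0, genbias = 0, ndt = 0.3) {
  p <- list(w_self = w_self, w_other = w_other, w_fairness = w_fairness,
            b = b, d = d, stbias = stbias, genbias = genbias, ndt = ndt)
  for (nm in STATIC_PARAMS) check_bounds(p[[nm]], nm)
  structure(p, class = "static_params")
}

base_param_names <- function(model) {
  if (model == "gaze") ADDM_PARAMS else STATIC_PARAMS
}

#' Map unconstrained sampler parameters to model space
#'
#' Applies the probit link `x = pnorm(M + delta * c)` with condition
#' effect-coded `c = +1` (high time pressure) or `c = -1` (low), followed by
#' the per-parameter range scaling, yielding the condition-specific
#' diffusion parameters.
#'
#' @param M Named (or ordered) numeric vector of 8 predispositions, in the
#'   order of `param_bounds()` rows for the chosen model.
#' @param delta Numeric vector of 8 time-pressure effects.
#' @param condition `"HIGH"` or `"LOW"`.
#' @param model `"gaze"` (ADDM, includes `theta`) or `"static"` (includes
#'   `ndt`).
#' @param percept,motor Fixed latencies for the gaze model.
#' @return An [addm_params()] or [static_params()] object.
#' @examples
#' to_model_space(rep(0, 8), rep(0, 8), "HIGH")$w_self  # 0: midpoint of range
#' @export
to_model_space <- function(M, delta, condition = c("HIGH", "LOW"),
                           model = c("gaze", "static"), percept = 0.08,
                           motor = 0.08) {
  condition <- match.arg(condition)
  model <- match.arg(model)
  nms <- base_param_names(model)
  stopifnot(length(M) == 8, length(delta) == 8)
  cc <- if (condition == "HIGH") 1 else -1
  x <- pnorm(as.numeric(M) + as.numeric(delta) * cc)
  vals <- vapply(seq_along(nms),
                 function(i) scale_to_bounds(x[i], nms[i]), numeric(1))
  names(vals) <- nms
  if (model == "gaze") {
    do.call(addm_params, c(as.list(vals),
                           list(percept = percept, motor = motor)))
  } else {
    do.call(static_params, as.list(vals))
  }
}

#' Log prior density of the unconstrained sampler parameters
#'
#' Independent normal priors with mean 0 and variance 0.5 on every
#' predisposition and time-pressure effect; their probit push-forward is
#' uniform on each parameter's range in both conditions.
#'
#' @param u Numeric vector of unconstrained parameters `(M, delta)`.
#' @return The summed log density.
#' @export
log_prior <- function(u) {
  sum(dnorm(u, mean = 0, sd = sqrt(0.5), log = TRUE))
}

# parameter list -> length-10 vector for the C++ core
par_vec <- function(params) {
  if (inherits(params, "addm_params")) {
    c(params$w_self, params$w_other, params$w_fairness, params$b, params$d,
      params$stbias, params$genbias, params$theta, params$percept,
      params$motor)
  } else if (inherits(params, "static_params")) {
    c(params$w_self, params$w_other, params$w_fairness, params$b, params$d,
      params$stbias, params$genbias, 0, params$ndt, 0)
  } else {
    stop("params must be addm_params or static_params", call. = FALSE)
  }
}

# unconstrained vector u (length 16: M then delta) -> per-condition C++
# parameter vectors; fast path equivalent to par_vec(to_model_space(...))
# (hot loop of the sampler, so no constructors or bound checks here)
u_to_parvecs <- function(u, model, percept = 0.08, motor = 0.08) {
  x_h <- pnorm(u[1:8] + u[9:16])
  x_l <- pnorm(u[1:8] - u[9:16])
  sc <- function(x) {
    c(x[1] * 0.2 - 0.1, x[2] * 0.2 - 0.1, x[3] * 0.2 - 0.1,
      x[4] * 0.5, x[5] * 2.5, x[6] - 0.5, x[7] - 0.5, x[8])
  }
  vh <- sc(x_h)
  vl <- sc(x_l)
  if (model == "gaze") {
    list(high = c(vh, percept, motor), low = c(vl, percept, motor))
  } else {
    list(high = c(vh[1:7], 0, vh[8], 0), low = c(vl[1:7], 0, vl[8], 0))
  }
}

u_names <- function(model) {
  nms <- base_param_names(model)
  c(paste0("M_", nms), paste0("delta_", nms))
}
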