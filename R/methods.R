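# S3 methods for fitted models.

#' @export
print.addm_fit <- function(x, ...) {
  cat(sprintf("%s model fit, subject %s (%d trials)\n",
              if (x$model == "gaze") "Gaze-informed ADDM" else
                "Static multi-attribute DDM",
              x$subject, x$n_trials))
  cat(sprintf("  chains %d, iterations %d + %d, %d sims/trial (preset %s)\n",
              x$settings$n_chains, x$settings$n_burn, x$settings$n_keep,
              x$settings$n_sims, x$settings$preset))
  cat(sprintf("  acceptance rate %.3f, max R-hat %.3f (%s)\n",
              x$accept_rate, max(x$rhat),
              if (x$converged) "converged" else "NOT converged"))
  cat("Posterior-mean parameters:\n")
  print(round(x$estimates, 4))
  invisible(x)
}

#' @export
summary.addm_fit <- function(object, ...) {
  flat <- matrix(object$draws, ncol = dim(object$draws)[3])
  colnames(flat) <- dimnames(object$draws)[[3]]
  qs <- t(apply(flat, 2, quantile, probs = c(0.025, 0.5, 0.975)))
  out <- list(fit = object,
              u_summary = cbind(mean = colMeans(flat), qs,
                                rhat = object$rhat))
  class(out) <- "summary.addm_fit"
  out
}

#' @export
print.summary.addm_fit <- function(x, ...) {
  print(x$fit)
  cat("\nUnconstrained posterior (M = predisposition, delta = time-pressure effect):\n")
  print(round(x$u_summary, 3))
  invisible(x)
}

#' @export
coef.addm_fit <- function(object, ...) {
  object$estimates
}

#' Posterior-predictive simulation from a fitted model
#'
#' Draws `nsim` simulated data sets of the fitted subject's trials at the
#' posterior-mean parameters (the same trials, proposals and — for the gaze
#' model — gaze timelines).
#'
#' @param object An `"addm_fit"`.
#' @param nsim Number of replicate data sets.
#' @param seed Optional seed passed to [set.seed()].
#' @param ... Unused.
#' @return A list of `nsim` data.frames of simulated outcomes (columns as in
#'   [simulate_trial()]).
#' @export
simulate.addm_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  ph <- fit_params(object, "HIGH")
  pl <- fit_params(object, "LOW")
  replicate(nsim, simulate_dataset(ph, pl, object$trials, object$timelines,
                                   object$sim),
            simplify = FALSE)
}

#' Per-trial model predictions
#'
#' Simulates each trial `n_sims` times at the posterior-mean parameters and
#' returns predicted acceptance, rejection and missed probabilities, mean RT
#' and mean log RT among responded simulations, and the predicted
#' probability of a generous response.
#'
#' @param object An `"addm_fit"`.
#' @param newdata Optional list with elements `trials` (and `timelines` for
#'   the gaze model) to predict for different trials; defaults to the fitted
#'   data.
#' @param n_sims Simulations per trial (default 1000).
#' @param ... Unused.
#' @return A data.frame, one row per trial, with the prediction columns
#'   appended to the trial identifiers.
#' @export
predict.addm_fit <- function(object, newdata = NULL, n_sims = 1000, ...) {
  trials <- if (is.null(newdata)) object$trials else newdata$trials
  timelines <- if (is.null(newdata)) object$timelines else newdata$timelines
  dat <- prepare_subject_data(trials, timelines, object$model)
  pv <- list(high = par_vec(fit_params(object, "HIGH")),
             low = par_vec(fit_params(object, "LOW")))
  pred <- cpp_predict_trials(pv$high, pv$low, object$model == "gaze",
                             dat$self, dat$other, dat$deadline, dat$cond,
                             dat$gen_dir, dat$seg_aoi, dat$seg_on,
                             dat$seg_off, dat$ptr, as.integer(n_sims),
                             object$sim$dt_ms / 1000, object$sim$noise_sd,
                             next_seed())
  cbind(as.data.frame(trials)[c("subject", "trial", "condition")],
        as.data.frame(pred))
}

#' @export
residuals.addm_fit <- function(object, n_sims = 1000, ...) {
  pred <- predict(object, n_sims = n_sims)
  obs <- ifelse(object$trials$choice == "ACCEPT", 1,
                ifelse(object$trials$choice == "REJECT", 0, NA))
  obs - pred$p_accept
}

#' Diagnostic plots for a fitted model
#'
#' Trace plots of a few unconstrained parameters and a bar chart of R-hat
#' values against the 1.1 convergence criterion.
#'
#' @param x An `"addm_fit"`.
#' @param pars Indices or names of unconstrained parameters to trace
#'   (default first four).
#' @param ... Unused.
#' @export
plot.addm_fit <- function(x, pars = 1:4, ...) {
  op <- par(mfrow = c(length(pars) + 1, 1), mar = c(2, 4, 1, 1))
  on.exit(par(op))
  nms <- dimnames(x$draws)[[3]]
  if (is.character(pars)) pars <- match(pars, nms)
  for (j in pars) {
    matplot(x$draws[, , j], type = "l", lty = 1, ylab = nms[j],
            col = grDevices::grey.colors(dim(x$draws)[2], alpha = 0.6))
  }
  barplot(x$rhat, las = 2, ylab = "R-hat", cex.names = 0.6)
  abline(h = 1.1, lty = 2)
  invisible(x)
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("Cluster-mass permutation test (%s contrast, %d permutations)\n",
              x$contrast, x$n_perm))
  cat(sprintf("  forming threshold p < %g (>= %d adjacent points), t_max 95th pct = %.2f\n",
              x$alpha, x$min_len, x$threshold))
  if (nrow(x$clusters) == 0) {
    cat("  no candidate clusters\n")
  } else {
    print(x$clusters)
  }
  invisible(x)
}

#' @export
print.cv_result <- function(x, ...) {
  cat("Split-half cross-validation (train: odd trials, test: even trials)\n")
  for (mod in x$models) {
    r <- x$correlations[[mod]]
    cat(sprintf("  %-7s r_high = %.3f, r_low = %.3f, r_change = %.3f\n",
                mod, r[["r_high"]], r[["r_low"]], r[["r_change"]]))
  }
  if (!is.null(x$comparison)) {
    cat(sprintf("  Williams' t(%d) = %.3f, p = %.4f (change-in-generosity)\n",
                x$comparison$df, x$comparison$statistic,
                x$comparison$p.value))
  }
  invisible(x)
}

#' @export
print.ppc_report <- function(x, ...) {
  cat("Posterior-predictive quantile check\n")
  for (cc in names(x)) {
    cat(sprintf("  %s: r(acceptance) = %.3f, r(logRT) = %.3f%s\n", cc,
                x[[cc]]$cor_acceptance, x[[cc]]$cor_logrt,
                if (isTRUE(x[[cc]]$degenerate)) " [degenerate bins]" else ""))
  }
  invisible(x)
}
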