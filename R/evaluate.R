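# Behavioural summaries, posterior-predictive quantile checks, split-half
# cross-validation, and dependent-correlation model comparison.

#' Proportion of generous choices
#'
#' Generous choices over responded trials; missed trials and trials without
#' a self/other trade-off (neutral proposals) are excluded from both
#' numerator and denominator.
#'
#' @param trials A trials table (typically one subject's).
#' @param condition Optional condition filter (`"HIGH"`/`"LOW"`).
#' @return The proportion in `[0, 1]`, or `NA` (with a warning) when no
#'   qualifying trial exists.
#' @export
proportion_generous <- function(trials, condition = NULL) {
  tr <- as.data.frame(trials)
  if (!is.null(condition)) {
    tr <- tr[toupper(tr$condition) == match_condition(condition), ]
  }
  cls <- classify_choice(tr$self, tr$other, tr$choice)
  denom <- sum(cls %in% c("GENEROUS", "SELFISH"))
  if (denom == 0) {
    warning("no responded trials with a self/other trade-off", call. = FALSE)
    return(NA_real_)
  }
  sum(cls == "GENEROUS") / denom
}

#' Generosity proportions per subject and condition
#'
#' @param trials A trials table.
#' @return A data.frame with columns `subject`, `condition`, `generosity`.
#' @export
generosity_by_subject <- function(trials) {
  tr <- as.data.frame(trials)
  out <- expand.grid(subject = unique(tr$subject),
                     condition = c("HIGH", "LOW"),
                     stringsAsFactors = FALSE)
  out$generosity <- mapply(function(s, cc) {
    suppressWarnings(
      proportion_generous(tr[tr$subject == s, ], cc))
  }, out$subject, out$condition)
  out
}

#' Screen subjects for response invariance
#'
#' Subjects who give the same response on more than 90% of their responded
#' trials are flagged for exclusion from model fitting (strictly more than:
#' exactly 90% is kept).
#'
#' @param trials A trials table (any number of subjects).
#' @return A data.frame with one row per subject: `subject`, `accept_rate`,
#'   `keep`, `reason`.
#' @export
exclusion_screen <- function(trials) {
  tr <- as.data.frame(trials)
  subjects <- unique(tr$subject)
  out <- data.frame(subject = subjects, accept_rate = NA_real_,
                    keep = TRUE, reason = "", stringsAsFactors = FALSE)
  for (i in seq_along(subjects)) {
    ch <- tr$choice[tr$subject == subjects[i]]
    resp <- ch[ch %in% c("ACCEPT", "REJECT")]
    if (length(resp) == 0) {
      out$keep[i] <- FALSE
      out$reason[i] <- "no responded trials"
      next
    }
    ar <- mean(resp == "ACCEPT")
    out$accept_rate[i] <- ar
    if (ar > 0.9) {
      out$keep[i] <- FALSE
      out$reason[i] <- "accepts > 90% of responded trials"
    } else if (ar < 0.1) {
      out$keep[i] <- FALSE
      out$reason[i] <- "rejects > 90% of responded trials"
    }
  }
  out
}

quantile_bins <- function(x, n_bins) {
  qs <- unique(quantile(x, probs = seq(0, 1, length.out = n_bins + 1),
                        na.rm = TRUE))
  if (length(qs) < 3) return(NULL)  # degenerate (near-constant predictions)
  cut(x, breaks = qs, include.lowest = TRUE, labels = FALSE)
}

#' Posterior-predictive quantile check
#'
#' Simulates each trial at the posterior-mean parameters, bins trials into
#' (up to) ten within-subject quantiles of the model-predicted acceptance
#' rate and of the model-predicted mean log RT (separately per condition),
#' and compares observed and predicted bin means.
#'
#' @param fit An [addm()] fit.
#' @param n_sims Simulations per trial (default 1000).
#' @param n_bins Number of quantile bins (default 10).
#' @return A list with class `"ppc_report"`: per condition, bin-mean tables
#'   for acceptance and log RT with observed/predicted columns, and their
#'   correlations; `degenerate` flags conditions with near-constant
#'   predictions.
#' @export
quantile_ppc <- function(fit, n_sims = 1000, n_bins = 10) {
  pred <- predict(fit, n_sims = n_sims)
  tr <- as.data.frame(fit$trials)
  out <- list()
  for (cc in c("HIGH", "LOW")) {
    rows <- which(toupper(tr$condition) == cc)
    if (length(rows) < n_bins) {
      warning("fewer trials than bins in condition ", cc, call. = FALSE)
    }
    resp <- rows[tr$choice[rows] != "MISSED"]
    obs_acc <- ifelse(tr$choice[resp] == "ACCEPT", 1, 0)
    obs_lrt <- log(tr$rt[resp])

    acc_bin <- quantile_bins(pred$p_accept[resp], n_bins)
    lrt_bin <- quantile_bins(pred$mean_logrt[resp], n_bins)
    mk <- function(bin, obs, prd) {
      if (is.null(bin)) return(NULL)
      data.frame(bin = sort(unique(bin)),
                 observed = as.numeric(tapply(obs, bin, mean)),
                 predicted = as.numeric(tapply(prd, bin, mean)))
    }
    acc_tab <- mk(acc_bin, obs_acc, pred$p_accept[resp])
    lrt_tab <- mk(lrt_bin, obs_lrt, pred$mean_logrt[resp])
    out[[cc]] <- list(
      acceptance = acc_tab,
      logrt = lrt_tab,
      cor_acceptance = if (!is.null(acc_tab) && nrow(acc_tab) > 2)
        cor(acc_tab$observed, acc_tab$predicted) else NA_real_,
      cor_logrt = if (!is.null(lrt_tab) && nrow(lrt_tab) > 2)
        cor(lrt_tab$observed, lrt_tab$predicted) else NA_real_,
      degenerate = is.null(acc_tab) || is.null(lrt_tab)
    )
  }
  structure(out, class = "ppc_report")
}

#' Williams' t test of two dependent correlations
#'
#' Compares two correlations `r1 = cor(x1, y)` and `r2 = cor(x2, y)` that
#' share the outcome variable `y`, given the correlation `r12` between the
#' two predictors, on `n` cases.
#'
#' @param r1,r2 The two correlations with the shared variable.
#' @param r12 Correlation between the two competing predictors.
#' @param n Number of cases (at least 4).
#' @return A list with `statistic` (t), `df` (`n - 3`) and two-tailed
#'   `p.value`.  Positive t favours `r1`.
#' @export
dependent_correlation_test <- function(r1, r2, r12, n) {
  stopifnot(n >= 4, abs(r12) < 1)
  if (abs(r1) >= 1 || abs(r2) >= 1) {
    stop("correlations must lie strictly inside (-1, 1)", call. = FALSE)
  }
  detR <- 1 - r1^2 - r2^2 - r12^2 + 2 * r1 * r2 * r12
  rbar <- (r1 + r2) / 2
  tval <- (r1 - r2) * sqrt((n - 1) * (1 + r12) /
    (2 * ((n - 1) / (n - 3)) * detR + rbar^2 * (1 - r12)^3))
  list(statistic = tval, df = n - 3, p.value = 2 * pt(-abs(tval), n - 3))
}

#' Odd/even split-half cross-validation of competing models
#'
#' Fits each model to the odd-numbered trials of every subject, predicts the
#' even-numbered trials by simulation at the posterior means, and compares
#' models on how well the predicted per-subject generosity (per condition,
#' and its high-minus-low change) correlates with the observed out-of-sample
#' values.
#'
#' @param trials A trials table (multiple subjects).
#' @param fixations A fixations table (needed for the gaze model).
#' @param models Character vector among `"gaze"`, `"static"`.
#' @param preset Sampler preset for the half fits (default `"mini"`).
#' @param n_sims Simulations per held-out trial (default 1000).
#' @param verbose Print per-subject progress.
#' @return A list with class `"cv_result"`: `per_subject` (predicted and
#'   observed generosity per subject/condition/model), `correlations`
#'   (per model: `r_high`, `r_low`, `r_change`), and, with two models,
#'   `comparison` — Williams' test on the change correlations.
#' @export
split_half_cv <- function(trials, fixations = NULL,
                          models = c("gaze", "static"), preset = "mini",
                          n_sims = 1000, verbose = FALSE) {
  trials <- addm_trials(trials)
  subjects <- unique(trials$subject)
  rows <- list()
  for (s in subjects) {
    tr_s <- trials[trials$subject == s, ]
    odd <- tr_s[tr_s$trial %% 2 == 1, ]
    even <- tr_s[tr_s$trial %% 2 == 0, ]
    for (cc in c("HIGH", "LOW")) {
      if (sum(toupper(odd$condition) == cc) < 2 ||
          sum(toupper(even$condition) == cc) < 2) {
        stop("need at least 2 trials per condition in each half", call. = FALSE)
      }
    }
    fx_s <- if (!is.null(fixations)) {
      fx <- as.data.frame(fixations)
      fx[fx$subject == s, ]
    } else NULL
    for (mod in models) {
      if (verbose) message("CV fit: subject ", s, ", model ", mod)
      fit <- addm(odd, fx_s, model = mod, preset = preset)
      pred <- predict(fit, newdata = list(
        trials = even,
        timelines = if (mod == "gaze")
          timelines_from_fixations(fx_s, even) else NULL
      ), n_sims = n_sims)
      for (cc in c("HIGH", "LOW")) {
        sel <- toupper(even$condition) == cc
        rows[[length(rows) + 1]] <- data.frame(
          subject = s, model = mod, condition = cc,
          pred_gen = mean(pred$p_generous[sel], na.rm = TRUE),
          obs_gen = suppressWarnings(proportion_generous(even, cc)))
      }
    }
  }
  per_subject <- do.call(rbind, rows)
  wide <- function(mod, col) {
    d <- per_subject[per_subject$model == mod, ]
    h <- d[d$condition == "HIGH", col]
    l <- d[d$condition == "LOW", col]
    cbind(high = h, low = l, change = h - l)
  }
  correlations <- list()
  chg_pred <- list()
  obs <- wide(models[1], "obs_gen")
  for (mod in models) {
    prd <- wide(mod, "pred_gen")
    ok_h <- complete.cases(prd[, "high"], obs[, "high"])
    ok_l <- complete.cases(prd[, "low"], obs[, "low"])
    ok_c <- complete.cases(prd[, "change"], obs[, "change"])
    correlations[[mod]] <- c(
      r_high = cor(prd[ok_h, "high"], obs[ok_h, "high"]),
      r_low = cor(prd[ok_l, "low"], obs[ok_l, "low"]),
      r_change = cor(prd[ok_c, "change"], obs[ok_c, "change"]))
    chg_pred[[mod]] <- prd[, "change"]
  }
  comparison <- NULL
  if (length(models) == 2) {
    ok <- complete.cases(chg_pred[[1]], chg_pred[[2]], obs[, "change"])
    comparison <- dependent_correlation_test(
      correlations[[models[1]]]["r_change"],
      correlations[[models[2]]]["r_change"],
      cor(chg_pred[[models[1]]][ok], chg_pred[[models[2]]][ok]),
      sum(ok))
  }
  structure(list(per_subject = per_subject, correlations = correlations,
                 comparison = comparison, models = models),
            class = "cv_result")
}
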