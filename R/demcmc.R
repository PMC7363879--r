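# Differential-evolution MCMC with probit-transformed priors.
#
# The engine samples an unconstrained vector u = (M, delta) of length k = 16
# per subject.  Proposals are scaled differences of two other chains plus a
# small jitter, evaluated by Metropolis-Hastings on prior + simulation-based
# log-likelihood.  Three stabilisers for the noisy likelihood: a
# probabilistic migration step (cyclic position swaps among a random subset
# of chains), re-evaluation of a chain's stored likelihood after three
# consecutive rejections, and an outlier reset of stray chains halfway
# through burn-in.

#' Sampler settings and presets
#'
#' Four presets are shipped.  `"paper"` uses the full estimation settings
#' (3k chains, 500 burn-in + 500 kept iterations, 10,000 simulations per
#' trial at a 1 ms step).  `"scaled_down"` keeps the 3k-chain geometry but
#' runs 300 + 300 iterations with 250 simulations per trial at a 10 ms step
#' — suitable for a single-subject fit in a few minutes.  `"recovery"` (24
#' chains, 300 + 300, 128 simulations, 10 ms) is used by the multi-subject
#' parameter-recovery experiment, where accurate posterior means matter;
#' `"mini"` (24 chains, 150 + 150, 96 simulations, 10 ms) is the quickest
#' preset, used where only directional comparisons are needed.
#'
#' @param preset `"scaled_down"`, `"recovery"`, `"mini"` or `"paper"`.
#' @param k Dimension of the unconstrained parameter vector (16).
#' @param ... Named overrides of individual fields (`n_chains`, `n_burn`,
#'   `n_keep`, `migrate_prob`, `gamma`, `jitter`, `stuck_limit`, `reset_at`,
#'   `n_sims`, `dt_ms`).
#' @return A list with class `"sampler_settings"`.
#' @export
sampler_settings <- function(preset = c("scaled_down", "recovery", "mini",
                                        "paper"),
                             k = 16, ...) {
  preset <- match.arg(preset)
  s <- switch(preset,
    paper = list(n_chains = 3L * k, n_burn = 500L, n_keep = 500L,
                 n_sims = 10000L, dt_ms = 1),
    scaled_down = list(n_chains = 3L * k, n_burn = 300L, n_keep = 300L,
                       n_sims = 250L, dt_ms = 10),
    recovery = list(n_chains = 24L, n_burn = 300L, n_keep = 300L,
                    n_sims = 128L, dt_ms = 10),
    mini = list(n_chains = 24L, n_burn = 150L, n_keep = 150L,
                n_sims = 96L, dt_ms = 10)
  )
  s <- c(s, list(migrate_prob = 0.1, gamma = 2.38 / sqrt(2 * k),
                 jitter = 1e-3, gamma2_prob = 0.1, gamma2 = 0.98,
                 stuck_limit = 3L, preset = preset, k = k))
  s$reset_at <- as.integer(floor(s$n_burn / 2))
  dots <- list(...)
  bad <- setdiff(names(dots), c(names(s)))
  if (length(bad) > 0) {
    stop("unknown sampler setting(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  s[names(dots)] <- dots
  if (s$n_chains < k + 2) stop("need at least k + 2 chains", call. = FALSE)
  structure(s, class = "sampler_settings")
}

#' Differential-evolution proposal for one chain
#'
#' `x_i + gamma * (x_r1 - x_r2) + jitter`, with `r1 != r2 != i` drawn
#' uniformly among the other chains and jitter uniform on
#' `[-jitter, jitter]` per coordinate.
#'
#' With probability `gamma2_prob` the scaling is replaced by `gamma2`
#' (close to 1), the standard mode-jumping move that lets a chain hop
#' between separated posterior modes along the ensemble's difference
#' vectors.
#'
#' @param i Index of the chain being updated.
#' @param chains Matrix of current positions (chains in rows).
#' @param gamma Difference scaling (default `2.38 / sqrt(2 k)`).
#' @param jitter Half-width of the uniform jitter.
#' @param gamma2_prob Probability of a mode-jumping proposal (default 0.1).
#' @param gamma2 Scaling of mode-jumping proposals (default 0.98).
#' @return The proposal vector.
#' @export
de_propose <- function(i, chains, gamma = 2.38 / sqrt(2 * ncol(chains)),
                       jitter = 1e-3, gamma2_prob = 0.1, gamma2 = 0.98) {
  stopifnot(nrow(chains) >= 3)
  others <- seq_len(nrow(chains))[-i]
  r <- sample(others, 2)
  g <- if (gamma2_prob > 0 && runif(1) < gamma2_prob) gamma2 else gamma
  chains[i, ] + g * (chains[r[1], ] - chains[r[2], ]) +
    runif(ncol(chains), -jitter, jitter)
}

#' Reset outlying chains to the ensemble bulk
#'
#' A chain is an outlier when its mean position falls outside
#' `mean +/- 1.96 sd` of the across-chain mean positions in any dimension;
#' outliers are moved to the current position of a randomly chosen
#' non-outlier chain.
#'
#' @param positions Matrix of current chain positions (chains in rows).
#' @param chain_means Matrix of per-chain mean positions accumulated so far
#'   (defaults to `positions`).
#' @return A list with the updated `positions` and the integer vector
#'   `reset` of chain indices that were re-positioned.
#' @export
reset_outliers <- function(positions, chain_means = positions) {
  m <- colMeans(chain_means)
  s <- apply(chain_means, 2, sd)
  s[s == 0] <- Inf  # a degenerate dimension flags no outliers
  out <- apply(chain_means, 1, function(x) any(abs(x - m) > 1.96 * s))
  idx <- which(out)
  if (length(idx) > 0 && length(idx) < nrow(positions)) {
    donors <- sample(which(!out), length(idx), replace = TRUE)
    positions[idx, ] <- positions[donors, , drop = FALSE]
  } else {
    idx <- integer(0)
  }
  list(positions = positions, reset = idx)
}

#' Migration move over an ensemble of chains
#'
#' Cyclically offers each chain of a uniformly sized random subset the
#' state of its successor in the cycle, accepting each swap by
#' Metropolis-Hastings on the stored log posteriors (no new likelihood
#' evaluations).  Replaces the differential-evolution sweep on a random
#' fraction of iterations to improve mixing across modes.
#'
#' @param positions Matrix of chain positions (chains in rows).
#' @param log_posts Stored log-posterior values per chain.
#' @return A list with updated `positions`, `log_posts`, and `moved`, the
#'   indices of chains that adopted a new state.
#' @export
migrate_chains <- function(positions, log_posts) {
  nc <- nrow(positions)
  m <- sample.int(nc, 1)
  idx <- sample.int(nc, m)
  old_pos <- positions[idx, , drop = FALSE]
  old_lp <- log_posts[idx]
  nxt <- c(seq_len(m)[-1], 1L)
  moved <- integer(0)
  for (t in seq_len(m)) {
    if (log(runif(1)) < old_lp[nxt[t]] - log_posts[idx[t]]) {
      positions[idx[t], ] <- old_pos[nxt[t], ]
      log_posts[idx[t]] <- old_lp[nxt[t]]
      moved <- c(moved, idx[t])
    }
  }
  list(positions = positions, log_posts = log_posts, moved = moved)
}

#' Run the DEMCMC sampler on a log-posterior function
#'
#' The generic engine behind [addm()]: initialises chains from the prior (or
#' `init`), alternates differential-evolution sweeps with probabilistic
#' migration, applies the stuck-chain likelihood refresh and the mid-burn-in
#' outlier reset, and returns the kept draws.
#'
#' @param log_post Function taking a length-`k` numeric vector and returning
#'   the log posterior density (may be stochastic for simulation-based
#'   likelihoods); non-finite values are treated as `-Inf`.
#' @param k Parameter dimension.
#' @param settings A [sampler_settings()] object.
#' @param init Optional initial positions (`n_chains x k` matrix); defaults
#'   to draws from the N(0, 0.5) prior.
#' @param noisy Whether `log_post` is stochastic; enables the stuck-chain
#'   refresh (default `TRUE`).
#' @return A list with `draws` (array `n_keep x n_chains x k`),
#'   `accept_rate`, `n_migrations`, `reset_chains` and the final
#'   log-posterior values.
#' @export
demcmc <- function(log_post, k, settings = sampler_settings(k = k),
                   init = NULL, noisy = TRUE) {
  nc <- settings$n_chains
  pos <- if (is.null(init)) {
    matrix(rnorm(nc * k, 0, sqrt(0.5)), nc, k)
  } else {
    stopifnot(nrow(init) == nc, ncol(init) == k)
    init
  }
  lp <- apply(pos, 1, function(u) {
    v <- log_post(u)
    if (is.finite(v)) v else -Inf
  })
  stuck <- integer(nc)
  n_acc <- 0L
  n_prop <- 0L
  n_migrations <- 0L
  reset_chains <- integer(0)
  mean_acc <- matrix(0, nc, k)  # running sums for burn-in chain means
  n_iter <- settings$n_burn + settings$n_keep
  draws <- array(NA_real_, c(settings$n_keep, nc, k))

  for (it in seq_len(n_iter)) {
    if (runif(1) < settings$migrate_prob) {
      n_migrations <- n_migrations + 1L
      mg <- migrate_chains(pos, lp)
      pos <- mg$positions
      lp <- mg$log_posts
      stuck[mg$moved] <- 0L
    } else {
      for (i in seq_len(nc)) {
        prop <- de_propose(i, pos, settings$gamma, settings$jitter,
                           settings$gamma2_prob, settings$gamma2)
        lp_prop <- log_post(prop)
        if (!is.finite(lp_prop)) lp_prop <- -Inf
        n_prop <- n_prop + 1L
        if (log(runif(1)) < lp_prop - lp[i]) {
          pos[i, ] <- prop
          lp[i] <- lp_prop
          stuck[i] <- 0L
          n_acc <- n_acc + 1L
        } else {
          stuck[i] <- stuck[i] + 1L
          if (noisy && stuck[i] >= settings$stuck_limit) {
            lp[i] <- log_post(pos[i, ])  # fresh simulations for the current set
            if (!is.finite(lp[i])) lp[i] <- -Inf
            stuck[i] <- 0L
          }
        }
      }
    }
    if (it <= settings$n_burn) {
      mean_acc <- mean_acc + pos
      if (it == settings$reset_at) {
        r <- reset_outliers(pos, mean_acc / it)
        if (length(r$reset) > 0) {
          lp[r$reset] <- apply(r$positions[r$reset, , drop = FALSE], 1,
                               log_post)
          reset_chains <- r$reset
          pos <- r$positions
        }
      }
    } else {
      draws[it - settings$n_burn, , ] <- pos
    }
  }
  list(draws = draws,
       accept_rate = if (n_prop > 0) n_acc / n_prop else NA_real_,
       n_migrations = n_migrations,
       reset_chains = reset_chains,
       log_post = lp)
}

#' Gelman-Rubin potential scale reduction
#'
#' The classic between/within-chain variance ratio computed per parameter on
#' the kept draws; values below 1.1 are taken as converged.
#'
#' @param draws Array `n_iter x n_chains x n_params` (a matrix is treated as
#'   a single parameter).
#' @return Named numeric vector of R-hat values (`Inf` where the
#'   within-chain variance is zero).
#' @export
gelman_rubin <- function(draws) {
  if (is.matrix(draws)) draws <- array(draws, c(dim(draws), 1))
  stopifnot(length(dim(draws)) == 3, dim(draws)[1] >= 2, dim(draws)[2] >= 2)
  n <- dim(draws)[1]
  m <- dim(draws)[2]
  k <- dim(draws)[3]
  out <- numeric(k)
  for (j in seq_len(k)) {
    x <- draws[, , j]
    means <- colMeans(x)
    vars <- apply(x, 2, stats::var)
    W <- mean(vars)
    B <- n * stats::var(means)
    if (W <= 0) {
      out[j] <- if (B > 0) Inf else NA_real_
    } else {
      var_plus <- (n - 1) / n * W + B / n
      out[j] <- sqrt(var_plus / W)
    }
  }
  names(out) <- dimnames(draws)[[3]]
  out
}

#' Fit the gaze-informed ADDM or static DDM to one subject
#'
#' Estimates the 16 unconstrained parameters (8 predispositions and 8
#' time-pressure effects) of the chosen model for a single subject's trials
#' by DEMCMC with the probit-uniform prior and the simulation-based KDE
#' likelihood, fitting both conditions simultaneously.  Parameter estimates
#' are the means of the posterior distributions mapped to model space.
#'
#' @param trials A trials table for one subject (see [addm_trials()]).
#' @param fixations A fixations table for the same subject (gaze model), or
#'   `NULL` for the static model.
#' @param model `"gaze"` or `"static"`.
#' @param preset Sampler preset passed to [sampler_settings()].
#' @param settings A [sampler_settings()] object (overrides `preset`).
#' @param timelines Optional pre-built list of per-trial gaze timelines (in
#'   the row order of `trials`); built from `fixations` otherwise.
#' @param extend_gaze Extend timelines that end before the deadline with
#'   [extend_timeline()] instead of failing.
#' @param verbose Print progress.
#' @return An object of class `"addm_fit"` with components `estimates`
#'   (posterior-mean parameters, one column per condition), `draws`
#'   (unconstrained posterior draws, `n_keep x n_chains x 16`), `rhat`,
#'   `converged`, `accept_rate`, and the sampler log.  Methods: `print`,
#'   `summary`, `coef`, `predict`, `simulate`, `residuals`, `plot`.
#' @seealso [sampler_settings()], [gelman_rubin()], [quantile_ppc()]
#' @export
addm <- function(trials, fixations = NULL, model = c("gaze", "static"),
                 preset = "scaled_down", settings = NULL, timelines = NULL,
                 extend_gaze = FALSE, verbose = FALSE) {
  model <- match.arg(model)
  trials <- addm_trials(trials)
  subjects <- unique(trials$subject)
  if (length(subjects) != 1) {
    stop("addm() fits one subject at a time; see run_fit() for batches",
         call. = FALSE)
  }
  screen <- exclusion_screen(trials)
  if (!screen$keep[1]) {
    warning("subject ", subjects, " gives the same response on more than ",
            "90% of responded trials (", screen$reason[1],
            "); estimates may be poorly constrained", call. = FALSE)
  }
  if (model == "gaze") {
    if (is.null(timelines)) {
      if (is.null(fixations)) {
        stop("the gaze model needs fixations (or pre-built timelines)",
             call. = FALSE)
      }
      timelines <- timelines_from_fixations(fixations, trials,
                                            extend = extend_gaze)
    } else if (extend_gaze) {
      dl <- deadline_s(trials$condition) * 1000
      timelines <- lapply(seq_along(timelines), function(i) {
        extend_timeline(timelines[[i]], dl[i])
      })
    }
  }
  k <- 16L
  if (is.null(settings)) settings <- sampler_settings(preset, k = k)
  sim <- sim_settings(dt_ms = settings$dt_ms)
  dat <- prepare_subject_data(trials, timelines, model)
  gaze <- model == "gaze"
  log_post <- function(u) {
    pv <- u_to_parvecs(u, model)
    ll <- cpp_dataset_loglik(pv$high, pv$low, gaze, dat$self, dat$other,
                             dat$deadline, dat$cond, dat$obs_choice,
                             dat$obs_rt, dat$seg_aoi, dat$seg_on,
                             dat$seg_off, dat$ptr,
                             as.integer(settings$n_sims),
                             sim$dt_ms / 1000, sim$noise_sd, LIK_EPS,
                             FALLBACK_BW, next_seed())
    log_prior(u) + ll
  }
  if (verbose) {
    message(sprintf("fitting %s model to subject %s: %d trials, %d chains, %d+%d iterations, %d sims/trial",
                    model, subjects, nrow(trials), settings$n_chains,
                    settings$n_burn, settings$n_keep, settings$n_sims))
  }
  run <- demcmc(log_post, k, settings, noisy = TRUE)
  dimnames(run$draws) <- list(NULL, NULL, u_names(model))

  # posterior means in model space, per condition
  flat <- matrix(run$draws, ncol = k)
  nms <- base_param_names(model)
  est <- matrix(NA_real_, 8, 2, dimnames = list(nms, c("HIGH", "LOW")))
  for (j in 1:8) {
    est[j, "HIGH"] <- mean(scale_to_bounds(pnorm(flat[, j] + flat[, j + 8]),
                                           nms[j]))
    est[j, "LOW"] <- mean(scale_to_bounds(pnorm(flat[, j] - flat[, j + 8]),
                                          nms[j]))
  }
  rhat <- gelman_rubin(run$draws)
  structure(list(
    call = match.call(),
    model = model,
    subject = subjects,
    n_trials = nrow(trials),
    estimates = est,
    u_mean = colMeans(flat),
    draws = run$draws,
    rhat = rhat,
    converged = all(rhat < 1.1),
    accept_rate = run$accept_rate,
    n_migrations = run$n_migrations,
    reset_chains = run$reset_chains,
    settings = settings,
    sim = sim,
    trials = trials,
    timelines = timelines
  ), class = "addm_fit")
}

# condition-specific parameter object from a fit's posterior means
fit_params <- function(fit, condition) {
  vals <- fit$estimates[, condition]
  if (fit$model == "gaze") {
    do.call(addm_params, as.list(vals))
  } else {
    do.call(static_params, as.list(vals))
  }
}
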