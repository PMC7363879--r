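test_that("differential-evolution proposals degenerate correctly", {
  chains <- matrix(rep(c(1, 2), each = 5), 5, 2)
  # identical ensemble and zero jitter: proposal equals the current position
  expect_equal(de_propose(1, chains, gamma = 1, jitter = 0), chains[1, ])
  # gamma = 0 leaves only jitter
  set.seed(41)
  chains2 <- matrix(rnorm(10), 5, 2)
  prop <- de_propose(2, chains2, gamma = 0, jitter = 1e-3, gamma2_prob = 0)
  expect_lt(max(abs(prop - chains2[2, ])), 1e-3 + 1e-12)
})

test_that("outlier reset moves only stray chains", {
  # an evenly spread ensemble (max deviation ~1.7 sd) has no outliers
  set.seed(42)
  pos <- matrix(rep(seq(-1, 1, length.out = 20), 3), 20, 3)
  r <- reset_outliers(pos, pos)
  expect_equal(length(r$reset), 0)
  expect_equal(r$positions, pos)
  pos[7, ] <- c(100, 0, 0)
  r2 <- reset_outliers(pos, pos)
  expect_true(7 %in% r2$reset)
  expect_lt(max(abs(r2$positions[7, ])), 10)
})

test_that("R-hat separates mixed from unmixed chains and is affine invariant", {
  set.seed(43)
  mixed <- array(rnorm(200 * 4 * 2), c(200, 4, 2))
  rh <- gelman_rubin(mixed)
  expect_true(all(rh < 1.1))
  split <- mixed
  split[, 1:2, 1] <- split[, 1:2, 1] + 10  # two chains at a distant mode
  expect_gt(gelman_rubin(split)[1], 2)
  # common affine rescaling leaves R-hat unchanged
  expect_equal(gelman_rubin(mixed * 3.7 + 2), rh, tolerance = 1e-12)
  # zero within-chain variance is degenerate
  const <- array(rep(c(0, 1), each = 50), c(50, 2, 1))
  expect_equal(unname(gelman_rubin(const)), Inf)
})

test_that("stuck-chain refresh re-evaluates the stored likelihood", {
  # a sharply peaked target rejects nearly every proposal; with a noisy
  # likelihood the engine must call log_post more often than once per
  # proposal because stuck chains get their current value refreshed
  counter_noisy <- 0
  lp_noisy <- function(u) {
    counter_noisy <<- counter_noisy + 1
    -1e6 * sum(u^2) + rnorm(1, 0, 0.1)
  }
  counter_exact <- 0
  lp_exact <- function(u) {
    counter_exact <<- counter_exact + 1
    -1e6 * sum(u^2)
  }
  s <- sampler_settings("mini", k = 2, n_chains = 6, n_burn = 20,
                        n_keep = 30, migrate_prob = 0)
  set.seed(44)
  demcmc(lp_noisy, 2, s, noisy = TRUE)
  set.seed(44)
  demcmc(lp_exact, 2, s, noisy = FALSE)
  base_calls <- 6 * (20 + 30) + 6  # one per proposal plus initialisation
  expect_equal(counter_exact, base_calls)
  expect_gt(counter_noisy, base_calls + 20)
})

test_that("the sampler recovers a known bivariate Gaussian posterior", {
  # exact-likelihood conjugate oracle: target N(mu, diag(sigma2))
  mu <- c(1, -0.5)
  sigma2 <- c(0.3, 0.15)
  log_post <- function(u) sum(dnorm(u, mu, sqrt(sigma2), log = TRUE))
  set.seed(45)
  s <- sampler_settings("mini", k = 2, n_chains = 12, n_burn = 300,
                        n_keep = 400)
  run <- demcmc(log_post, 2, s, noisy = FALSE)
  flat <- matrix(run$draws, ncol = 2)
  for (j in 1:2) {
    chain_means <- colMeans(run$draws[, , j])
    mcse <- sd(chain_means) / sqrt(length(chain_means))
    expect_lt(abs(mean(flat[, j]) - mu[j]), 3 * mcse + 0.02)
    expect_equal(sd(flat[, j]), sqrt(sigma2[j]), tolerance = 0.15)
  }
  expect_true(all(gelman_rubin(run$draws) < 1.1))
  expect_gt(run$accept_rate, 0.1)
  expect_lt(run$accept_rate, 0.6)
})

test_that("migration leaves an equal ensemble invariant and mixes states", {
  # direct move: equal ensemble is invariant; a strictly better successor
  # state is always adopted
  set.seed(40)
  eq <- migrate_chains(matrix(1, 5, 2), rep(-3, 5))
  expect_true(all(eq$positions == 1))
  expect_equal(eq$log_posts, rep(-3, 5))
  # all chains identical: migration must not change anything
  lp <- function(u) sum(dnorm(u, log = TRUE))
  s <- sampler_settings("mini", k = 2, n_chains = 6, n_burn = 2, n_keep = 3,
                        migrate_prob = 1, gamma = 0, jitter = 0)
  set.seed(46)
  init <- matrix(rep(c(0.3, -0.2), each = 6), 6, 2)
  run <- demcmc(lp, 2, s, init = init, noisy = FALSE)
  expect_true(all(apply(run$draws, c(1, 3), function(x) length(unique(x))) ==
                    1))
  expect_gt(run$n_migrations, 0)
})

test_that("fitting is reproducible under a fixed seed", {
  study <- gen_study(generative_config(n_subjects = 1,
                                       trials_per_condition = 6), seed = 47)
  s <- sampler_settings("mini", n_chains = 18, n_burn = 10, n_keep = 10,
                        n_sims = 30)
  set.seed(48)
  f1 <- addm(study$trials, model = "gaze", settings = s,
             timelines = study$timelines)
  set.seed(48)
  f2 <- addm(study$trials, model = "gaze", settings = s,
             timelines = study$timelines)
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$estimates, f2$estimates)
  # posterior draws map into the parameter box
  expect_true(all(f1$estimates >= param_bounds()[rownames(f1$estimates), "min"]))
  expect_true(all(f1$estimates <= param_bounds()[rownames(f1$estimates), "max"]))
  # methods run
  expect_output(print(f1), "Gaze-informed ADDM")
  expect_equal(dim(coef(f1)), c(8, 2))
  pred <- predict(f1, n_sims = 50)
  expect_equal(nrow(pred), nrow(study$trials))
  expect_true(all(abs(pred$p_accept + pred$p_reject + pred$p_missed - 1) <
                    1e-12))
  sims <- simulate(f1, nsim = 2, seed = 1)
  expect_length(sims, 2)
  expect_equal(nrow(sims[[1]]), nrow(study$trials))
})

test_that("a response-invariant subject triggers the exclusion warning", {
  study <- gen_study(generative_config(n_subjects = 1,
                                       trials_per_condition = 6), seed = 49)
  tr <- study$trials
  tr$choice <- "ACCEPT"
  tr$rt[is.na(tr$rt)] <- 0.5
  s <- sampler_settings("mini", n_chains = 18, n_burn = 4, n_keep = 4,
                        n_sims = 20)
  expect_warning(
    addm(tr, model = "gaze", settings = s, timelines = study$timelines),
    "90%")
})
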