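test_that("halved Silverman bandwidth matches the closed form and scaling law", {
  set.seed(21)
  x <- rnorm(1000)
  a <- min(sd(x), IQR(x) / 1.34)
  expect_equal(silverman_bandwidth(x), 0.5 * 0.9 * a * 1000^(-0.2))
  # standard normal sample: approximately 0.5 * 0.9 * 1000^(-1/5)
  expect_equal(silverman_bandwidth(x), 0.1133, tolerance = 0.05)
  # doubling n multiplies the bandwidth by 2^(-1/5)
  y <- rep(x, 2)
  expect_equal(silverman_bandwidth(y) / silverman_bandwidth(x), 2^(-0.2),
               tolerance = 1e-10)
  # degenerate inputs fall back to the fixed bandwidth
  expect_equal(silverman_bandwidth(rep(0.4, 50)), 0.010)
  expect_equal(silverman_bandwidth(numeric(0)), 0.010)
  expect_equal(silverman_bandwidth(0.3), 0.010)
})

fake_sample <- function(accept, reject, miss) {
  structure(list(accept_rts = accept, reject_rts = reject,
                 n_missed = miss,
                 n_total = length(accept) + length(reject) + miss),
            class = "predictive_sample")
}

test_that("trial likelihood weights class KDE by class frequency and floors at eps", {
  set.seed(22)
  acc <- rnorm(600, 0.5, 0.05)
  rej <- rnorm(300, 0.7, 0.05)
  ps <- fake_sample(acc, rej, 100)
  h <- silverman_bandwidth(acc)
  expect_equal(trial_likelihood(ps, "ACCEPT", 0.5),
               0.6 * mean(dnorm(0.5, acc, h)))
  expect_equal(trial_likelihood(ps, "MISSED"), 0.1)
  # density at the mode of a dense cloud dwarfs the floor
  expect_gt(trial_likelihood(ps, "ACCEPT", 0.5), 1)
  # observed response with no simulated analogue hits the floor
  none <- fake_sample(acc, numeric(0), 0)
  expect_equal(trial_likelihood(none, "REJECT", 0.6), 1e-10)
  zero_miss <- fake_sample(acc, rej, 0)
  expect_equal(trial_likelihood(zero_miss, "MISSED"), 1e-10)
})

test_that("compiled KDE likelihood agrees exactly with the R composition", {
  set.seed(23)
  for (rep in 1:10) {
    acc <- round(rnorm(sample(c(0, 3, 120), 1), 0.5, 0.08), 3)
    rej <- round(rnorm(sample(c(0, 2, 80), 1), 0.8, 0.1), 3)
    miss <- sample(0:20, 1)
    ps <- fake_sample(acc, rej, miss)
    for (case in list(list("ACCEPT", 0.51), list("REJECT", 0.79),
                      list("MISSED", NA))) {
      r_val <- log(trial_likelihood(ps, case[[1]], case[[2]]))
      cpp_val <- gaddm:::cpp_kde_loglik(
        acc, rej, miss, ps$n_total,
        match(case[[1]], c("ACCEPT", "REJECT", "MISSED")) - 1L,
        ifelse(is.na(case[[2]]), -1, case[[2]]), 1e-10, 0.010)
      expect_equal(cpp_val, r_val, tolerance = 1e-12)
    }
  }
})

test_that("predictive draws partition the simulations and respect censoring", {
  study <- gen_study(generative_config(n_subjects = 1,
                                       trials_per_condition = 2), seed = 5)
  p <- study$truth$S01$params$HIGH
  tl <- study$timelines[[1]]
  set.seed(24)
  ps <- draw_predictive(p, 20, 80, "HIGH", tl, n_sims = 500)
  expect_equal(length(ps$accept_rts) + length(ps$reject_rts) + ps$n_missed,
               500)
  # strong drift towards accepting a generous proposal (the threshold is
  # high enough that noise rarely crosses during the percept window)
  p_strong <- addm_params(w_other = 0.1, theta = 0, b = 0.5, d = 1)
  ps2 <- draw_predictive(p_strong, 0, 100, "HIGH",
                         flat_timeline("OTHER", 1500), n_sims = 500)
  expect_gt(length(ps2$accept_rts) / 500, 0.85)
  # determinism under seed
  set.seed(25)
  a <- draw_predictive(p, 20, 80, "HIGH", tl, n_sims = 200)
  set.seed(25)
  b <- draw_predictive(p, 20, 80, "HIGH", tl, n_sims = 200)
  expect_identical(a, b)
})

test_that("likelihood mass is conserved across choice classes", {
  # accept density + reject density + missed mass integrates to 1
  set.seed(26)
  study <- gen_study(generative_config(n_subjects = 1,
                                       trials_per_condition = 4), seed = 26)
  grid <- seq(-2, 12, by = 0.002)
  for (i in sample(nrow(study$trials), 5)) {
    tr <- study$trials[i, ]
    u <- rnorm(16, 0, sqrt(0.5))
    p <- to_model_space(u[1:8], u[9:16], toupper(tr$condition))
    ps <- draw_predictive(p, tr$self, tr$other, tr$condition,
                          study$timelines[[i]], n_sims = 1000)
    dens_mass <- function(rts) {
      if (length(rts) == 0) return(0)
      h <- silverman_bandwidth(rts)
      (length(rts) / ps$n_total) *
        sum(vapply(grid, function(g) mean(dnorm(g, rts, h)),
                   numeric(1))) * 0.002
    }
    total <- dens_mass(ps$accept_rts) + dens_mass(ps$reject_rts) +
      ps$n_missed / ps$n_total
    expect_equal(total, 1, tolerance = 0.02)
  }
})

test_that("dataset log-likelihood is finite over the box and prefers the truth", {
  study <- gen_study(generative_config(n_subjects = 1,
                                       trials_per_condition = 40), seed = 27)
  ph <- study$truth$S01$params$HIGH
  pl <- study$truth$S01$params$LOW
  set.seed(28)
  # finiteness at random box corners
  for (rep in 1:5) {
    u <- runif(16, -3, 3)
    ph_r <- to_model_space(u[1:8], u[9:16], "HIGH")
    pl_r <- to_model_space(u[1:8], u[9:16], "LOW")
    ll <- dataset_loglik(ph_r, pl_r, study$trials, study$timelines,
                         n_sims = 60, settings = sim_settings(dt_ms = 5))
    expect_true(is.finite(ll))
  }
  # true parameters beat a grossly wrong point (repeated noisy evaluations)
  wrong_h <- addm_params(w_self = 0.1, w_other = -0.1, b = 0.02, d = 2.5,
                         stbias = -0.5, genbias = 0.5, theta = 1)
  wrong_l <- wrong_h
  ll_true <- mean(replicate(3, dataset_loglik(
    ph, pl, study$trials, study$timelines, n_sims = 150,
    settings = sim_settings(dt_ms = 5))))
  ll_wrong <- mean(replicate(3, dataset_loglik(
    wrong_h, wrong_l, study$trials, study$timelines, n_sims = 150,
    settings = sim_settings(dt_ms = 5))))
  expect_gt(ll_true, ll_wrong + 50)
  # empty data has zero log-likelihood
  expect_equal(dataset_loglik(ph, pl, study$trials[0, ], list()), 0)
})

test_that("the per-trial likelihood table matches direct evaluation", {
  study <- gen_study(generative_config(n_subjects = 1,
                                       trials_per_condition = 3), seed = 29)
  ph <- study$truth$S01$params$HIGH
  pl <- study$truth$S01$params$LOW
  set.seed(30)
  tab <- likelihood_table(ph, pl, study$trials, study$timelines, n_sims = 80,
                          settings = sim_settings(dt_ms = 5))
  expect_equal(nrow(tab), nrow(study$trials))
  expect_true(all(tab$likelihood >= 1e-10))
  expect_equal(tab$loglik, log(tab$likelihood))
  expect_true(all(abs(tab$p_accept + tab$p_reject + tab$p_missed - 1) <
                    1e-12))
})
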