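test_that("boundary decay follows the closed form", {
  expect_equal(boundary_at(0.3, 1.7, 0), 0.3)
  expect_equal(boundary_at(0.3, 0, 5), 0.3)
  expect_equal(boundary_at(0.5, 2.5, 1), 0.5 * exp(-2.5))
  expect_error(boundary_at(0.3, 1, -1))
})

test_that("starting point combines response and generosity biases by favoured party", {
  p <- addm_params(stbias = 0.1, genbias = -0.05)
  expect_equal(starting_point(p, 40, 70), 0.05)
  expect_equal(starting_point(p, 70, 40), 0.15)
  expect_equal(starting_point(p, 50, 50), 0.1)
  expect_equal(starting_point(addm_params(), 30, 80), 0)
})

test_that("momentary drift gates unseen attributes and discounts unattended ones", {
  p <- addm_params(w_self = 0.05, w_other = 0.03, w_fairness = 0.02,
                   theta = 1)
  # only Self seen, gaze on Self: no discount, other terms gated off
  expect_equal(momentary_drift(p, 80, 20, "SELF", TRUE, FALSE), 4.0)
  # both seen, gaze on Self with full discount: other weight killed,
  # fairness carries no attention factor
  expect_equal(momentary_drift(p, 80, 20, "SELF", TRUE, TRUE),
               0.05 * 80 + 0 * 0.03 * 20 + 0.02 * 60)
  # percept window with no prior information contributes nothing
  expect_equal(momentary_drift(p, 80, 20, "SELF", FALSE, FALSE,
                               in_percept = TRUE), 0)
  # percept window with prior Self: (1 - theta) * w_self * Self
  p2 <- addm_params(w_self = 0.05, theta = 0.4)
  expect_equal(momentary_drift(p2, 80, 20, "OTHER", TRUE, FALSE,
                               in_percept = TRUE), 0.6 * 0.05 * 80)
  # theta = 0 makes gaze position irrelevant
  p3 <- addm_params(w_self = 0.05, w_other = 0.03, w_fairness = 0.02,
                    theta = 0)
  for (aoi in c("SELF", "OTHER", "NEITHER")) {
    expect_equal(momentary_drift(p3, 80, 20, aoi, TRUE, TRUE),
                 0.05 * 80 + 0.03 * 20 + 0.02 * 60)
  }
})

test_that("compiled drift plan matches the R drift function step by step", {
  set.seed(31)
  dt_ms <- 5
  for (rep in 1:10) {
    p <- addm_params(w_self = runif(1, -0.1, 0.1),
                     w_other = runif(1, -0.1, 0.1),
                     w_fairness = runif(1, -0.1, 0.1),
                     theta = runif(1))
    cuts <- sort(sample(seq(20, 1480, 20), 4))
    fx <- data.frame(aoi = sample(c("SELF", "OTHER"), 2),
                     onset = cuts[c(1, 3)], offset = cuts[c(2, 4)])
    tl <- build_timeline(fx, 1500)
    tc <- gaddm:::timeline_codes(tl)
    self <- sample(0:100, 1)
    other <- sample(0:100, 1)
    mu_cpp <- gaddm:::cpp_drift_series(gaddm:::par_vec(p), TRUE, self, other,
                                       1.5, tc$aoi, tc$onset, tc$offset,
                                       dt_ms / 1000)
    # reconstruct the drift series with the R-level pieces
    entry <- function(aoi) {
      seg <- tl[tl$aoi == aoi, ]
      if (nrow(seg) == 0) Inf else seg$onset[1]
    }
    es <- entry("SELF")
    eo <- entry("OTHER")
    pms <- p$percept * 1000
    mu_r <- vapply(seq_along(mu_cpp), function(i) {
      t <- (i - 1) * dt_ms
      seg <- tl[tl$onset <= t & t < tl$offset, ]
      aoi <- if (nrow(seg) > 0) seg$aoi[1] else "NEITHER"
      in_w <- (t >= es && t < es + pms) || (t >= eo && t < eo + pms)
      momentary_drift(p, self, other, aoi,
                      seen_self = es + pms <= t, seen_other = eo + pms <= t,
                      in_percept = in_w)
    }, numeric(1))
    expect_equal(mu_cpp, mu_r, tolerance = 1e-12)
  }
})

test_that("degenerate threshold terminates immediately with motor-only RT", {
  set.seed(5)
  tl <- flat_timeline("NEITHER", 1500)
  p <- addm_params(b = 0, d = 0, stbias = 0, genbias = 0)
  out <- simulate_trial(p, 40, 70, "HIGH", tl, n_sims = 200)
  expect_true(all(out$decision_time == 0))
  expect_true(all(out$rt == p$motor))
  expect_true(all(out$n_unique_fixated == 0))
  # both responses occur at the unbiased tie
  expect_true(all(c("ACCEPT", "REJECT") %in% out$choice))
})

test_that("RT decomposes into decision time plus latencies", {
  set.seed(6)
  fx <- data.frame(aoi = c("SELF", "OTHER"), onset = c(100, 500),
                   offset = c(500, 1500))
  tl <- build_timeline(fx, 1500)
  p <- addm_params(w_self = 0.04, w_other = 0.04, b = 0.4, theta = 0.3)
  out <- simulate_trial(p, 70, 40, "HIGH", tl, n_sims = 500)
  resp <- out[out$choice != "MISSED", ]
  expect_equal(resp$rt,
               resp$decision_time + p$motor +
                 resp$n_unique_fixated * p$percept)
  # outcome frequencies over all simulations partition the sample
  expect_equal(nrow(out), 500)
  expect_true(all(out$choice %in% c("ACCEPT", "REJECT", "MISSED")))
})

test_that("drift sign drives the majority choice and grows with the weight", {
  set.seed(8)
  tl <- flat_timeline("SELF", 1500)
  acc <- vapply(c(0.02, 0.06), function(w) {
    p <- addm_params(w_self = w, theta = 0, d = 0, b = 0.3)
    mean(simulate_trial(p, 80, 20, "HIGH", tl,
                        sim_settings(noise_sd = 1),
                        n_sims = 2000)$choice == "ACCEPT")
  }, numeric(1))
  expect_gt(acc[1], 0.5)
  expect_gt(acc[2], acc[1])
})

test_that("no mean drift accrues before the first fixation", {
  # gaze arrives only at 800 ms; with huge weights the accumulator must
  # still be driven by noise alone before then
  set.seed(9)
  fx <- data.frame(aoi = "SELF", onset = 800, offset = 10000)
  tl <- build_timeline(fx, 10000)
  p <- addm_params(w_self = 0.1, b = 0.5, d = 0, theta = 0)
  out <- simulate_trial(p, 100, 0, "LOW", tl, sim_settings(noise_sd = 1),
                        n_sims = 3000)
  early <- out[out$decision_time < 0.8 & out$choice != "MISSED", ]
  # pre-fixation crossings are symmetric noise crossings
  expect_gt(nrow(early), 100)
  expect_lt(abs(mean(early$choice == "ACCEPT") - 0.5), 0.05)
  # after information arrives the strong positive drift dominates
  late <- out[out$decision_time > 1.0, ]
  expect_gt(mean(late$choice == "ACCEPT"), 0.9)
})

test_that("attention discount makes gaze matter exactly when theta > 0", {
  # both timelines fixate both AOIs at the same moments (so information
  # gating and percept windows are identical) and then diverge: one dwells
  # on OTHER for the rest of the trial, the other on SELF
  diverging <- function(rest) {
    build_timeline(data.frame(aoi = c("SELF", "OTHER", rest),
                              onset = c(0, 80, 160),
                              offset = c(80, 160, 10000)), 10000)
  }
  tl_other <- diverging("OTHER")
  tl_self <- diverging("SELF")
  p_theta <- addm_params(w_other = 0.1, b = 0.5, d = 0, theta = 0.8)
  s1 <- sim_settings(noise_sd = 1)
  set.seed(10)
  acc_other <- mean(simulate_trial(p_theta, 0, 100, "LOW", tl_other, s1,
                                   n_sims = 3000)$choice == "ACCEPT")
  acc_self <- mean(simulate_trial(p_theta, 0, 100, "LOW", tl_self, s1,
                                  n_sims = 3000)$choice == "ACCEPT")
  expect_gt(acc_other, acc_self + 0.05)
  # with theta = 0 the two gaze patterns are distributionally identical
  p0 <- addm_params(w_other = 0.1, b = 0.5, d = 0, theta = 0)
  set.seed(11)
  a <- simulate_trial(p0, 20, 80, "LOW", tl_other, s1, n_sims = 4000)
  b <- simulate_trial(p0, 20, 80, "LOW", tl_self, s1, n_sims = 4000)
  expect_lt(abs(mean(a$choice == "ACCEPT") - mean(b$choice == "ACCEPT")),
            0.03)
  suppressWarnings(
    expect_gt(stats::ks.test(a$rt[a$choice == "ACCEPT"],
                             b$rt[b$choice == "ACCEPT"])$p.value, 0.01))
})

test_that("simulation is reproducible under a seed and vectorises over trials", {
  study <- gen_study(generative_config(n_subjects = 1,
                                       trials_per_condition = 5), seed = 3)
  ph <- study$truth$S01$params$HIGH
  pl <- study$truth$S01$params$LOW
  set.seed(99)
  a <- simulate_dataset(ph, pl, study$trials, study$timelines)
  set.seed(99)
  b <- simulate_dataset(ph, pl, study$trials, study$timelines)
  expect_identical(a, b)
  expect_equal(nrow(a), nrow(study$trials))
  empty <- simulate_dataset(ph, pl, study$trials[0, ], list())
  expect_equal(nrow(empty), 0)
})

test_that("a too-short timeline is rejected", {
  tl <- build_timeline(data.frame(aoi = "SELF", onset = 0, offset = 400), 400)
  expect_error(simulate_trial(addm_params(), 40, 70, "HIGH", tl),
               "covers only")
})

test_that("static model ignores gaze and adds its ndt to the decision time", {
  p <- static_params(w_self = 0.03, w_other = 0.02, b = 0.3, d = 0,
                     ndt = 0.3)
  set.seed(12)
  out <- simulate_trial_static(p, 80, 20, "LOW", n_sims = 1000)
  resp <- out[out$choice != "MISSED", ]
  expect_equal(resp$rt, resp$decision_time + 0.3)
  expect_true(all(resp$rt >= 0.3))
})

test_that("gaze model with theta 0, zero percept and full information matches the static model", {
  # distributional equivalence: same weights, motor standing in for ndt
  w <- 0.04
  b <- 0.3
  ndt <- 0.25
  p_gaze <- addm_params(w_self = w, b = b, d = 0.5, theta = 0,
                        percept = 0, motor = ndt)
  p_stat <- static_params(w_self = w, b = b, d = 0.5, ndt = ndt)
  tl <- flat_timeline("SELF", 10000)
  set.seed(13)
  g <- simulate_trial(p_gaze, 60, 30, "LOW", tl, n_sims = 8000)
  s <- simulate_trial_static(p_stat, 60, 30, "LOW", n_sims = 8000)
  expect_lt(abs(mean(g$choice == "ACCEPT") - mean(s$choice == "ACCEPT")),
            0.025)
  suppressWarnings(
    expect_gt(stats::ks.test(g$rt[g$choice == "ACCEPT"],
                             s$rt[s$choice == "ACCEPT"])$p.value, 0.01))
})

test_that("increasing other-regard weakly increases generosity", {
  set.seed(14)
  tl <- flat_timeline("OTHER", 10000)
  gen_rate <- vapply(c(0, 0.03, 0.08), function(w) {
    p <- addm_params(w_other = w, b = 0.3, d = 0.5, theta = 0.3)
    out <- simulate_trial(p, 20, 80, "LOW", tl, n_sims = 1500)
    mean(out$choice == "ACCEPT")  # accepting is the generous response here
  }, numeric(1))
  expect_true(all(diff(gen_rate) > -0.02))
  expect_gt(gen_rate[3], gen_rate[1])
})
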