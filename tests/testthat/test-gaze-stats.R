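make_fix <- function(subject, trial, aoi, on, off) {
  data.frame(subject = subject, trial = trial, aoi = aoi, onset_ms = on,
             offset_ms = off)
}

make_tr <- function(subject, trial, condition = "HIGH", rt = 1.4,
                    choice = "ACCEPT") {
  data.frame(subject = subject, trial = trial, self = 40, other = 70,
             condition = condition, choice = choice, rt = rt)
}

test_that("occupancy reflects dwell proportions and sums to one", {
  tr <- addm_trials(make_tr("s1", 1))
  fx <- make_fix("s1", 1, "SELF", 0, 1400)
  occ <- occupancy(tr, fx, "HIGH", horizon_ms = 500)
  expect_true(all(occ$p_self == 1))
  expect_true(all(occ$p_other == 0))
  tr2 <- addm_trials(rbind(make_tr("s1", 1), make_tr("s1", 2)))
  fx2 <- rbind(make_fix("s1", 1, "SELF", 0, 1400),
               make_fix("s1", 2, "OTHER", 0, 1400))
  occ2 <- occupancy(tr2, fx2, "HIGH", horizon_ms = 500)
  expect_true(all(occ2$p_self == 0.5))
  expect_true(all(occ2$p_other == 0.5))
  expect_equal(occ2$p_self + occ2$p_other + occ2$p_neither,
               matrix(1, 1, 500, dimnames = list("s1", NULL)))
})

test_that("trials stop contributing to occupancy at their RT", {
  tr <- addm_trials(rbind(make_tr("s1", 1, rt = 0.2),
                          make_tr("s1", 2, rt = 1.4)))
  fx <- rbind(make_fix("s1", 1, "SELF", 0, 1400),
              make_fix("s1", 2, "OTHER", 0, 1400))
  occ <- occupancy(tr, fx, "HIGH", horizon_ms = 400)
  # both trials active before 200 ms, only trial 2 afterwards
  expect_equal(unname(occ$n_active[1, 150]), 2)
  expect_equal(unname(occ$n_active[1, 350]), 1)
  expect_equal(unname(occ$p_self[1, 150]), 0.5)
  expect_equal(unname(occ$p_self[1, 350]), 0)
  expect_equal(unname(occ$p_other[1, 350]), 1)
  # the include_ended variant keeps them in the denominator as NEITHER
  occ2 <- occupancy(tr, fx, "HIGH", horizon_ms = 400, include_ended = TRUE)
  expect_equal(unname(occ2$n_active[1, 350]), 2)
  expect_equal(unname(occ2$p_neither[1, 350]), 0.5)
})

test_that("occupancy matches generator first-fixation rates", {
  set.seed(61)
  cfg <- generative_config(n_subjects = 1, trials_per_condition = 60)
  tls <- replicate(200, gen_gaze_timeline(0.8, 1500, cfg), simplify = FALSE)
  first <- vapply(tls, function(tl) first_fixation(tl, 0), character(1))
  expect_equal(mean(first == "SELF"), 0.8, tolerance = 0.08)
})

test_that("pointwise statistics behave under null and constructed bias", {
  set.seed(62)
  flat <- matrix(rnorm(10 * 50, 0, 0.01), 10, 50)
  pw <- pointwise_stat(flat, contrast = "BIAS")
  expect_gt(min(pw$p), 1e-4)  # no wild significance under a tiny-noise null
  biased <- flat + 0.3
  pw2 <- pointwise_stat(biased, contrast = "BIAS")
  expect_true(all(pw2$stat > 10))
  expect_true(all(pw2$p < 1e-6))
  # CONDITION contrast differences the two matrices
  pw3 <- pointwise_stat(biased, flat, contrast = "CONDITION")
  expect_true(all(pw3$stat > 10))
  expect_error(pointwise_stat(flat[1:2, , drop = FALSE]), "3 subjects")
})

test_that("cluster formation needs adjacency and a common sign", {
  p <- rep(1, 20)
  stat <- rep(0, 20)
  expect_equal(nrow(form_clusters(p, stat)), 0)
  # one isolated significant point is dropped
  p[5] <- 0.001
  stat[5] <- 5
  expect_equal(nrow(form_clusters(p, stat)), 0)
  # a run of 3 forms one cluster with summed mass
  p[10:12] <- 0.001
  stat[10:12] <- c(4, 5, 6)
  cl <- form_clusters(p, stat)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$start_ms, 9)
  expect_equal(cl$end_ms, 12)
  expect_equal(cl$mass, 15)
  # opposite signs split clusters
  stat[11] <- -5
  expect_equal(nrow(form_clusters(p, stat)), 0)  # runs of 1 each
  p[13] <- 0.001
  stat[13] <- 7
  cl2 <- form_clusters(p, stat)
  expect_equal(nrow(cl2), 1)
  expect_equal(cl2$mass, 13)
})

test_that("permutation test recovers an injected early bias", {
  set.seed(63)
  n_subj <- 12
  H <- 500
  x <- matrix(rnorm(n_subj * H, 0, 0.2), n_subj, H)
  x[, 1:300] <- x[, 1:300] + 0.4  # strong bias over the first 300 ms
  res <- permutation_tmax(x, contrast = "BIAS", n_perm = 500)
  expect_gt(nrow(res$clusters), 0)
  top <- res$clusters[which.max(res$clusters$mass), ]
  expect_lt(top$p, 0.05)
  expect_true(top$significant)
  expect_lt(top$start_ms, 300)
  expect_gt(top$end_ms, 250)
})

test_that("identically zero series yield no clusters under permutation", {
  x <- matrix(0, 8, 100)
  res <- permutation_tmax(x, contrast = "BIAS", n_perm = 200)
  expect_equal(nrow(res$clusters), 0)
  expect_equal(res$threshold, 0)
})

test_that("early gaze bias is the normalised dwell difference", {
  tl_self <- flat_timeline("SELF", 1500)
  expect_equal(early_gaze_bias(tl_self, rt = 1.0), 1)
  # responded before the window: normalise by the RT
  tl <- build_timeline(data.frame(aoi = "SELF", onset = 0, offset = 150),
                       1500)
  expect_equal(early_gaze_bias(tl, rt = 0.2), 150 / 200)
  # balanced gaze cancels
  tl_bal <- build_timeline(data.frame(aoi = c("SELF", "OTHER"),
                                      onset = c(0, 143),
                                      offset = c(143, 286)), 1500)
  expect_equal(early_gaze_bias(tl_bal, rt = 1.0), 0)
  # missed trials use the full window
  expect_equal(early_gaze_bias(tl_self, rt = NA), 1)
  expect_warning(out <- early_gaze_bias(tl_self, rt = 0), "zero")
  expect_true(is.na(out))
  # bounded in [-1, 1] over random timelines
  set.seed(64)
  cfg <- generative_config()
  for (i in 1:20) {
    tl_r <- gen_gaze_timeline(runif(1), 1500, cfg)
    v <- early_gaze_bias(tl_r, rt = runif(1, 0.1, 1.4))
    expect_gte(v, -1)
    expect_lte(v, 1)
  }
})

test_that("Brown-Forsythe matches the median-centred Levene test and ignores location", {
  set.seed(65)
  g1 <- rnorm(40, 0, 1)
  g2 <- rnorm(40, 5, 3)
  bf <- brown_forsythe(list(g1, g2))
  ref <- car::leveneTest(c(g1, g2), factor(rep(1:2, each = 40)),
                         center = median)
  expect_equal(bf$statistic, ref[1, "F value"], tolerance = 1e-10)
  expect_equal(bf$p.value, ref[1, "Pr(>F)"], tolerance = 1e-10)
  # location-free: shifting one group changes nothing
  bf2 <- brown_forsythe(list(g1 + 100, g2))
  expect_equal(bf2$statistic, bf$statistic, tolerance = 1e-10)
  expect_error(brown_forsythe(list(g1)), "length")
  expect_error(brown_forsythe(list(g1, 1)), "at least 2")
})

test_that("Brown-Forsythe detects a variance ratio of three at n = 50", {
  set.seed(66)
  rejections <- mean(replicate(40, {
    brown_forsythe(list(rnorm(50, 0, 1), rnorm(50, 0, 3)))$p.value < 0.05
  }))
  expect_gt(rejections, 0.9)
  # and stays near the nominal level under equal spread
  set.seed(67)
  level <- mean(replicate(60, {
    brown_forsythe(list(rnorm(50), rnorm(50)))$p.value < 0.05
  }))
  expect_lt(level, 0.15)
})
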