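# Feature extraction: window rules, analytic trace oracle, averaging
# properties, adaptation effects.

test_that("peak_constriction takes the window minimum over valid bins", {
  t_rel <- seq(-0.5, 2, by = 0.05)
  z <- rep(0, length(t_rel))
  expect_equal(peak_constriction(t_rel, z)$peak, 0)
  z[t_rel > 0.4 & t_rel < 0.6] <- c(-0.2, -0.9, -0.5)
  expect_equal(peak_constriction(t_rel, z)$peak, -0.9)
  z[] <- NA
  expect_true(is.na(peak_constriction(t_rel, z)$peak))
})

test_that("window membership is half-open on the 20-Hz grid", {
  t_rel <- c(0.25, 0.3, 1.25, 1.3)
  z <- c(-9, -1, -2, -9)
  # 0.3 in, 1.3 out; 0.25 out
  expect_equal(peak_constriction(t_rel, z)$peak, -2)
  expect_equal(peak_constriction(t_rel, z)$n_valid, 2L)
  # pretest [-0.2, 0): -0.2 in, 0 out
  expect_equal(pretest_pupil(c(-0.25, -0.2, -0.05, 0), c(9, 1, 3, 9)), 2)
})

test_that("pretest_pupil averages valid pre-onset bins", {
  t_rel <- seq(-0.5, 0.5, by = 0.05)
  expect_equal(pretest_pupil(t_rel, rep(0.7, length(t_rel))), 0.7)
  z <- rep(NA_real_, length(t_rel))
  expect_true(is.na(pretest_pupil(t_rel, z)))
})

test_that("noise-free pipeline output matches the analytic kernel sum", {
  # oracle: evaluate the generative sum directly on the 20-Hz grid and
  # baseline it, in mm; compare with sd * z_test from the full pipeline
  p <- noiseless_params()
  pr <- participant_profiles(p, seed = 8)
  des <- build_design("P01", reps_per_numerosity_per_session = 2, seed = 9)
  sessions <- lapply(1:4, function(s)
    simulate_session(des[des$session == s, ], p, pr[1, ],
                     seed = derive_seed(10, s)))
  pp <- preprocess_participant(sessions)

  s1 <- sessions[[1]]
  gt <- s1$ground_truth
  n_trials <- nrow(s1$design)
  mm_trace <- function(tt) {  # generative sum at arbitrary times, in mm
    out <- rep(pr$baseline_mm[1], length(tt))
    out <- out + gt$adapter_amplitude * pupil_kernel(tt)  # initial adaptation
    for (tr in seq_len(n_trials)) {
      t0 <- 60 + (tr - 1) * 5.5
      out <- out + gt$adapter_amplitude * pupil_kernel(tt - t0) +
        gt$test_amplitudes[tr] * pupil_kernel(tt - t0 - 2.5)
    }
    out
  }
  bin_mean <- function(tb) # mean of the 25 raw samples of bin starting at tb
    vapply(tb, function(b) mean(mm_trace(b + (0:24) / 500)), numeric(1))

  tr1 <- pp$trials[pp$trials$session == 1 & pp$trials$trial == 1, ]
  t_test <- 62.5
  pred <- bin_mean(tr1$t_rel_test + t_test)
  base_w <- tr1$t_rel_test >= -0.2 - 1e-9 & tr1$t_rel_test < 0.2 - 1e-9
  pred_corr <- pred - median(pred[base_w])
  got_mm <- tr1$z_test * pp$stats$sd
  # bins before the first top-up are outside any trial epoch, hence missing
  expect_true(all(is.finite(got_mm[tr1$t_rel_test >= -2.5])))
  fin <- is.finite(got_mm)
  expect_equal(got_mm[fin], pred_corr[fin], tolerance = 1e-6)

  # recovered peak within one-bin tolerance of the kernel minimum mapping
  pk <- peak_constriction(tr1$t_rel_test, tr1$z_test)
  expect_equal(pk$peak * pp$stats$sd,
               min(pred_corr[tr1$t_rel_test >= 0.3 - 1e-9 &
                               tr1$t_rel_test < 1.3 - 1e-9]),
               tolerance = 1e-6)
})

test_that("pre-test pupil separates adaptation conditions (incomplete recovery)", {
  co <- make_cohort(n_participants = 1, reps = 2, seed = 31,
                    params = noiseless_params())
  pp <- preprocess_participant(co$sessions[[1]])
  f <- trial_features(pp$trials)
  m_high <- mean(f$pretest_pupil[f$condition == "high"])
  m_low <- mean(f$pretest_pupil[f$condition == "low"])
  # larger adapter response (160 dots) leaves the pupil more constricted
  expect_lt(m_high, m_low)
})

test_that("peak of the trial-mean trace >= mean of trial peaks", {
  # a complete-data property (min is concave-like under averaging); missing
  # bins can break it, so run an artifact-free cohort with trial variability
  p <- noiseless_params()
  p$amp_trial_cv <- 0.15
  co <- make_cohort(n_participants = 1, reps = 3, seed = 55, params = p)
  pp <- preprocess_participant(co$sessions[[1]])
  tr <- pp$trials
  m <- aggregate(z_test ~ t_rel_test, data = tr, FUN = mean, na.rm = TRUE,
                 na.action = na.pass)
  pk_mean <- peak_constriction(m$t_rel_test, m$z_test)$peak
  f <- trial_features(tr)
  expect_gte(pk_mean, mean(f$peak_constriction, na.rm = TRUE))
})

test_that("adaptation_effect_pupil: sign, zero case, shift invariance", {
  co <- make_cohort(n_participants = 1, reps = 2, seed = 13,
                    params = noiseless_params())
  pp <- preprocess_participant(co$sessions[[1]])
  eff <- adaptation_effect_pupil(pp$trials)
  # k_high < k_low with positive gain -> weaker constriction after adapt-high
  expect_gt(eff, 0)
  # adding a constant to all corrected traces leaves the difference unchanged
  shifted <- pp$trials
  shifted$z_test <- shifted$z_test + 0.37
  expect_equal(adaptation_effect_pupil(shifted), eff)
  # identical traces in both conditions -> 0
  same <- pp$trials
  same$condition <- "high"
  same2 <- same
  same2$condition <- "low"
  expect_equal(adaptation_effect_pupil(rbind(same, same2)), 0)
})

test_that("adaptation_effect_behavior matches the analytic expectation", {
  des <- build_design("P01", reps_per_numerosity_per_session = 2, seed = 3)
  p0 <- noiseless_params()
  prof <- data.frame(participant_id = "P01", baseline_mm = 5,
                     k_high = 0.75, k_low = 1)
  e <- simulate_estimates(des, p0, prof, seed = 1)
  expect_equal(adaptation_effect_behavior(e), 40 * 0.25)  # 10, exactly
  # k_high = k_low, cv = 0 -> 0
  prof$k_high <- 1
  e0 <- simulate_estimates(des, p0, prof, seed = 1)
  expect_equal(adaptation_effect_behavior(e0), 0)
  # linear growth in (k_low - k_high)
  prof$k_high <- 0.9
  expect_equal(adaptation_effect_behavior(
    simulate_estimates(des, p0, prof, seed = 1)), 40 * 0.1)
})

test_that("condition averages respect missingness and report per-cell peaks", {
  co <- make_cohort(n_participants = 2, reps = 2, seed = 91)
  trials <- do.call(rbind, lapply(co$sessions, function(ss)
    preprocess_participant(ss)$trials))
  ca <- condition_averages(trials)
  expect_setequal(unique(ca$peaks$numerosity), c(10, 14, 20, 28, 40))
  expect_setequal(unique(ca$peaks$condition), c("high", "low"))
  expect_true(all(is.finite(ca$peaks$peak)))
  expect_true(all(is.finite(ca$peaks$sem_across_participants)))
})
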