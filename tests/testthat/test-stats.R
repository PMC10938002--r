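# Mixed-model inference: structural parity of the design, effect recovery,
# degenerate inputs, outlier rule, correlation behavior, power battery.

feature_cohort <- function(n_participants = 8, reps = 4, seed = 1,
                           params = sim_params()) {
  params$n_participants <- n_participants
  pr <- participant_profiles(params, seed = derive_seed(seed, "prof"))
  des <- build_design(pr$participant_id,
                      experiment = rep_len(1:2, n_participants),
                      reps_per_numerosity_per_session = reps,
                      seed = derive_seed(seed, "des"))
  list(params = params, profiles = pr, design = des,
       features = simulate_features(des, params, pr,
                                    seed = derive_seed(seed, "feat")),
       estimates = simulate_estimates(des, params, pr,
                                      seed = derive_seed(seed, "est")))
}

test_that("pupil model has exactly the stated fixed and random structure", {
  fc <- feature_cohort(seed = 3)
  m <- fit_pupil_model(fc$features)
  expect_identical(m$terms$term,
                   c("numerosity", "adaptation", "pretest_pupil"))
  expect_true(all(m$terms$df1 == 1))
  # every candidate grouping is attempted: either retained or logged as
  # dropped for zero variance
  expect_setequal(c(m$random_terms, m$dropped_random),
                  c("participant", "experiment", "luminance"))
  expect_true("participant" %in% m$random_terms)
  expect_equal(m$terms$df2[1], m$n_obs - 4)
  expect_true(all(m$terms$p >= 0 & m$terms$p <= 1))
})

test_that("behavior model includes the 4-df interaction", {
  fc <- feature_cohort(seed = 4)
  m <- fit_behavior_model(fc$estimates)
  expect_identical(m$terms$term,
                   c("numerosity_f", "adaptation", "numerosity_f:adaptation"))
  expect_identical(m$terms$df1, c(4L, 1L, 4L))
  expect_true(all(m$random_terms %in% c("participant", "experiment")))
})

test_that("pupil model recovers adaptation and numerosity effects with the right signs", {
  fc <- feature_cohort(n_participants = 8, reps = 6, seed = 11)
  m <- fit_pupil_model(fc$features)
  tt <- m$terms
  expect_lt(tt$p[tt$term == "adaptation"], 0.05)
  expect_lt(tt$p[tt$term == "numerosity"], 0.05)
  # higher numerosity -> more constriction -> more negative peak
  expect_lt(m$coefficients[["numerosity"]], 0)
  # sum coding, first level "low": stronger constriction after adapt-low
  expect_lt(m$coefficients[["adaptation1"]], 0)
})

test_that("behavior model recovers adaptation, with low-high gap growing in N", {
  fc <- feature_cohort(n_participants = 8, reps = 6, seed = 12)
  m <- fit_behavior_model(fc$estimates)
  tt <- m$terms
  expect_lt(tt$p[tt$term == "adaptation"], 0.05)
  expect_lt(tt$p[tt$term == "numerosity_f:adaptation"], 0.05)
  e <- fc$estimates
  gap <- sapply(c(10, 14, 20, 28, 40), function(n)
    mean(e$estimate[e$numerosity == n & e$condition == "low"]) -
      mean(e$estimate[e$numerosity == n & e$condition == "high"]))
  expect_true(all(diff(gap) > 0))
})

test_that("no-effect, no-noise cohort gives a null adaptation term", {
  p <- noiseless_params(n_participants = 4)
  p$k_high <- 0.999999; p$k_low <- 1  # constructor requires k_high < k_low
  pr <- participant_profiles(p, seed = 2)
  pr$k_high <- pr$k_low  # exact null
  des <- build_design(pr$participant_id,
                      reps_per_numerosity_per_session = 3, seed = 3)
  e <- simulate_estimates(des, p, pr, seed = 4)
  # estimates depend on numerosity only -> adaptation coefficient exactly 0
  # (the F ratio itself is 0/0 round-off on a perfect fit, so test the
  # numerator)
  m <- suppressWarnings(fit_behavior_model(e))
  expect_lt(abs(m$coefficients[["adaptation1"]]), 1e-8)
})

test_that("constant pre-test covariate is dropped deterministically", {
  fc <- feature_cohort(seed = 5)
  f <- fc$features
  f$pretest_pupil <- 0.3
  m <- fit_pupil_model(f)
  expect_identical(m$dropped_fixed, "pretest_pupil")
  expect_identical(m$terms$term, c("numerosity", "adaptation"))
})

test_that("single-experiment data drops degenerate random terms", {
  fc <- feature_cohort(seed = 6)
  f <- fc$features[fc$features$experiment == 1, ]  # luminance constant too
  m <- fit_pupil_model(f)
  expect_false("luminance" %in% m$random_terms)
  expect_false("experiment" %in% m$random_terms)
  expect_true("participant" %in% m$random_terms)
})

test_that("3-SD rule removes a wild estimate and the fit proceeds on n-1", {
  # cells must be large enough that 3 SD is attainable: a lone outlier in a
  # cell of n can sit at most (n-1)/sqrt(n) SDs from the cell mean
  fc <- feature_cohort(reps = 10, seed = 7)
  e <- fc$estimates
  e$estimate[1] <- 1e6
  # hand check of the cell statistic
  cell <- e$participant_id == e$participant_id[1] &
    e$condition == e$condition[1] & e$numerosity == e$numerosity[1]
  x <- e$estimate[cell]
  expect_gt(abs(x[1] - mean(x)), 3 * sd(x) * 0.99)  # wild point flagged
  keep <- outlier_keep(e)
  expect_false(keep[1])
  m <- fit_behavior_model(e)
  # the wild point goes (other legitimate lognormal tails may go with it)
  expect_equal(m$n_obs, sum(keep))
  expect_lte(m$n_obs, nrow(e) - 1)
})

test_that("correlate_effects: exact, degenerate and permuted cases", {
  pe <- data.frame(participant_id = sprintf("P%02d", 1:10),
                   pupil_effect = seq(0.1, 1, by = 0.1))
  be <- data.frame(participant_id = sprintf("P%02d", 1:10),
                   behavior_effect = 3 * seq(0.1, 1, by = 0.1))
  r <- correlate_effects(pe, be)
  expect_equal(r$r, 1)
  expect_equal(r$n, 10)

  be0 <- be; be0$behavior_effect <- 2
  expect_error(correlate_effects(pe, be0), "zero variance")
  expect_error(correlate_effects(pe[1:2, ], be[1:2, ]), ">= 3")

  # shuffled pairings: r centered on 0
  set.seed(42)
  pe2 <- data.frame(participant_id = sprintf("P%02d", 1:20),
                    pupil_effect = rnorm(20))
  rs <- replicate(200, {
    be2 <- data.frame(participant_id = sample(pe2$participant_id),
                      behavior_effect = rnorm(20))
    correlate_effects(pe2, be2)$r
  })
  expect_lt(abs(mean(rs)), 0.08)
})

test_that("adaptation power >= 80% at default effect sizes (battery)", {
  rej <- vapply(1:40, function(i) {
    fc <- feature_cohort(n_participants = 8, reps = 4, seed = 1000 + i)
    m <- fit_pupil_model(fc$features)
    m$terms$p[m$terms$term == "adaptation"] < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.8)
})
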