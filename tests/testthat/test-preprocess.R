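# Cleaning rules: artifact flags, saccade-trial exclusion, down-sampling,
# z-scoring, baseline correction, order-of-operations properties.

mk_samples <- function(pupil, fs = 500, gaze = 0) {
  n <- length(pupil)
  data.frame(t_s = (seq_len(n) - 1) / fs, pupil_mm = pupil,
             gaze_x_deg = rep_len(gaze, n), gaze_y_deg = rep_len(0, n),
             valid_flag = rep_len(1L, n))
}

test_that("flag_invalid_samples applies floor, rate and blink-margin rules", {
  # constant trace: all valid
  fl <- flag_invalid_samples(mk_samples(rep(5, 100)))
  expect_true(all(fl$valid))
  expect_equal(nrow(fl$intervals), 0)

  # hand computation: 0.1 mm over 2 ms = 50 mm/s > 25 -> both samples flagged
  s <- mk_samples(c(rep(5, 10), 4.9, rep(4.9, 10)))
  fl <- flag_invalid_samples(s)
  expect_false(fl$valid[10])
  expect_false(fl$valid[11])
  expect_true(all(fl$valid[-(10:11)]))

  # sub-1-mm dip flagged with 100-ms margins on each side
  p <- rep(5, 500); p[201:300] <- 0.5
  fl <- flag_invalid_samples(mk_samples(p))
  expect_true(all(!fl$valid[151:350]))  # 100 ms = 50 samples each side
  expect_true(all(fl$valid[1:149]))
  expect_true(all(fl$valid[352:500]))
  # merged into one interval
  expect_equal(nrow(fl$intervals), 1)

  # empty stream
  fl <- flag_invalid_samples(mk_samples(numeric(0)))
  expect_length(fl$valid, 0)
})

test_that("rate rule ignores pairs straddling removed sub-floor samples", {
  # drop to 0 and back: the 5 -> 0 jumps are blink edges, not rate pairs;
  # adjacent *valid* samples are the two 5-mm flanks, 3 samples apart
  p <- c(rep(5, 10), 0, rep(5, 10))
  fl <- flag_invalid_samples(mk_samples(p),
                             cleaning_params(blink_margin_s = 0))
  expect_false(fl$valid[11])        # below floor
  expect_true(all(fl$valid[-11]))   # flanks survive: 0 mm/s across the gap
})

test_that("exclude_saccade_trials drops sustained >1-deg excursions only", {
  p <- noiseless_params()
  pr <- participant_profiles(p, seed = 1)
  des <- build_design("P01", reps_per_numerosity_per_session = 1, seed = 2)
  s <- simulate_session(des[des$session == 1, ], p, pr[1, ], seed = 3)

  keep <- exclude_saccade_trials(s$samples, s$events)
  expect_true(all(keep$keep))  # gaze constant at fixation

  # single-sample 1.5-deg glitch: kept by the run-length rule
  sg <- s$samples
  i <- which(sg$t_s >= 61)[1]
  sg$gaze_x_deg[i] <- 1.5
  expect_true(all(exclude_saccade_trials(sg, s$events)$keep))

  # sustained excursion: dropped
  sg$gaze_x_deg[i:(i + 99)] <- 1.5
  k2 <- exclude_saccade_trials(sg, s$events)
  expect_false(k2$keep[k2$trial == 1])
  expect_true(all(k2$keep[k2$trial != 1]))

  expect_error(exclude_saccade_trials(sg[, c("t_s", "pupil_mm")], s$events),
               "gaze")
})

test_that("saccade drop fraction tracks the injected trial probability", {
  p <- sim_params(n_participants = 4, saccade_trial_prob = 0.055)
  pr <- participant_profiles(p, seed = 5)
  des <- build_design(pr$participant_id,
                      reps_per_numerosity_per_session = 6, seed = 6)
  drops <- unlist(lapply(seq_len(4), function(i) {
    lapply(1:4, function(s) {
      ses <- simulate_session(des[des$participant_id ==
                                    pr$participant_id[i] &
                                    des$session == s, ], p, pr[i, ],
                              seed = derive_seed(7, i, s))
      k <- exclude_saccade_trials(ses$samples, ses$events)
      !k$keep
    })
  }))
  n <- length(drops)  # 480 trials
  phat <- mean(drops)
  expect_lt(abs(phat - 0.055), 3 * sqrt(0.055 * 0.945 / n))
})

test_that("downsample averages valid samples into anchored 50-ms bins", {
  s <- mk_samples(rep(5, 50))
  ds <- downsample(s, rep(TRUE, 50))
  expect_equal(ds$value, c(5, 5))
  expect_equal(ds$t, c(0, 0.05))
  # bin with two valid samples {4, 6} -> 5
  v <- rep(FALSE, 50); v[3] <- v[7] <- TRUE
  s$pupil_mm[3] <- 4; s$pupil_mm[7] <- 6
  ds <- downsample(s, v)
  expect_equal(ds$value[1], 5)
  expect_true(is.na(ds$value[2]))  # fully invalid bin -> missing
  expect_equal(ds$n_valid, c(2L, 0L))
})

test_that("z-scoring has exact pooled median 0 / SD 1 and location invariance", {
  st <- zscore_stats(c(4, 5, 6))
  expect_equal(st$median, 5)
  expect_equal(st$sd, 1)
  x <- rnorm(500, 5, 0.4)
  st <- zscore_stats(x)
  z <- (x - st$median) / st$sd
  expect_lt(abs(median(z)), 1e-12)
  expect_lt(abs(sd(z) - 1), 1e-12)
  st2 <- zscore_stats(x + 1)
  expect_equal((x + 1 - st2$median) / st2$sd, z)
  expect_error(zscore_stats(rep(3, 10)), "degenerate")
  expect_error(zscore_stats(2), "degenerate")
})

test_that("baseline correction subtracts the window median and is idempotent", {
  tr <- data.frame(t = seq(0, 1, by = 0.05), value = 0.7)
  bc <- baseline_correct(tr, 0.5)
  expect_true(all(bc$value == 0))
  tr$value <- seq_along(tr$t) / 10
  bc <- baseline_correct(tr, 0.5)
  w <- tr$t >= 0.3 - 1e-9 & tr$t < 0.7 - 1e-9
  expect_equal(attr(bc, "baseline"), median(tr$value[w]))
  expect_identical(median(bc$value[w]), 0)       # exact by construction
  expect_equal(baseline_correct(bc, 0.5)$value, bc$value)  # idempotent
  # empty window -> excluded with reason
  tr$value <- NA_real_
  bc <- baseline_correct(tr, 0.5)
  expect_equal(attr(bc, "excluded"), "empty baseline window")
})

test_that("flagged samples never leak into bins, z stats or baselines", {
  p <- sim_params(n_participants = 1)
  pr <- participant_profiles(p, seed = 1)
  des <- build_design("P01", reps_per_numerosity_per_session = 2, seed = 2)
  s <- simulate_session(des[des$session == 1, ], p, pr[1, ],
                        seed = derive_seed(3, 1))
  fl <- flag_invalid_samples(s$samples)
  expect_gt(sum(!fl$valid), 0)
  # poison every flagged sample with an extreme sentinel and push it through
  # the downstream stages with the same mask: outputs must be unchanged
  pois <- s$samples
  pois$pupil_mm[!fl$valid] <- 1e6
  ds_ref <- downsample(s$samples, fl$valid)
  ds_pois <- downsample(pois, fl$valid)
  expect_identical(ds_ref, ds_pois)
  expect_identical(zscore_stats(ds_ref$value), zscore_stats(ds_pois$value))
  b_ref <- baseline_correct(data.frame(t = ds_ref$t, value = ds_ref$value),
                            62.5)
  b_pois <- baseline_correct(data.frame(t = ds_pois$t, value = ds_pois$value),
                             62.5)
  expect_identical(b_ref$value, b_pois$value)
})

test_that("attrition ledger is exact and traces live on the 20-Hz grid", {
  co <- make_cohort(n_participants = 1, reps = 2, seed = 77)
  pp <- preprocess_participant(co$sessions[[1]])
  a <- pp$attrition
  expect_equal(unname(a["trials_in"]),
               unname(a["trials_excluded"] + a["trials_featured"]))
  expect_equal(unname(a["trials_in"]), 40)
  one <- pp$trials[pp$trials$session == pp$trials$session[1] &
                     pp$trials$trial == pp$trials$trial[1], ]
  expect_true(all(abs(diff(one$t_rel_test) - 0.05) < 1e-9))
  # every bin time sits on the 20-Hz grid
  off <- pp$trials$t_rel_test * 20
  expect_true(all(abs(off - round(off)) < 1e-6))
})
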