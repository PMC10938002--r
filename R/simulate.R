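# Synthetic eye-tracking sessions and verbal numerosity estimates with a
# known generative structure, so every downstream stage is verifiable at
# desk scale without real recordings.

#' Simulation parameters
#'
#' Defines the generative world: per-participant baseline pupil diameter and
#' slow drift; a constriction impulse locked to every luminance onset whose
#' amplitude grows with the log of the *perceived* numerosity
#' (`amplitude = gain0 + gain1 * log(perceived N)`, in mm); adaptation acting
#' multiplicatively on perceived numerosity (`k_high < 1 <= k_low`) with
#' per-participant spread `k_sd`; lognormal multiplicative noise on verbal
#' estimates; and artifact processes (blinks as sub-1-mm dropouts, isolated
#' spikes exceeding 25 mm/s, gaze excursions above 1 deg on a Bernoulli
#' fraction of trials).
#'
#' @param n_participants Cohort size (default 22, the pooled sample).
#' @param baseline_mean_mm,baseline_sd_mm Per-participant baseline pupil
#'   diameter draw (mm).
#' @param drift_amplitude_mm,drift_timescale_s Slow pupil fluctuations:
#'   amplitude (mm) and characteristic period (s) of a sum of 3 random-phase
#'   sinusoids.
#' @param gain0,gain1 Constriction-amplitude intercept and log-numerosity
#'   slope (mm); amplitude of the impulse to an onset of perceived
#'   numerosity p is `gain0 + gain1 * log(p)`.
#' @param response_latency_s Minimum latency of the pupillary response (s,
#'   >= 0.3).
#' @param peak_time_s Time of kernel peak after onset (s, inside 0.3-1.3).
#' @param kernel_duration_s Kernel support; its slow tail is what leaves the
#'   pupil incompletely recovered 0.5 s after adapter offset.
#' @param amp_trial_cv Multiplicative trial-to-trial variability of response
#'   amplitudes (coefficient of variation).
#' @param k_high,k_low Perceived-numerosity factors after adapting to high /
#'   low numerosity (`k_high < k_low`).
#' @param k_sd Between-participant SD of each adaptation factor.
#' @param estimate_cv Lognormal coefficient of variation of verbal estimates.
#' @param noise_sd_mm White measurement noise per 500-Hz sample (mm).
#' @param blink_rate_hz,spike_rate_hz Poisson rates of blink dropouts and
#'   single-sample spikes.
#' @param saccade_trial_prob Probability that a trial contains a >1-deg gaze
#'   excursion (default 0.055, the fraction of trials the study reports
#'   discarding).
#' @param gaze_noise_sd_deg Gaze jitter SD around fixation (deg).
#' @param sample_rate_hz Eye-tracker sampling rate (500 Hz).
#' @param feature_noise_sd Trial-level noise SD, in z units, used by the
#'   feature-level surrogate generator [simulate_features()].
#' @return Object of class `sim_params`.
#' @export
sim_params <- function(n_participants = 22L,
                       baseline_mean_mm = 5, baseline_sd_mm = 0.5,
                       drift_amplitude_mm = 0.1, drift_timescale_s = 30,
                       gain0 = 0.08, gain1 = 0.11,
                       response_latency_s = 0.3, peak_time_s = 0.9,
                       kernel_duration_s = 6,
                       amp_trial_cv = 0.1,
                       k_high = 0.75, k_low = 1.0, k_sd = 0.08,
                       estimate_cv = 0.15,
                       noise_sd_mm = 0.005,
                       blink_rate_hz = 0.15, spike_rate_hz = 0.02,
                       saccade_trial_prob = 0.055,
                       gaze_noise_sd_deg = 0.05,
                       sample_rate_hz = 500L,
                       feature_noise_sd = 0.3) {
  stopifnot(
    n_participants >= 1, baseline_mean_mm > 0, baseline_sd_mm >= 0,
    response_latency_s >= 0.3,
    peak_time_s > response_latency_s, peak_time_s <= 1.3,
    k_high < k_low, k_high > 0,
    estimate_cv >= 0, noise_sd_mm >= 0,
    blink_rate_hz >= 0, spike_rate_hz >= 0,
    saccade_trial_prob >= 0, saccade_trial_prob <= 1,
    sample_rate_hz > 0
  )
  structure(as.list(environment()), class = "sim_params")
}

#' Derive a reproducible 31-bit stage seed from a master seed
#'
#' Hashes the master seed together with arbitrary string/numeric labels
#' (stage name, participant id, session index ...) so that every pipeline
#' stage gets an independent, platform-stable stream.
#'
#' @param master Integer master seed.
#' @param ... Labels identifying the stage.
#' @return Integer in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(master, ...) {
  key <- paste(c(master, ...), collapse = "/")
  h <- 0
  for (v in utf8ToInt(key)) h <- (h * 31 + v) %% 2147483647
  as.integer(h)
}

#' Perceived numerosity after adaptation
#'
#' Adaptation scales perceived numerosity multiplicatively: a participant
#' with condition factor k perceives an n-dot array as n * k dots. Factors
#' below 1 (adapt-high) produce underestimation.
#'
#' @param n Physical numerosity (> 0, vectorized).
#' @param k Participant's condition-specific adaptation factor.
#' @return Perceived numerosity, monotone increasing in `n`.
#' @export
perceived_numerosity <- function(n, k) {
  if (any(n <= 0)) stop("invalid-parameter: n must be > 0", call. = FALSE)
  n * k
}

#' Pupillary constriction impulse kernel
#'
#' Smooth unimodal negative-going impulse: zero before `latency`, then a
#' gamma-shaped lobe `-(x/tau) * exp(1 - x/tau)` with `x = t - latency` and
#' `tau = peak_time - latency`, normalized to minimum -1 at `peak_time`.
#' The default peaks at 0.9 s, inside the a-priori 0.3-1.3 s constriction
#' window, and decays slowly enough that ~25% of the response remains 2.5 s
#' after onset, which is what leaves pre-test pupil size condition-dependent
#' after the 500-ms blank.
#'
#' @param t Time since onset (s, vectorized; values < 0 allowed, return 0).
#' @param latency Response latency (s).
#' @param peak_time Time of the peak (s).
#' @return Unitless kernel values in `[-1, 0]`.
#' @export
pupil_kernel <- function(t, latency = 0.3, peak_time = 0.9) {
  tau <- peak_time - latency
  stopifnot(tau > 0)
  x <- t - latency
  out <- numeric(length(t))
  pos <- x > 0
  out[pos] <- -(x[pos] / tau) * exp(1 - x[pos] / tau)
  out
}

#' Draw per-participant generative profiles
#'
#' One row per participant: baseline pupil diameter and the two adaptation
#' factors (shared between the pupillometry and psychophysics simulators, so
#' that individual adaptation strength drives both modalities).
#'
#' @param params A [sim_params()].
#' @param seed Integer seed.
#' @return `data.frame(participant_id, baseline_mm, k_high, k_low)`.
#' @export
participant_profiles <- function(params, seed = 1L) {
  local_seed(seed)
  n <- params$n_participants
  data.frame(
    participant_id = sprintf("P%02d", seq_len(n)),
    baseline_mm = stats::rnorm(n, params$baseline_mean_mm, params$baseline_sd_mm),
    k_high = pmax(0.05, stats::rnorm(n, params$k_high, params$k_sd)),
    k_low = pmax(0.05, stats::rnorm(n, params$k_low, params$k_sd)),
    stringsAsFactors = FALSE
  )
}

# Event table for one session: 60-s initial adaptation, then per trial
# 2-s top-up, 0.5-s blank, 0.5-s test, 2.5-s inter-trial interval.
session_events <- function(n_trials) {
  t0 <- 60 + (seq_len(n_trials) - 1) * 5.5
  data.frame(
    trial = rep(seq_len(n_trials), each = 5L),
    event = rep(c("topup_start", "blank_start", "test_on", "test_off",
                  "trial_end"), n_trials),
    t_s = as.vector(rbind(t0, t0 + 2, t0 + 2.5, t0 + 3, t0 + 5.5))
  )
}

#' Simulate one eye-tracker session
#'
#' Builds a 500-Hz sample stream for one participant-session of the
#' pupillometry experiment: baseline + slow sinusoidal drift + one
#' constriction kernel per luminance onset (initial adaptation, every top-up,
#' every test) + white measurement noise, then injects blinks (pupil dropped
#' to 0 mm for 100-300 ms), single-sample spikes (> 25 mm/s) and >1-deg gaze
#' excursions on a Bernoulli fraction of trials. Test-onset amplitudes follow
#' `gain0 + gain1 * log(n * k_condition)`; adapter onsets use the adapter's
#' own numerosity (160 or 10).
#'
#' @param design Design rows (one participant, one session; columns
#'   condition, trial, numerosity).
#' @param params A [sim_params()].
#' @param profile One row of [participant_profiles()].
#' @param seed Integer seed; identical seed gives an identical session.
#' @return `raw_session` list: `samples` (t_s, pupil_mm, gaze_x_deg,
#'   gaze_y_deg, valid_flag), `events`, `design`, and `ground_truth`
#'   (per-trial amplitudes, artifact intervals, spike times, saccade trials).
#' @export
simulate_session <- function(design, params, profile, seed = 1L) {
  if (nrow(design) == 0 || length(unique(design$session)) > 1 ||
      length(unique(design$condition)) > 1)
    stop("invalid design: need rows of a single participant-session",
         call. = FALSE)
  local_seed(seed)
  fs <- params$sample_rate_hz
  cond <- design$condition[1]
  n_trials <- nrow(design)
  events <- session_events(n_trials)
  dur <- 60 + n_trials * 5.5
  nsamp <- as.integer(round(dur * fs))
  t <- (seq_len(nsamp) - 1) / fs

  # slow drift: 3 random-phase sinusoids around the stated timescale
  drift <- rep(0, nsamp)
  for (j in 1:3) {
    period <- params$drift_timescale_s * stats::runif(1, 0.5, 2)
    drift <- drift + sin(2 * pi * t / period + stats::runif(1, 0, 2 * pi))
  }
  drift <- drift * params$drift_amplitude_mm / 3

  pupil <- profile$baseline_mm + drift

  kern_n <- as.integer(round(params$kernel_duration_s * fs))
  kern <- pupil_kernel((seq_len(kern_n) - 1) / fs,
                       params$response_latency_s, params$peak_time_s)
  add_kernel <- function(trace, onset_s, amplitude) {
    i0 <- as.integer(round(onset_s * fs)) + 1L
    idx <- i0:min(i0 + kern_n - 1L, nsamp)
    trace[idx] <- trace[idx] + amplitude * kern[seq_along(idx)]
    trace
  }

  k <- if (cond == "high") profile$k_high else profile$k_low
  adapter_n <- if (cond == "high") 160 else 10
  amp_adapter <- params$gain0 + params$gain1 * log(adapter_n)
  amp_noise <- function() 1 + stats::rnorm(1, 0, params$amp_trial_cv)

  pupil <- add_kernel(pupil, 0, amp_adapter * amp_noise())
  test_amp <- numeric(n_trials)
  for (tr in seq_len(n_trials)) {
    t_topup <- 60 + (tr - 1) * 5.5
    pupil <- add_kernel(pupil, t_topup, amp_adapter * amp_noise())
    a <- (params$gain0 +
            params$gain1 * log(perceived_numerosity(design$numerosity[tr], k))) *
      amp_noise()
    test_amp[tr] <- a
    pupil <- add_kernel(pupil, t_topup + 2.5, a)
  }

  if (params$noise_sd_mm > 0)
    pupil <- pupil + stats::rnorm(nsamp, 0, params$noise_sd_mm)

  # gaze: white jitter around fixation
  gx <- stats::rnorm(nsamp, 0, params$gaze_noise_sd_deg)
  gy <- stats::rnorm(nsamp, 0, params$gaze_noise_sd_deg)

  # saccade trials: sustained gaze excursion > 1 deg inside the trial epoch
  sacc <- which(stats::runif(n_trials) < params$saccade_trial_prob)
  for (tr in sacc) {
    t_on <- 60 + (tr - 1) * 5.5 + stats::runif(1, 0.2, 4.8)
    len <- as.integer(round(stats::runif(1, 0.15, 0.4) * fs))
    amp <- stats::runif(1, 1.3, 3)
    th <- stats::runif(1, 0, 2 * pi)
    i0 <- as.integer(round(t_on * fs)) + 1L
    idx <- i0:min(i0 + len - 1L, nsamp)
    gx[idx] <- gx[idx] + amp * cos(th)
    gy[idx] <- gy[idx] + amp * sin(th)
  }

  # blinks: Poisson dropouts to 0 mm (below the 1-mm validity floor)
  n_blinks <- stats::rpois(1, params$blink_rate_hz * dur)
  blink_int <- matrix(numeric(0), 0, 2)
  valid <- rep(1L, nsamp)
  if (n_blinks > 0) {
    on <- sort(stats::runif(n_blinks, 0, dur - 0.4))
    len <- stats::runif(n_blinks, 0.1, 0.3)
    blink_int <- cbind(on, on + len)
    for (b in seq_len(n_blinks)) {
      idx <- (as.integer(round(on[b] * fs)) + 1L):
        min(as.integer(round((on[b] + len[b]) * fs)), nsamp)
      pupil[idx] <- 0
      valid[idx] <- 0L
    }
  }

  # spikes: isolated single-sample jumps far above the 25 mm/s ceiling
  n_spikes <- stats::rpois(1, params$spike_rate_hz * dur)
  spike_idx <- integer(0)
  if (n_spikes > 0) {
    spike_idx <- sort(sample.int(nsamp, n_spikes))
    pupil[spike_idx] <- pupil[spike_idx] +
      sample(c(-1, 1), n_spikes, TRUE) * stats::runif(n_spikes, 0.3, 0.6)
  }

  structure(list(
    samples = data.frame(t_s = t, pupil_mm = pupil, gaze_x_deg = gx,
                         gaze_y_deg = gy, valid_flag = valid),
    events = events,
    design = design,
    ground_truth = list(
      k = k, test_amplitudes = test_amp, adapter_amplitude = amp_adapter,
      blink_intervals = blink_int, spike_idx = spike_idx,
      saccade_trials = sacc
    )
  ), class = "raw_session")
}

#' Simulate verbal numerosity estimates
#'
#' One estimate per design row: `n * k_condition` for the participant, times
#' a lognormal factor with unit mean and coefficient of variation
#' `estimate_cv`. Multiplicative error makes the adapt-high vs adapt-low
#' difference grow with numerosity.
#'
#' @param design Design rows (may span participants; participant ids must
#'   appear in `profiles`).
#' @param params A [sim_params()].
#' @param profiles Data frame from [participant_profiles()].
#' @param seed Integer seed.
#' @return `data.frame(participant_id, experiment, condition, numerosity,
#'   trial, estimate)` with all estimates positive.
#' @export
simulate_estimates <- function(design, params, profiles, seed = 1L) {
  local_seed(seed)
  i <- match(design$participant_id, profiles$participant_id)
  if (anyNA(i)) stop("design references unknown participants", call. = FALSE)
  k <- ifelse(design$condition == "high", profiles$k_high[i], profiles$k_low[i])
  cv <- params$estimate_cv
  noise <- if (cv > 0) {
    sdlog <- sqrt(log(1 + cv^2))
    stats::rlnorm(nrow(design), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  } else 1
  data.frame(
    participant_id = design$participant_id,
    experiment = design$experiment,
    condition = design$condition,
    numerosity = design$numerosity,
    trial = design$trial,
    estimate = perceived_numerosity(design$numerosity, k) * noise,
    stringsAsFactors = FALSE
  )
}

#' Feature-level surrogate cohort generator
#'
#' Draws per-trial peak-constriction and pre-test features directly from the
#' generative equations of [simulate_session()], skipping the 500-Hz trace:
#' `peak = -(gain0 + gain1 * log(n * k)) / trace_sd + noise` (z units, with a
#' nominal mm-to-z scale) and `pretest = tail * adapter amplitude / trace_sd
#' + noise`, where `tail` is the kernel value 2.5 s after adapter onset. This
#' is the desk-scale stand-in used for large simulation batteries (type-I
#' error, power, pupil-behavior coupling); single-cohort parameter recovery
#' runs the full raw-trace pipeline instead.
#'
#' @param design Design rows for any number of participants.
#' @param params A [sim_params()].
#' @param profiles Data frame from [participant_profiles()].
#' @param seed Integer seed.
#' @param trace_sd_mm Nominal per-participant trace SD used to convert mm to
#'   z units.
#' @return Features data frame compatible with [fit_pupil_model()].
#' @export
simulate_features <- function(design, params, profiles, seed = 1L,
                              trace_sd_mm = 0.2) {
  local_seed(seed)
  i <- match(design$participant_id, profiles$participant_id)
  if (anyNA(i)) stop("design references unknown participants", call. = FALSE)
  k <- ifelse(design$condition == "high", profiles$k_high[i], profiles$k_low[i])
  # per-participant responsivity intercept surviving z-scoring (z units)
  pid <- unique(design$participant_id)
  icpt <- stats::setNames(stats::rnorm(length(pid), 0, 0.1), pid)
  amp <- (params$gain0 + params$gain1 * log(design$numerosity * k)) *
    (1 + stats::rnorm(nrow(design), 0, params$amp_trial_cv))
  adapter_n <- ifelse(design$condition == "high", 160, 10)
  amp_ad <- params$gain0 + params$gain1 * log(adapter_n)
  tail25 <- pupil_kernel(2.5, params$response_latency_s, params$peak_time_s)
  data.frame(
    participant_id = design$participant_id,
    experiment = design$experiment,
    session = design$session,
    condition = design$condition,
    numerosity = design$numerosity,
    trial = design$trial,
    luminance = ifelse(design$experiment == 2,
                       paste0("exp2_n", design$numerosity), "exp1"),
    peak_constriction = icpt[design$participant_id] - amp / trace_sd_mm +
      stats::rnorm(nrow(design), 0, params$feature_noise_sd),
    pretest_pupil = tail25 * amp_ad / trace_sd_mm +
      stats::rnorm(nrow(design), 0, params$feature_noise_sd),
    stringsAsFactors = FALSE
  )
}

#' Write a raw session to tab-separated files
#'
#' Produces `<prefix>_samples.tsv`, `<prefix>_events.tsv` and
#' `<prefix>_truth.json`.
#'
#' @param session A `raw_session`.
#' @param prefix File-path prefix.
#' @return The three paths, invisibly.
#' @export
write_session <- function(session, prefix) {
  ps <- paste0(prefix, "_samples.tsv")
  pe <- paste0(prefix, "_events.tsv")
  pt <- paste0(prefix, "_truth.json")
  utils::write.table(session$samples, ps, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(session$events, pe, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  gt <- session$ground_truth
  gt$blink_intervals <- unname(apply(gt$blink_intervals, 1, c, simplify = FALSE))
  jsonlite::write_json(gt, pt, auto_unbox = TRUE, digits = NA)
  invisible(c(samples = ps, events = pe, truth = pt))
}

#' Read a raw session back from tab-separated files
#'
#' @param prefix File-path prefix used by [write_session()].
#' @param design Design rows of the session (not serialized with samples).
#' @return A `raw_session` (without ground truth unless present on disk).
#' @export
read_session <- function(prefix, design = NULL) {
  samples <- utils::read.table(paste0(prefix, "_samples.tsv"), header = TRUE,
                               sep = "\t")
  events <- utils::read.table(paste0(prefix, "_events.tsv"), header = TRUE,
                              sep = "\t", stringsAsFactors = FALSE)
  pt <- paste0(prefix, "_truth.json")
  gt <- if (file.exists(pt)) jsonlite::read_json(pt, simplifyVector = TRUE) else NULL
  structure(list(samples = samples, events = events, design = design,
                 ground_truth = gt), class = "raw_session")
}
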