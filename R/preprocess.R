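# Cleaning of raw sample streams: artifact flagging, saccade-trial
# exclusion, down-sampling, per-participant z-scoring and event-locked
# median baseline correction. Order of operations is fixed:
# flag -> trial exclusion -> down-sample -> z-score -> baseline-correct.

#' Cleaning parameters
#'
#' @param min_pupil_mm Validity floor for pupil diameter (mm); smaller values
#'   (blinks read as dropouts) are artifacts.
#' @param max_rate_mm_per_s Ceiling on the absolute rate of change of pupil
#'   diameter between adjacent valid samples (mm/s).
#' @param saccade_amp_deg Gaze-displacement amplitude above which a trial is
#'   discarded (deg).
#' @param saccade_min_run Minimum run length (samples) of the displacement
#'   for a saccade call, so single-sample gaze glitches do not cost a trial.
#' @param blink_margin_s Dilation margin applied on each side of a sub-floor
#'   dropout run, since blink edges corrupt neighboring samples (s).
#' @param out_rate_hz Output rate of down-sampling (Hz).
#' @param baseline_halfwidth_s Half-width of the two-sided median baseline
#'   window around an onset (s); 0.2 gives the 400-ms window.
#' @return Object of class `cleaning_params`.
#' @export
cleaning_params <- function(min_pupil_mm = 1, max_rate_mm_per_s = 25,
                            saccade_amp_deg = 1, saccade_min_run = 3L,
                            blink_margin_s = 0.1, out_rate_hz = 20,
                            baseline_halfwidth_s = 0.2) {
  stopifnot(min_pupil_mm > 0, max_rate_mm_per_s > 0, saccade_amp_deg > 0,
            saccade_min_run >= 1, blink_margin_s >= 0, out_rate_hz > 0,
            baseline_halfwidth_s > 0)
  structure(as.list(environment()), class = "cleaning_params")
}

# Contiguous TRUE runs of a logical vector -> two-column matrix of
# (start, end) indices.
runs_of <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(starts[r$values], ends[r$values])
}

#' Flag invalid pupil samples
#'
#' A sample is invalid when (i) pupil diameter is below the validity floor
#' (blink dropouts included), with each sub-floor run dilated by the blink
#' margin on both sides; or (ii) the absolute rate of change between
#' adjacent floor-valid samples exceeds the ceiling, in which case both
#' samples of the pair are flagged.
#'
#' @param samples Data frame with `t_s` (sorted ascending) and `pupil_mm`.
#' @param params A [cleaning_params()].
#' @return List: `valid` logical vector, and `intervals` — a data frame of
#'   merged artifact intervals (`t_start`, `t_end`, in s).
#' @export
flag_invalid_samples <- function(samples, params = cleaning_params()) {
  n <- nrow(samples)
  if (n == 0)
    return(list(valid = logical(0),
                intervals = data.frame(t_start = numeric(0),
                                       t_end = numeric(0))))
  t <- samples$t_s
  p <- samples$pupil_mm
  low <- p < params$min_pupil_mm
  invalid <- low

  # dilate sub-floor (blink) runs by the margin
  if (any(low) && params$blink_margin_s > 0) {
    dt <- if (n > 1) stats::median(diff(t)) else 1
    m <- max(0L, as.integer(round(params$blink_margin_s / dt)))
    if (m > 0L) {
      lr <- runs_of(low)
      for (r in seq_len(nrow(lr)))
        invalid[max(1L, lr[r, 1] - m):min(n, lr[r, 2] + m)] <- TRUE
    }
  }

  # rate rule on adjacent floor-valid samples
  ok <- which(!low)
  if (length(ok) > 1) {
    rate <- abs(diff(p[ok])) / diff(t[ok])
    bad <- which(rate > params$max_rate_mm_per_s)
    invalid[ok[bad]] <- TRUE
    invalid[ok[bad + 1L]] <- TRUE
  }

  iv <- runs_of(invalid)
  list(valid = !invalid,
       intervals = data.frame(t_start = t[iv[, 1]], t_end = t[iv[, 2]]))
}

# Trial epochs from the event table: [topup_start, trial_end) per trial.
trial_epochs <- function(events) {
  on <- events[events$event == "topup_start", c("trial", "t_s")]
  off <- events[events$event == "trial_end", c("trial", "t_s")]
  m <- merge(on, off, by = "trial", suffixes = c("_start", "_end"))
  m[order(m$trial), ]
}

#' Flag trials containing saccades
#'
#' Within each trial epoch (top-up onset to trial end), gaze displacement is
#' measured as the Euclidean distance from the trial's median fixation
#' position; a trial is dropped when the displacement exceeds the amplitude
#' criterion for at least `saccade_min_run` consecutive samples.
#'
#' @param samples Data frame with `t_s`, `gaze_x_deg`, `gaze_y_deg`.
#' @param events Event table with `topup_start` / `trial_end` rows per trial.
#' @param params A [cleaning_params()].
#' @return Data frame `(trial, keep, reason)`; attribute `drop_fraction`.
#' @export
exclude_saccade_trials <- function(samples, events,
                                   params = cleaning_params()) {
  if (is.null(samples$gaze_x_deg) || is.null(samples$gaze_y_deg))
    stop("gaze channels missing", call. = FALSE)
  ep <- trial_epochs(events)
  keep <- logical(nrow(ep))
  for (i in seq_len(nrow(ep))) {
    idx <- samples$t_s >= ep$t_s_start[i] & samples$t_s < ep$t_s_end[i]
    gx <- samples$gaze_x_deg[idx]; gy <- samples$gaze_y_deg[idx]
    disp <- sqrt((gx - stats::median(gx))^2 + (gy - stats::median(gy))^2)
    over <- disp > params$saccade_amp_deg
    keep[i] <- TRUE
    if (any(over)) {
      r <- runs_of(over)
      if (any(r[, 2] - r[, 1] + 1L >= params$saccade_min_run))
        keep[i] <- FALSE
    }
  }
  out <- data.frame(trial = ep$trial, keep = keep,
                    reason = ifelse(keep, "", "saccade"),
                    stringsAsFactors = FALSE)
  attr(out, "drop_fraction") <- mean(!keep)
  out
}

#' Down-sample valid samples into fixed-rate bins
#'
#' Bins are anchored at the session start: bin j covers
#' `[j/out_rate, (j+1)/out_rate)`. Each bin's value is the mean of its valid
#' samples; a bin with no valid sample is missing (NA). Flagged samples never
#' contribute.
#'
#' @param samples Data frame with `t_s` and `pupil_mm`.
#' @param valid Logical vector from [flag_invalid_samples()] (possibly
#'   further restricted to retained trials).
#' @param out_rate_hz Output rate (Hz).
#' @return Data frame `(t, value, n_valid)` with `t` the bin start time.
#' @export
downsample <- function(samples, valid, out_rate_hz = 20) {
  stopifnot(out_rate_hz > 0, length(valid) == nrow(samples))
  if (nrow(samples) == 0)
    return(data.frame(t = numeric(0), value = numeric(0),
                      n_valid = integer(0)))
  bin <- floor(samples$t_s * out_rate_hz + 1e-9)
  bins <- seq(min(bin), max(bin))
  v <- ifelse(valid, samples$pupil_mm, 0)
  sums <- rowsum(v, factor(bin, levels = bins))
  cnt <- rowsum(as.numeric(valid), factor(bin, levels = bins))
  val <- as.vector(sums / cnt)
  val[cnt == 0] <- NA_real_
  data.frame(t = bins / out_rate_hz, value = val,
             n_valid = as.integer(cnt))
}

#' Per-participant z-scoring statistics
#'
#' Median and standard deviation over a participant's entire down-sampled
#' valid data (all sessions and conditions pooled); z = (x - median) / sd,
#' so the pooled data has median 0 and SD 1 by construction.
#'
#' @param x Numeric vector of all down-sampled values of one participant
#'   (NAs allowed, ignored).
#' @return List `(median, sd)`.
#' @export
zscore_stats <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2) stop("degenerate input: need >= 2 valid points",
                          call. = FALSE)
  s <- stats::sd(x)
  if (s == 0) stop("degenerate input: zero variance", call. = FALSE)
  list(median = stats::median(x), sd = s)
}

#' Baseline-correct an event-locked trace
#'
#' Subtracts the median of the valid bins inside the two-sided window
#' `[event_time - halfwidth, event_time + halfwidth)` from the whole trace.
#' Idempotent: the corrected trace's in-window median is exactly 0.
#'
#' @param trace Data frame with columns `t` and `value` (NAs allowed).
#' @param event_time Onset time on the same clock as `trace$t` (s).
#' @param halfwidth Window half-width (s).
#' @return `trace` with corrected `value`; attribute `baseline` holds the
#'   subtracted median. If the window holds no valid bin, `value` is all NA
#'   and attribute `excluded` gives the reason.
#' @export
baseline_correct <- function(trace, event_time, halfwidth = 0.2) {
  win <- trace$t >= event_time - halfwidth - 1e-9 &
    trace$t < event_time + halfwidth - 1e-9
  vals <- trace$value[win]
  vals <- vals[is.finite(vals)]
  if (!length(vals)) {
    trace$value <- NA_real_
    attr(trace, "excluded") <- "empty baseline window"
    return(trace)
  }
  b <- stats::median(vals)
  trace$value <- trace$value - b
  attr(trace, "baseline") <- b
  trace
}

# Clean one session: flag artifacts, drop saccade trials, down-sample the
# valid samples of retained trials. Returns the 20-Hz session trace (in mm),
# the trial keep/drop table and the artifact intervals.
clean_session <- function(session, params = cleaning_params()) {
  fl <- flag_invalid_samples(session$samples, params)
  sacc <- exclude_saccade_trials(session$samples, session$events, params)
  ep <- trial_epochs(session$events)
  keep_ep <- ep[ep$trial %in% sacc$trial[sacc$keep], ]
  in_kept <- rep(FALSE, nrow(session$samples))
  for (i in seq_len(nrow(keep_ep)))
    in_kept <- in_kept | (session$samples$t_s >= keep_ep$t_s_start[i] &
                            session$samples$t_s < keep_ep$t_s_end[i])
  ds <- downsample(session$samples, fl$valid & in_kept, params$out_rate_hz)
  list(trace = ds, trials = sacc, artifact_intervals = fl$intervals,
       events = session$events, design = session$design)
}

#' Preprocess all sessions of one participant
#'
#' Runs the fixed order of operations — artifact flagging, saccade-trial
#' exclusion, 20-Hz down-sampling of valid samples from retained trials,
#' z-scoring over the participant's pooled data, then median baseline
#' correction separately relative to the adapter (top-up) onset and the test
#' onset of each trial.
#'
#' @param sessions List of `raw_session` objects (same participant).
#' @param params A [cleaning_params()].
#' @return List with `trials` — long data frame (participant_id, experiment,
#'   session, condition, trial, numerosity, t_rel_test, z_adapt, z_test) for
#'   retained trials; `log` — per-trial exclusion ledger (trial labels, kept,
#'   reason); `stats` — the participant's z statistics; and
#'   `attrition` — counts (trials_in, trials_excluded, trials_featured).
#' @export
preprocess_participant <- function(sessions, params = cleaning_params()) {
  cleaned <- lapply(sessions, clean_session, params = params)
  st <- zscore_stats(unlist(lapply(cleaned, function(cs) cs$trace$value)))

  hw <- params$baseline_halfwidth_s
  pre <- ceiling((hw + 0.05) * params$out_rate_hz) / params$out_rate_hz
  rows <- list()
  logs <- list()
  for (cs in cleaned) {
    des <- cs$design
    z <- (cs$trace$value - st$median) / st$sd
    tr_t <- cs$trace$t
    ep <- trial_epochs(cs$events)
    test_on <- cs$events[cs$events$event == "test_on", c("trial", "t_s")]
    for (i in seq_len(nrow(des))) {
      trial_id <- des$trial[i]
      info <- des[i, c("participant_id", "experiment", "session",
                       "condition", "trial", "numerosity")]
      kept <- cs$trials$keep[cs$trials$trial == trial_id]
      if (!kept) {
        logs[[length(logs) + 1L]] <- cbind(info, data.frame(
          kept = FALSE, reason = "saccade", stringsAsFactors = FALSE))
        next
      }
      t0 <- ep$t_s_start[ep$trial == trial_id]  # top-up (adapter) onset
      t1 <- test_on$t_s[test_on$trial == trial_id]
      t2 <- ep$t_s_end[ep$trial == trial_id]
      idx <- which(tr_t >= t0 - pre - 1e-9 & tr_t < t2 - 1e-9)
      tr <- data.frame(t = tr_t[idx], value = z[idx])
      if (all(!is.finite(tr$value))) {
        logs[[length(logs) + 1L]] <- cbind(info, data.frame(
          kept = FALSE, reason = "no valid bins", stringsAsFactors = FALSE))
        next
      }
      ba <- baseline_correct(tr, t0, hw)
      bt <- baseline_correct(tr, t1, hw)
      if (!is.null(attr(ba, "excluded")) || !is.null(attr(bt, "excluded"))) {
        logs[[length(logs) + 1L]] <- cbind(info, data.frame(
          kept = FALSE, reason = "empty baseline window",
          stringsAsFactors = FALSE))
        next
      }
      rows[[length(rows) + 1L]] <- cbind(
        info[rep(1L, length(idx)), ],
        data.frame(t_rel_test = round((tr$t - t1) * 20) / 20,  # exact grid
                   z_adapt = ba$value, z_test = bt$value))
      logs[[length(logs) + 1L]] <- cbind(info, data.frame(
        kept = TRUE, reason = "", stringsAsFactors = FALSE))
    }
  }
  trials <- if (length(rows)) do.call(rbind, rows) else NULL
  if (!is.null(trials)) rownames(trials) <- NULL
  log <- do.call(rbind, logs)
  rownames(log) <- NULL
  list(trials = trials, log = log, stats = st,
       attrition = c(trials_in = nrow(log),
                     trials_excluded = sum(!log$kept),
                     trials_featured = sum(log$kept)))
}
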