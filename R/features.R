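# Per-trial scalar features from processed traces, condition averages, and
# per-participant adaptation effects for the pupil-behavior correlation.

# Half-open window membership on the 20-Hz grid: t in [start, end).
in_window <- function(t, start, end) t >= start - 1e-9 & t < end - 1e-9

#' Peak pupil constriction of one trial
#'
#' Minimum (most constricted, signed) baseline-corrected value over the
#' valid bins of the a-priori window 0.3-1.3 s after test onset.
#'
#' @param t_rel Bin times relative to test onset (s).
#' @param z Test-locked baseline-corrected values (NAs allowed).
#' @param window Constriction window `(start, end)` in s, half-open.
#' @return List `(peak, n_valid)`; `peak` is NA when no valid bin falls in
#'   the window (the trial is then excluded from models).
#' @export
peak_constriction <- function(t_rel, z, window = c(0.3, 1.3)) {
  w <- in_window(t_rel, window[1], window[2]) & is.finite(z)
  if (!any(w)) return(list(peak = NA_real_, n_valid = 0L))
  list(peak = min(z[w]), n_valid = sum(w))
}

#' Pre-test pupil size of one trial
#'
#' Mean of the valid adapter-locked (adapter-baselined) values in the 200 ms
#' before test onset; carries the residual, condition-dependent pupil-size
#' difference left by incomplete recovery from the adapter.
#'
#' @param t_rel Bin times relative to test onset (s).
#' @param z Adapter-locked baseline-corrected values (NAs allowed).
#' @param window Pre-test window `(start, end)` in s, half-open.
#' @return Mean value, or NA when the window holds no valid bin.
#' @export
pretest_pupil <- function(t_rel, z, window = c(-0.2, 0)) {
  w <- in_window(t_rel, window[1], window[2]) & is.finite(z)
  if (!any(w)) return(NA_real_)
  mean(z[w])
}

#' Extract per-trial features from a processed-trial table
#'
#' @param trials Long table from [preprocess_participant()] (columns
#'   participant_id, experiment, session, condition, numerosity, trial,
#'   t_rel_test, z_adapt, z_test).
#' @param peak_window,pretest_window Feature windows (s, half-open).
#' @return One row per trial: labels, `luminance` level (one per numerosity
#'   in experiment 2, constant in experiment 1), `peak_constriction`,
#'   `pretest_pupil`, `n_valid_bins_in_peak_window`.
#' @export
trial_features <- function(trials, peak_window = c(0.3, 1.3),
                           pretest_window = c(-0.2, 0)) {
  key <- interaction(trials$participant_id, trials$session, trials$trial,
                     drop = TRUE)
  idx <- split(seq_len(nrow(trials)), key)
  out <- lapply(idx, function(i) {
    tr <- trials[i, ]
    pk <- peak_constriction(tr$t_rel_test, tr$z_test, peak_window)
    data.frame(
      participant_id = tr$participant_id[1],
      experiment = tr$experiment[1],
      session = tr$session[1],
      condition = tr$condition[1],
      numerosity = tr$numerosity[1],
      trial = tr$trial[1],
      luminance = if (tr$experiment[1] == 2)
        paste0("exp2_n", tr$numerosity[1]) else "exp1",
      peak_constriction = pk$peak,
      pretest_pupil = pretest_pupil(tr$t_rel_test, tr$z_adapt,
                                    pretest_window),
      n_valid_bins_in_peak_window = pk$n_valid,
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$participant_id, res$session, res$trial), ]
}

#' Condition-average traces and their peaks
#'
#' Averages test-locked corrected traces across trials for each adaptation
#' condition x numerosity cell (missing bins respected), then takes the peak
#' of each average trace inside the constriction window — the same order of
#' operations used for the figure-style summaries (average first, then
#' peak). SEM of per-participant peaks is attached when several participants
#' are present.
#'
#' @param trials Long processed-trial table (possibly several participants).
#' @param peak_window Constriction window (s).
#' @return List: `traces` (condition, numerosity, t_rel_test, mean_z, n),
#'   `peaks` (condition, numerosity, peak, sem_across_participants).
#' @export
condition_averages <- function(trials, peak_window = c(0.3, 1.3)) {
  agg <- stats::aggregate(z_test ~ condition + numerosity + t_rel_test,
                          data = trials, FUN = mean, na.rm = TRUE,
                          na.action = stats::na.pass)
  names(agg)[names(agg) == "z_test"] <- "mean_z"
  cells <- unique(agg[, c("condition", "numerosity")])
  pk <- lapply(seq_len(nrow(cells)), function(i) {
    sub <- agg[agg$condition == cells$condition[i] &
                 agg$numerosity == cells$numerosity[i], ]
    # per-participant peaks of per-participant mean traces, for the SEM
    ppk <- vapply(unique(trials$participant_id), function(p) {
      tp <- trials[trials$participant_id == p &
                     trials$condition == cells$condition[i] &
                     trials$numerosity == cells$numerosity[i], ]
      if (!nrow(tp)) return(NA_real_)
      m <- stats::aggregate(z_test ~ t_rel_test, data = tp, FUN = mean,
                            na.rm = TRUE, na.action = stats::na.pass)
      peak_constriction(m$t_rel_test, m$z_test, peak_window)$peak
    }, numeric(1))
    ppk <- ppk[is.finite(ppk)]
    data.frame(
      condition = cells$condition[i], numerosity = cells$numerosity[i],
      peak = peak_constriction(sub$t_rel_test, sub$mean_z, peak_window)$peak,
      sem_across_participants = if (length(ppk) > 1)
        stats::sd(ppk) / sqrt(length(ppk)) else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  peaks <- do.call(rbind, pk)
  peaks <- peaks[order(peaks$condition, peaks$numerosity), ]
  rownames(peaks) <- NULL
  list(traces = agg[order(agg$condition, agg$numerosity, agg$t_rel_test), ],
       peaks = peaks)
}

#' Pupillary adaptation effect of one participant
#'
#' Averages the participant's test-locked traces across numerosities within
#' each adaptation condition, takes the constriction-window peak of each
#' average trace, and returns peak(high) - peak(low). Weaker constriction
#' after adapting to high numerosity gives a positive value.
#'
#' @param trials Processed-trial table of a single participant.
#' @param peak_window Constriction window (s).
#' @return Numeric difference, or NA when a condition is entirely missing
#'   (the participant is then dropped from the correlation).
#' @export
adaptation_effect_pupil <- function(trials, peak_window = c(0.3, 1.3)) {
  pk <- vapply(c("high", "low"), function(cond) {
    sub <- trials[trials$condition == cond, ]
    if (!nrow(sub)) return(NA_real_)
    m <- stats::aggregate(z_test ~ t_rel_test, data = sub, FUN = mean,
                          na.rm = TRUE, na.action = stats::na.pass)
    peak_constriction(m$t_rel_test, m$z_test, peak_window)$peak
  }, numeric(1))
  if (anyNA(pk)) return(NA_real_)
  pk[["high"]] - pk[["low"]]
}

#' Behavioral adaptation effect of one participant
#'
#' Difference of mean verbal estimates of the highest test numerosity:
#' adapt-low minus adapt-high, so stronger adaptation gives a larger value.
#'
#' @param estimates Estimate records of a single participant.
#' @param numerosity Test numerosity used (default 40, where the
#'   psychophysical effect is strongest).
#' @return Numeric difference, or NA when either condition cell is missing.
#' @export
adaptation_effect_behavior <- function(estimates, numerosity = 40) {
  hi <- estimates$estimate[estimates$numerosity == numerosity &
                             estimates$condition == "high"]
  lo <- estimates$estimate[estimates$numerosity == numerosity &
                             estimates$condition == "low"]
  if (!length(hi) || !length(lo)) return(NA_real_)
  mean(lo) - mean(hi)
}
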