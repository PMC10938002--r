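# End-to-end orchestration: simulate -> preprocess -> features -> stats,
# with derived stage seeds, attrition accounting and a reproducible
# manifest.

#' Pipeline run configuration
#'
#' @param n_participants Cohort size (default 22, the pooled sample;
#'   participants are assigned alternately to experiments 1 and 2).
#' @param experiments Experiments to include (subset of 1:2).
#' @param reps_per_numerosity_per_session Repetitions per numerosity per
#'   session (default 18, i.e. 360 trials per participant).
#' @param sim A [sim_params()] (its `n_participants` is overridden).
#' @param cleaning A [cleaning_params()].
#' @param spec A [stimulus_spec()]. The default widens the field to 30 deg
#'   because the printed 11-deg field cannot contain the printed dot areas
#'   (see [stimulus_spec()]).
#' @param out_dir Output directory (created if missing).
#' @param master_seed Integer master seed; all stage seeds derive from it.
#' @param make_figures Write summary figures (requires a PNG device).
#' @return Object of class `run_config`.
#' @export
run_config <- function(n_participants = 22L, experiments = c(1L, 2L),
                       reps_per_numerosity_per_session = 18L,
                       sim = sim_params(), cleaning = cleaning_params(),
                       spec = stimulus_spec(field_diameter = 30),
                       out_dir = tempfile("pupilnum_run_"),
                       master_seed = 1L,
                       make_figures = isTRUE(capabilities("png"))) {
  stopifnot(n_participants >= 1, all(experiments %in% 1:2),
            reps_per_numerosity_per_session >= 1)
  sim$n_participants <- as.integer(n_participants)
  structure(list(
    n_participants = as.integer(n_participants),
    experiments = as.integer(experiments),
    reps = as.integer(reps_per_numerosity_per_session),
    sim = sim, cleaning = cleaning, spec = spec,
    out_dir = out_dir, master_seed = as.integer(master_seed),
    make_figures = isTRUE(make_figures)
  ), class = "run_config")
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full pipeline
#'
#' Generates example stimuli, a full trial design, synthetic eye-tracking
#' sessions and verbal estimates for every participant; preprocesses and
#' extracts features participant by participant; fits the pupil and
#' behavior models and the pupil-behavior correlation; and writes all
#' tables (TSV), model results (JSON), optional figures and a manifest with
#' seeds, attrition counts and output checksums. Identical configuration
#' gives identical manifest hashes.
#'
#' @param config A [run_config()].
#' @return The manifest, invisibly (also written as `manifest.json`).
#' @export
run_all <- function(config) {
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  ms <- config$master_seed

  # --- stimuli ---------------------------------------------------------
  stage("stimuli", {
    dir.create(file.path(out, "stimuli"), showWarnings = FALSE)
    for (cond in c("high", "low"))
      write_array_json(
        make_adapter(cond, config$spec, seed = derive_seed(ms, "adapter", cond)),
        file.path(out, "stimuli", sprintf("adapter_%s.json", cond)))
    for (ex in config$experiments)
      for (n in config$spec$test_numerosities)
        write_array_json(
          make_test(n, ex, config$spec,
                    seed = derive_seed(ms, "test", ex, n)),
          file.path(out, "stimuli", sprintf("test_e%d_n%02d.json", ex, n)))
  })

  # --- design ----------------------------------------------------------
  profiles <- participant_profiles(config$sim,
                                   seed = derive_seed(ms, "profiles"))
  expt <- rep_len(config$experiments, config$n_participants)
  design <- stage("design",
    build_design(profiles$participant_id, experiment = expt,
                 reps_per_numerosity_per_session = config$reps,
                 spec = config$spec, seed = derive_seed(ms, "design")))
  write_tsv(design, file.path(out, "design.tsv"))

  # --- simulate + preprocess + features, streamed per participant ------
  feats <- list(); logs <- list(); cond_means <- list(); pupil_eff <- list()
  attrition <- list()
  for (p in seq_len(config$n_participants)) {
    pid <- profiles$participant_id[p]
    pdes <- design[design$participant_id == pid, ]
    sessions <- stage("simulate", lapply(sort(unique(pdes$session)),
      function(s) simulate_session(pdes[pdes$session == s, ], config$sim,
                                   profiles[p, ],
                                   seed = derive_seed(ms, "session", pid, s))))
    pp <- stage("preprocess", preprocess_participant(sessions, config$cleaning))
    logs[[pid]] <- pp$log
    attrition[[pid]] <- pp$attrition
    if (!is.null(pp$trials)) {
      feats[[pid]] <- stage("features", trial_features(pp$trials))
      cm <- condition_averages(pp$trials)
      cm$traces$participant_id <- pid
      cond_means[[pid]] <- cm$traces
      pupil_eff[[pid]] <- data.frame(
        participant_id = pid,
        pupil_effect = adaptation_effect_pupil(pp$trials),
        stringsAsFactors = FALSE)
    }
  }
  features <- do.call(rbind, feats); rownames(features) <- NULL
  exclusions <- do.call(rbind, logs); rownames(exclusions) <- NULL
  write_tsv(features, file.path(out, "features.tsv"))
  write_tsv(exclusions, file.path(out, "exclusions.tsv"))

  # --- estimates (psychophysical sessions, separate design) ------------
  est_design <- build_design(profiles$participant_id, experiment = expt,
                             reps_per_numerosity_per_session = config$reps,
                             spec = config$spec,
                             seed = derive_seed(ms, "est_design"))
  estimates <- stage("estimates",
    simulate_estimates(est_design, config$sim, profiles,
                       seed = derive_seed(ms, "estimates")))
  write_tsv(estimates, file.path(out, "estimates.tsv"))

  # --- models ----------------------------------------------------------
  pupil_model <- stage("pupil_model", fit_pupil_model(features))
  behavior_model <- stage("behavior_model", fit_behavior_model(estimates))
  write_model_json(pupil_model, file.path(out, "pupil_model.json"))
  write_model_json(behavior_model, file.path(out, "behavior_model.json"))

  behav_eff <- do.call(rbind, lapply(split(estimates,
                                           estimates$participant_id),
    function(s) data.frame(participant_id = s$participant_id[1],
                           behavior_effect = adaptation_effect_behavior(s),
                           stringsAsFactors = FALSE)))
  correlation <- if (config$n_participants >= 3) {
    stage("correlation",
          correlate_effects(do.call(rbind, pupil_eff), behav_eff))
  } else NULL  # Pearson r undefined below 3 participants; smoke scale
  write_tsv(if (is.null(correlation))
              merge(do.call(rbind, pupil_eff), behav_eff,
                    by = "participant_id")
            else correlation$pairs,
            file.path(out, "correlation_pairs.tsv"))

  cond_avg <- stage("condition_averages", {
    allcm <- do.call(rbind, cond_means)
    agg <- stats::aggregate(mean_z ~ condition + numerosity + t_rel_test,
                            data = allcm, FUN = mean, na.rm = TRUE,
                            na.action = stats::na.pass)
    write_tsv(agg, file.path(out, "condition_average_traces.tsv"))
    agg
  })

  if (config$make_figures && !is.null(correlation))
    tryCatch(pipeline_figures(cond_avg, features, correlation, out),
             error = function(e)
               message("figure generation skipped: ", conditionMessage(e)))

  # --- manifest --------------------------------------------------------
  att <- do.call(rbind, attrition)
  files <- list.files(out, recursive = TRUE, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  manifest <- list(
    package_version = as.character(utils::packageVersion("pupilnum")),
    master_seed = ms,
    n_participants = config$n_participants,
    trials_per_participant_designed = 4L * 5L * config$reps,
    attrition = data.frame(participant_id = rownames(att), att,
                           row.names = NULL),
    correlation = if (is.null(correlation)) NULL else
      list(r = correlation$r, p = correlation$p, n = correlation$n),
    file_md5 = as.list(tools::md5sum(files))
  )
  names(manifest$file_md5) <- basename(files)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

# Condition-average trace figure, peak-by-numerosity figure, and the
# pupil-behavior correlation scatter.
pipeline_figures <- function(cond_avg, features, correlation, out) {
  cols <- c(high = "firebrick", low = "steelblue")
  grDevices::png(file.path(out, "fig_traces.png"), 900, 600)
  graphics::plot(NULL, xlim = range(cond_avg$t_rel_test),
                 ylim = range(cond_avg$mean_z, na.rm = TRUE),
                 xlab = "time from test onset (s)", ylab = "pupil size (z)")
  for (cond in unique(cond_avg$condition))
    for (n in unique(cond_avg$numerosity)) {
      s <- cond_avg[cond_avg$condition == cond & cond_avg$numerosity == n, ]
      graphics::lines(s$t_rel_test, s$mean_z, col = cols[cond])
    }
  graphics::abline(v = 0, lty = 2)
  graphics::legend("bottomright", legend = names(cols), col = cols, lty = 1)
  grDevices::dev.off()

  pk <- stats::aggregate(peak_constriction ~ condition + numerosity,
                         data = features, FUN = mean, na.rm = TRUE)
  grDevices::png(file.path(out, "fig_peaks.png"), 700, 500)
  graphics::plot(NULL, xlim = range(pk$numerosity),
                 ylim = range(pk$peak_constriction),
                 xlab = "test numerosity", ylab = "mean peak constriction (z)",
                 log = "x")
  for (cond in unique(pk$condition)) {
    s <- pk[pk$condition == cond, ]
    s <- s[order(s$numerosity), ]
    graphics::lines(s$numerosity, s$peak_constriction, type = "b",
                    col = cols[cond], pch = 16)
  }
  graphics::legend("topright", legend = names(cols), col = cols, lty = 1)
  grDevices::dev.off()

  grDevices::png(file.path(out, "fig_correlation.png"), 600, 600)
  graphics::plot(correlation$pairs$behavior_effect,
                 correlation$pairs$pupil_effect,
                 xlab = "behavioral adaptation effect (estimate diff @ N=40)",
                 ylab = "pupil adaptation effect (peak diff, high - low)",
                 pch = 16)
  graphics::abline(stats::lm(pupil_effect ~ behavior_effect,
                             data = correlation$pairs), col = "gray40")
  graphics::title(sprintf("r = %.2f, p = %.3g", correlation$r,
                          correlation$p))
  grDevices::dev.off()
  invisible(NULL)
}
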