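# Trial-level mixed-effects inference: the pupil model (numerosity +
# adaptation + pre-test pupil, random intercepts for participant,
# experiment and luminance), the behavior model (numerosity x adaptation,
# random intercepts for participant and experiment, 3-SD outlier rule), and
# the pupil-behavior adaptation correlation across participants.

# Marginal (type-III-style) F tests of each fixed-effect term from a fitted
# model. Factors must be coded with sum-to-zero contrasts for these Wald
# tests to be order-invariant. Denominator df = n_obs - rank(X), matching
# the F(1, n - p) style of trial-level reports.
term_f_tests <- function(fit, X) {
  b <- if (inherits(fit, "merMod")) lme4::fixef(fit) else stats::coef(fit)
  V <- as.matrix(stats::vcov(fit))
  asgn <- attr(X, "assign")
  labels <- attr(X, "term.labels")
  est <- names(b)[!is.na(b)]
  keep <- match(est, colnames(X))
  n <- nrow(X)
  p <- length(est)
  terms_id <- sort(unique(asgn[asgn > 0]))
  out <- lapply(terms_id, function(j) {
    cols <- which(asgn == j)
    cols <- cols[colnames(X)[cols] %in% est]
    if (!length(cols)) return(NULL)
    bi <- b[colnames(X)[cols]]
    Vi <- V[colnames(X)[cols], colnames(X)[cols], drop = FALSE]
    q <- length(bi)
    Fv <- as.numeric(t(bi) %*% solve(Vi) %*% bi) / q
    data.frame(term = labels[j], F = Fv, df1 = q, df2 = n - p,
               p = stats::pf(Fv, q, n - p, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random-effect terms with non-degenerate grouping in `data`.
usable_re <- function(data, candidates) {
  keep <- vapply(candidates, function(v) {
    v %in% names(data) && length(unique(data[[v]])) >= 2
  }, logical(1))
  candidates[keep]
}

# Fit lmer with the given fixed formula and random-intercept terms,
# dropping zero-variance random terms (singular fits) one at a time; falls
# back to lm when none survive.
fit_with_fallback <- function(fixed, re_terms, data) {
  dropped <- character(0)
  repeat {
    if (!length(re_terms)) {
      fit <- stats::lm(fixed, data = data)
      return(list(fit = fit, re = character(0), dropped = dropped))
    }
    form <- stats::as.formula(paste(
      deparse(fixed, width.cutoff = 500L), "+",
      paste(sprintf("(1 | %s)", re_terms), collapse = " + ")))
    fit <- suppressMessages(suppressWarnings(
      lme4::lmer(form, data = data, REML = TRUE,
                 control = lme4::lmerControl(calc.derivs = FALSE,
                                             check.conv.singular = "ignore"))))
    vc <- as.data.frame(lme4::VarCorr(fit))
    vc <- vc[vc$grp != "Residual", ]
    zero <- vc$grp[vc$vcov < 1e-10]
    if (!length(zero)) return(list(fit = fit, re = re_terms,
                                   dropped = dropped))
    dropped <- c(dropped, zero[1])
    re_terms <- setdiff(re_terms, zero[1])
  }
}

model_result <- function(fit, X, type, n_obs, n_dropped_rows, re_terms,
                         dropped_re, dropped_fixed, formula_str) {
  vc <- if (inherits(fit, "merMod")) {
    v <- as.data.frame(lme4::VarCorr(fit))
    data.frame(group = v$grp, variance = v$vcov, stringsAsFactors = FALSE)
  } else data.frame(group = "Residual",
                    variance = summary(fit)$sigma^2)
  b <- if (inherits(fit, "merMod")) lme4::fixef(fit) else stats::coef(fit)
  structure(list(
    type = type,
    terms = term_f_tests(fit, X),
    coefficients = b,
    random = vc,
    n_obs = n_obs,
    n_dropped_rows = n_dropped_rows,
    random_terms = re_terms,
    dropped_random = dropped_re,
    dropped_fixed = dropped_fixed,
    formula = formula_str,
    fit = fit
  ), class = "pupilnum_model")
}

#' @export
print.pupilnum_model <- function(x, ...) {
  cat(sprintf("<pupilnum_model> %s model, %d observations (%d rows dropped)\n",
              x$type, x$n_obs, x$n_dropped_rows))
  cat("  ", x$formula, "\n", sep = "")
  tt <- x$terms
  for (i in seq_len(nrow(tt)))
    cat(sprintf("  %-28s F(%d,%d) = %8.2f, p = %.3g\n", tt$term[i],
                tt$df1[i], tt$df2[i], tt$F[i], tt$p[i]))
  if (length(x$dropped_random))
    cat("  dropped zero-variance random terms:",
        paste(x$dropped_random, collapse = ", "), "\n")
  if (length(x$dropped_fixed))
    cat("  dropped degenerate fixed terms:",
        paste(x$dropped_fixed, collapse = ", "), "\n")
  invisible(x)
}

#' Fit the trial-level pupil model
#'
#' Gaussian identity-link mixed model of per-trial peak constriction with
#' fixed effects numerosity (continuous), adaptation condition (2 levels,
#' sum coding) and pre-test pupil size (continuous), and random intercepts
#' for participant, experiment and luminance level. Rows with missing
#' features are dropped and counted; zero-variance random terms (e.g.
#' luminance when only experiment 1 is present) and constant covariates are
#' dropped automatically and reported.
#'
#' @param features Features table from [trial_features()] or
#'   [simulate_features()] (columns participant_id, experiment, condition,
#'   numerosity, luminance, peak_constriction, pretest_pupil).
#' @return A `pupilnum_model`; `$terms` holds one marginal F test per fixed
#'   effect.
#' @export
fit_pupil_model <- function(features) {
  d <- features
  ok <- is.finite(d$peak_constriction) & is.finite(d$pretest_pupil)
  n_drop <- sum(!ok)
  d <- d[ok, ]
  d$adaptation <- factor(d$condition, levels = c("low", "high"))
  stats::contrasts(d$adaptation) <- stats::contr.sum(2)
  d$participant <- factor(d$participant_id)
  d$experiment <- factor(d$experiment)
  if (!is.null(d$luminance)) d$luminance <- factor(d$luminance)

  dropped_fixed <- character(0)
  rhs <- c("numerosity", "adaptation", "pretest_pupil")
  if (stats::var(d$pretest_pupil) < 1e-12) {
    rhs <- setdiff(rhs, "pretest_pupil")
    dropped_fixed <- "pretest_pupil"
  }
  fixed <- stats::as.formula(
    paste("peak_constriction ~", paste(rhs, collapse = " + ")))
  X <- stats::model.matrix(fixed, d)
  attr(X, "term.labels") <- attr(stats::terms(fixed), "term.labels")

  re <- usable_re(d, c("participant", "experiment", "luminance"))
  fw <- fit_with_fallback(fixed, re, d)
  model_result(fw$fit, X, "pupil", nrow(d), n_drop, fw$re, fw$dropped,
               dropped_fixed,
               paste(deparse(fixed), "+ (1|", paste(fw$re, collapse = ") + (1|"),
                     ")"))
}

#' Remove outlying estimates by the 3-SD rule
#'
#' Flags estimates farther than `k` standard deviations from the mean of
#' their participant x condition x numerosity cell (cells with fewer than 3
#' responses, where the SD is unstable, are kept whole).
#'
#' @param estimates Estimate records.
#' @param k SD multiple (default 3).
#' @return Logical vector, TRUE for rows to keep.
#' @export
outlier_keep <- function(estimates, k = 3) {
  cell <- interaction(estimates$participant_id, estimates$condition,
                      estimates$numerosity, drop = TRUE)
  keep <- rep(TRUE, nrow(estimates))
  for (i in split(seq_len(nrow(estimates)), cell)) {
    if (length(i) < 3) next
    x <- estimates$estimate[i]
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) next
    keep[i] <- abs(x - mean(x)) <= k * s
  }
  keep
}

#' Fit the trial-level behavior model
#'
#' Applies the 3-SD outlier rule, then fits verbal estimates with fixed
#' effects numerosity (5-level factor, sum coding), adaptation condition and
#' their interaction (the 4-df term that captures the underestimation gap
#' growing with numerosity), with random intercepts for participant and
#' experiment.
#'
#' @param estimates Estimate records from [simulate_estimates()] (or real
#'   data shaped likewise).
#' @return A `pupilnum_model`.
#' @export
fit_behavior_model <- function(estimates) {
  keep <- outlier_keep(estimates)
  d <- estimates[keep & is.finite(estimates$estimate), ]
  n_drop <- nrow(estimates) - nrow(d)
  cells <- table(d$condition, d$numerosity)
  if (any(cells == 0)) {
    bad <- which(cells == 0, arr.ind = TRUE)[1, ]
    stop(sprintf("empty cell after outlier removal: condition %s, numerosity %s",
                 rownames(cells)[bad[1]], colnames(cells)[bad[2]]),
         call. = FALSE)
  }
  d$adaptation <- factor(d$condition, levels = c("low", "high"))
  stats::contrasts(d$adaptation) <- stats::contr.sum(2)
  d$numerosity_f <- factor(d$numerosity)
  stats::contrasts(d$numerosity_f) <-
    stats::contr.sum(length(levels(d$numerosity_f)))
  d$participant <- factor(d$participant_id)
  d$experiment <- factor(d$experiment)

  fixed <- estimate ~ numerosity_f * adaptation
  X <- stats::model.matrix(fixed, d)
  attr(X, "term.labels") <- attr(stats::terms(fixed), "term.labels")
  re <- usable_re(d, c("participant", "experiment"))
  fw <- fit_with_fallback(fixed, re, d)
  model_result(fw$fit, X, "behavior", nrow(d), n_drop, fw$re, fw$dropped,
               character(0),
               paste(deparse(fixed), "+ (1|", paste(fw$re, collapse = ") + (1|"),
                     ")"))
}

#' Correlate pupillary and behavioral adaptation effects
#'
#' Pearson correlation across participants between the pupil adaptation
#' effect (peak difference of numerosity-averaged traces, high minus low)
#' and the behavioral effect (estimate difference at the highest
#' numerosity, low minus high).
#'
#' @param pupil_effects Data frame `(participant_id, pupil_effect)`.
#' @param behavior_effects Data frame `(participant_id, behavior_effect)`.
#' @return List `(r, p, n, pairs)` of class `pupilnum_correlation`.
#' @export
correlate_effects <- function(pupil_effects, behavior_effects) {
  m <- merge(pupil_effects, behavior_effects, by = "participant_id")
  m <- m[is.finite(m$pupil_effect) & is.finite(m$behavior_effect), ]
  if (nrow(m) < 3)
    stop("need >= 3 participants with both effects", call. = FALSE)
  if (stats::sd(m$pupil_effect) == 0 || stats::sd(m$behavior_effect) == 0)
    stop("undefined correlation: zero variance in one modality",
         call. = FALSE)
  ct <- stats::cor.test(m$pupil_effect, m$behavior_effect,
                        method = "pearson")
  structure(list(r = unname(ct$estimate), p = ct$p.value, n = nrow(m),
                 pairs = m), class = "pupilnum_correlation")
}

#' @export
print.pupilnum_correlation <- function(x, ...) {
  cat(sprintf("<pupilnum_correlation> Pearson r = %.3f, p = %.3g, n = %d\n",
              x$r, x$p, x$n))
  invisible(x)
}

#' Serialize a model result to JSON
#'
#' @param model A `pupilnum_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  jsonlite::write_json(list(
    type = model$type,
    formula = model$formula,
    terms = model$terms,
    coefficients = as.list(model$coefficients),
    random = model$random,
    n_obs = model$n_obs,
    n_dropped_rows = model$n_dropped_rows,
    dropped_random = model$dropped_random,
    dropped_fixed = model$dropped_fixed
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
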