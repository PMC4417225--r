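#' Two-stage mixed-effects model (BLUPs as predictors)
#'
#' Stage 1 summarizes each subject's exposure trajectory with a linear
#' mixed model (random intercept and, by default, random slope over
#' gestational weeks; time-varying covariates as fixed effects). Stage 2
#' regresses the outcome on the subject-level BLUPs (predicted intercept,
#' and slope when retained) plus baseline covariates. Under the `"auto"`
#' policy Stage 1 is demoted to a random-intercept-only model when the
#' slope structure is degenerate or unsupported: a boundary/singular fit,
#' |intercept-slope correlation| above `demote_correlation`
#' (near-collinear random effects), or a REML likelihood-ratio comparison
#' against the intercept-only model below the 95% chi-square(2) critical
#' value (the slope adds one variance and one correlation parameter; the
#' boundary makes this conservative toward demotion). This mirrors the
#' practice of refitting without the random slope when it contributes
#' nothing.
#'
#' Stage-1 estimation uncertainty is *not* propagated into Stage-2
#' standard errors; the simulation harness measures the resulting
#' undercoverage rather than hiding it.
#'
#' @param cohort an ln-scale cohort.
#' @param slope_policy `"auto"`, `"force_slope"`, or `"intercept_only"`.
#' @param demote_correlation |correlation| above which `"auto"` drops the
#'   random slope.
#' @return a [method_result()]; `extra$stage1` holds the `lmm_fit` and
#'   `extra$demoted` whether the slope was dropped.
#' @export
two_stage_blup_model <- function(cohort, slope_policy = c("auto", "force_slope", "intercept_only"),
                                 demote_correlation = 0.95) {
  slope_policy <- match.arg(slope_policy)
  st <- stage1_with_policy(cohort, slope_policy, demote_correlation)
  s1 <- st$s1
  notes <- st$notes
  demoted <- st$demoted
  dat <- dplyr::left_join(
    s1$blups,
    cohort_subjects(cohort)[, c("subject_id", "outcome", active_baseline(cohort))],
    by = "subject_id"
  )
  terms <- c("intercept", if (s1$used_slope) "slope")
  X <- build_design(dat, c(terms, active_baseline(cohort)))
  fit <- fit_logistic(dat$outcome, X)
  est <- wald_row(fit, terms)
  est$term <- paste0("blup_", est$term)
  method_result(
    method = "two_stage_blup", estimates = est, n_used = nrow(dat),
    notes = c(notes, fit$notes),
    extra = list(stage1 = s1, stage2 = fit, demoted = demoted)
  )
}

#' Two-stage model on clusters of BLUPs
#'
#' Instead of entering the BLUPs continuously, groups subjects by k-means
#' on the standardized (intercept, slope) plane and regresses the outcome
#' on the cluster membership. Clusters are relabelled by ascending mean
#' intercept so that the highest index is the "greater predicted
#' intercept" group and odds ratios have a stable reference (cluster 1).
#'
#' @param cohort an ln-scale cohort.
#' @param k number of clusters (2 <= k < N/10).
#' @param seed seed for the k-means restarts.
#' @return a [method_result()]; `extra$assignment` maps subjects to
#'   clusters, `extra$stage1` is the mixed-model fit.
#' @export
two_stage_cluster_model <- function(cohort, k = 2, seed = 1) {
  st <- stage1_with_policy(cohort, "auto", demote_correlation = 0.95)
  if (st$demoted || !st$s1$used_slope) {
    stop_input("random-slope structure is degenerate here; use two_stage_blup_model")
  }
  s1 <- st$s1
  N <- nrow(s1$blups)
  if (k < 2 || k >= N / 10) stop_input("k must satisfy 2 <= k < N/10")
  Z <- scale(as.matrix(s1$blups[, c("intercept", "slope")]))
  km <- with_seed(seed, kmeans(Z, centers = k, nstart = 20))
  relabel <- order(tapply(s1$blups$intercept, km$cluster, mean))
  cl <- match(km$cluster, relabel)
  assignment <- tibble::tibble(subject_id = s1$blups$subject_id, cluster = cl)

  dat <- dplyr::left_join(
    assignment,
    cohort_subjects(cohort)[, c("subject_id", "outcome", active_baseline(cohort))],
    by = "subject_id"
  )
  dat$cluster <- factor(dat$cluster, levels = seq_len(k))
  X <- build_design(dat, c("cluster", active_baseline(cohort)))
  fit <- fit_logistic(dat$outcome, X)
  est <- wald_row(fit, paste0("cluster", 2:k))
  method_result(
    method = "two_stage_cluster", estimates = est, n_used = nrow(dat),
    notes = fit$notes,
    extra = list(stage1 = s1, stage2 = fit, assignment = assignment,
                 sizes = as.integer(table(cl)))
  )
}

# Shared Stage-1 policy: fit, and demote the random slope when degenerate
# or unsupported by a REML likelihood-ratio comparison.
stage1_with_policy <- function(cohort, policy, demote_correlation) {
  notes <- character()
  demoted <- FALSE
  if (policy == "intercept_only") {
    return(list(s1 = fit_lmm(cohort, random_slope = FALSE),
                notes = notes, demoted = FALSE))
  }
  s1 <- fit_lmm(cohort, random_slope = TRUE)
  if (policy == "auto") {
    s0 <- fit_lmm(cohort, random_slope = FALSE)
    lrt <- 2 * (s1$reml_loglik - s0$reml_loglik)
    bad <- s1$singular || s1$var_slope <= 1e-10 ||
      (is.finite(s1$re_correlation) &&
         abs(s1$re_correlation) > demote_correlation) ||
      lrt < stats::qchisq(0.95, df = 2)
    if (bad) {
      demoted <- TRUE
      notes <- sprintf(
        "random slope demoted (corr=%.2f, var_slope=%.3g, REML LRT=%.2f%s); refit intercept-only",
        s1$re_correlation, s1$var_slope, lrt,
        if (s1$singular) ", boundary" else ""
      )
      s1 <- s0
    }
  }
  list(s1 = s1, notes = notes, demoted = demoted)
}
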