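#' Simultaneous multiple logistic regression across visits
#'
#' Regresses the binary outcome on the exposures at every visit at once,
#' with time-varying covariates entered per visit and baseline covariates
#' once. Only subjects observed at all visits can contribute
#' (complete-case), so `n_used` shrinks under dropout; correlated repeated
#' exposures can inflate standard errors. With `bayes = TRUE` the visit
#' exposure block is estimated by MAP under a temporally correlated
#' Gaussian (AR(1)) prior, shrinking the visit coefficients toward zero
#' and toward each other (see [fit_map_logistic()]).
#'
#' @param cohort an ln-scale cohort.
#' @param bayes use the shrinkage-prior variant.
#' @param tau2,rho prior variance/correlation passed to
#'   [fit_map_logistic()] (`NULL` = grid selection).
#' @param exposure_transform optional function applied to the ln exposure
#'   before modelling (non-linearity hook); default identity.
#' @return a [method_result()].
#' @export
multiple_logistic_model <- function(cohort, bayes = FALSE, tau2 = NULL, rho = NULL,
                                    exposure_transform = NULL) {
  wide <- wide_model_frame(cohort, exposure_transform)
  if (nrow(wide$data) < 10) {
    stop_input("fewer than 10 complete-case subjects (", nrow(wide$data), ")")
  }
  X <- build_design(wide$data, c(wide$exposure_cols, wide$tv_cols, wide$baseline_cols))
  y <- wide$data$outcome
  fit <- if (bayes) {
    fit_map_logistic(y, X, exposure_block = wide$exposure_cols, tau2 = tau2, rho = rho)
  } else {
    fit_logistic(y, X)
  }
  est <- wald_row(fit, wide$exposure_cols)
  notes <- fit$notes
  if (bayes) {
    notes <- c(notes, sprintf("MAP prior: tau2=%.3g, rho=%.2g", fit$tau2, fit$rho))
  }
  method_result(
    method = if (bayes) "bayes_multiple_logistic" else "multiple_logistic",
    estimates = est, n_used = length(y), notes = notes,
    extra = list(fit = fit)
  )
}

# complete-case wide frame: exposure and tv covariates spread by visit
wide_model_frame <- function(cohort, exposure_transform = NULL) {
  nm <- n_visits(cohort)
  df <- tibble::as_tibble(cohort)
  if (!is.null(exposure_transform)) df$exposure <- exposure_transform(df$exposure)
  tv <- active_tv(cohort)
  value_cols <- c("exposure", tv)
  wide <- tidyr::pivot_wider(
    df[, c("subject_id", "visit", value_cols)],
    names_from = "visit", values_from = dplyr::all_of(value_cols),
    names_glue = "{.value}_visit{visit}", names_sort = TRUE
  )
  expo_cols <- paste0("exposure_visit", 1:nm)
  tv_cols <- as.vector(outer(tv, 1:nm, function(a, b) paste0(a, "_visit", b)))
  for (cc in setdiff(c(expo_cols, tv_cols), names(wide))) wide[[cc]] <- NA_real_
  wide <- wide[stats::complete.cases(wide[, expo_cols]), , drop = FALSE]
  bc <- active_baseline(cohort)
  wide <- dplyr::left_join(wide, cohort_subjects(cohort)[, c("subject_id", "outcome", bc)],
                           by = "subject_id")
  list(data = wide, exposure_cols = expo_cols, tv_cols = tv_cols, baseline_cols = bc)
}

#' Parallel cross-sectional logistic models, one per visit
#'
#' Fits a separate logistic model at each visit on the subjects observed
#' there, avoiding between-visit collinearity at the cost of multiple
#' testing. Optionally Bonferroni-adjusts the per-visit p-values. The
#' result also embeds the pooled-GEE joint equality test of
#' H0: beta_1 = ... = beta_n (see [fit_pooled_gee()]) as a global test.
#'
#' @inheritParams multiple_logistic_model
#' @param correction `"none"` or `"bonferroni"` (per-visit p times the
#'   number of visits, capped at 1, reported in column `p_adjusted`).
#' @param gee also run the pooled GEE equality test (set `FALSE` to skip).
#' @return a [method_result()] with one estimate row per visit and
#'   per-visit `n_used` in `extra$per_visit_n`.
#' @export
cross_sectional_models <- function(cohort, correction = c("none", "bonferroni"),
                                   gee = TRUE, exposure_transform = NULL) {
  correction <- match.arg(correction)
  nm <- n_visits(cohort)
  df <- tibble::as_tibble(cohort)
  if (!is.null(exposure_transform)) df$exposure <- exposure_transform(df$exposure)
  tv <- active_tv(cohort)
  bc <- active_baseline(cohort)
  subj <- cohort_subjects(cohort)

  rows <- list()
  fits <- list()
  n_per <- integer(nm)
  for (j in seq_len(nm)) {
    dj <- df[df$visit == j, , drop = FALSE]
    dj <- dplyr::left_join(dj[, c("subject_id", "outcome", "exposure", tv)],
                           subj[, c("subject_id", bc)], by = "subject_id")
    n_per[j] <- nrow(dj)
    X <- build_design(dj, c("exposure", tv, bc))
    fit <- fit_logistic(dj$outcome, X)
    fits[[j]] <- fit
    row <- wald_row(fit, "exposure")
    row$term <- paste0("exposure_visit", j)
    rows[[j]] <- row
  }
  est <- dplyr::bind_rows(rows)
  if (correction == "bonferroni") {
    est$p_adjusted <- pmin(est$p * nm, 1)
  }
  gt <- NULL
  if (gee && nm > 1) {
    gfit <- fit_pooled_gee(cohort)
    gt <- tibble::tibble(
      test = "gee_equality", statistic = gfit$equality_stat,
      df = gfit$equality_df, p = gfit$equality_p
    )
  }
  method_result(
    method = "cross_sectional", estimates = est, global_tests = gt,
    n_used = length(unique(df$subject_id)),
    notes = if (correction == "bonferroni") "Bonferroni-adjusted p in p_adjusted" else character(),
    extra = list(per_visit_n = n_per, fits = fits)
  )
}

#' Logistic model on the subject-mean exposure
#'
#' Summarizes each subject's repeated measurements by the arithmetic mean
#' of the ln values over available visits (equivalently the ln of the
#' geometric mean concentration) and fits a subject-level logistic model.
#' Time-varying covariates are averaged per subject, so a binary
#' time-of-day indicator becomes the proportion of afternoon samples.
#' All subjects with at least one visit are used.
#'
#' @inheritParams multiple_logistic_model
#' @return a [method_result()] with one `mean_exposure` row.
#' @export
mean_summary_model <- function(cohort, exposure_transform = NULL) {
  dat <- subject_level_frame(cohort, exposure_transform, summary = "mean")
  X <- build_design(dat$data, c("mean_exposure", dat$tv_cols, dat$baseline_cols))
  fit <- fit_logistic(dat$data$outcome, X)
  method_result(
    method = "mean_summary", estimates = wald_row(fit, "mean_exposure"),
    n_used = nrow(dat$data), notes = fit$notes, extra = list(fit = fit)
  )
}

#' Logistic model on the subject-maximum exposure
#'
#' Uses each subject's largest ln exposure across available visits,
#' targeting acute/spike exposure mechanisms. Time-varying covariates are
#' taken from the visit at which the maximum occurred; ties are broken by
#' the earliest such visit.
#'
#' @inheritParams multiple_logistic_model
#' @return a [method_result()] with one `max_exposure` row.
#' @export
max_summary_model <- function(cohort, exposure_transform = NULL) {
  dat <- subject_level_frame(cohort, exposure_transform, summary = "max")
  X <- build_design(dat$data, c("max_exposure", dat$tv_cols, dat$baseline_cols))
  fit <- fit_logistic(dat$data$outcome, X)
  method_result(
    method = "max_summary", estimates = wald_row(fit, "max_exposure"),
    n_used = nrow(dat$data), notes = fit$notes, extra = list(fit = fit)
  )
}

subject_level_frame <- function(cohort, exposure_transform = NULL,
                                summary = c("mean", "max")) {
  summary <- match.arg(summary)
  df <- tibble::as_tibble(cohort)
  if (!is.null(exposure_transform)) df$exposure <- exposure_transform(df$exposure)
  tv <- active_tv(cohort)
  bc <- active_baseline(cohort)
  if (summary == "mean") {
    agg <- df |>
      dplyr::group_by(.data$subject_id) |>
      dplyr::summarise(
        mean_exposure = mean(.data$exposure),
        dplyr::across(dplyr::all_of(tv), mean),
        .groups = "drop"
      )
  } else {
    agg <- df |>
      dplyr::group_by(.data$subject_id) |>
      dplyr::arrange(.data$visit, .by_group = TRUE) |>
      dplyr::slice(which.max(.data$exposure)) |> # which.max: earliest tie wins
      dplyr::ungroup() |>
      dplyr::rename(max_exposure = "exposure") |>
      dplyr::select(dplyr::all_of(c("subject_id", "max_exposure", tv)))
  }
  dat <- dplyr::left_join(agg, cohort_subjects(cohort)[, c("subject_id", "outcome", bc)],
                          by = "subject_id")
  list(data = dat, tv_cols = tv, baseline_cols = bc)
}
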