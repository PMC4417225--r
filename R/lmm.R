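#' Linear mixed model for the exposure trajectory
#'
#' Stage-1 model of the two-stage strategy: ln exposure regressed on time
#' (centred at the cohort mean and measured in gestational weeks) with a
#' subject-level random intercept and, optionally, a random slope, the two
#' jointly bivariate normal. Time-varying covariates enter as fixed
#' effects. Estimation is REML via \pkg{lme4}; per-subject BLUPs are the
#' conditional modes given the REML variance components, which for a
#' linear mixed model coincide with the standard conditional-mean (BLUP)
#' formula.
#'
#' @param cohort an ln-scale cohort.
#' @param random_slope include a per-week random slope.
#' @param fixed_covariates fixed-effect covariates; defaults to the
#'   cohort's time-varying covariates not already residualized out.
#' @return an `lmm_fit` list: `fixed_effects`, `var_intercept`,
#'   `var_slope`, `re_correlation`, `resid_var`, `blups` (tibble of
#'   subject_id, intercept, slope), `used_slope`, `singular`,
#'   `reml_loglik`, `time_center` (weeks).
#' @export
fit_lmm <- function(cohort, random_slope = TRUE, fixed_covariates = NULL) {
  if (!identical(attr(cohort, "exposure_scale"), "ln")) {
    stop_input("fit_lmm expects an ln-scale cohort")
  }
  fixed_covariates <- fixed_covariates %||% active_tv(cohort)
  df <- tibble::as_tibble(cohort)
  if (random_slope) {
    nvis <- table(df$subject_id)
    if (sum(nvis >= 2) < 2) {
      stop_input("random slope needs >= 2 subjects with >= 2 visits")
    }
  }
  time_center <- mean(df$time_days) / 7
  df$time_c <- df$time_days / 7 - time_center
  fixed <- paste(c("time_c", fixed_covariates), collapse = " + ")
  re <- if (random_slope) "(1 + time_c | subject_id)" else "(1 | subject_id)"
  form <- as.formula(paste("exposure ~", fixed, "+", re))
  fit <- suppressWarnings(suppressMessages(lme4::lmer(
    form, data = df, REML = TRUE,
    control = lme4::lmerControl(check.conv.singular = "ignore",
                                calc.derivs = FALSE)
  )))
  vc <- as.data.frame(lme4::VarCorr(fit))
  v_int <- vc$vcov[vc$grp == "subject_id" & vc$var1 == "(Intercept)" & is.na(vc$var2)]
  v_slp <- if (random_slope) {
    vc$vcov[vc$grp == "subject_id" & vc$var1 == "time_c" & is.na(vc$var2)]
  } else 0
  re_cor <- if (random_slope) {
    r <- vc$sdcor[vc$grp == "subject_id" & !is.na(vc$var2)]
    if (length(r)) r else 0
  } else NA_real_
  resid_var <- vc$vcov[vc$grp == "Residual"]
  re_modes <- lme4::ranef(fit)$subject_id
  blups <- tibble::tibble(
    subject_id = rownames(re_modes),
    intercept = re_modes[["(Intercept)"]],
    slope = if (random_slope) re_modes[["time_c"]] else NULL
  )
  structure(list(
    fixed_effects = lme4::fixef(fit),
    var_intercept = v_int, var_slope = v_slp, re_correlation = re_cor,
    resid_var = resid_var, blups = blups,
    used_slope = random_slope, singular = lme4::isSingular(fit),
    reml_loglik = as.numeric(logLik(fit)),
    time_center = time_center, model = fit
  ), class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf(
    "<lmm_fit> %s; var(int)=%.4g%s, resid var=%.4g, REML loglik=%.2f%s\n",
    if (x$used_slope) "random intercept + slope" else "random intercept",
    x$var_intercept,
    if (x$used_slope) sprintf(", var(slope)=%.4g, corr=%.2f", x$var_slope, x$re_correlation) else "",
    x$resid_var, x$reml_loglik,
    if (x$singular) " [boundary fit]" else ""
  ))
  invisible(x)
}

#' @export
#' @rdname tidiers
tidy.lmm_fit <- function(x, ...) x$blups

#' @export
#' @rdname tidiers
glance.lmm_fit <- function(x, ...) {
  tibble::tibble(
    var_intercept = x$var_intercept, var_slope = x$var_slope,
    re_correlation = x$re_correlation, resid_var = x$resid_var,
    used_slope = x$used_slope, singular = x$singular,
    reml_loglik = x$reml_loglik
  )
}

#' Scatter of subject-level BLUPs
#'
#' The intercept-by-slope picture used to decide whether trajectories
#' separate into groups (colour = outcome when available).
#'
#' @param object an `lmm_fit`.
#' @param cohort optional cohort supplying the outcome for colouring.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.lmm_fit <- function(object, cohort = NULL, ...) {
  dat <- object$blups
  if (!object$used_slope) stop_input("autoplot needs a random-slope fit")
  if (!is.null(cohort)) {
    dat <- dplyr::left_join(dat, cohort_subjects(cohort)[, c("subject_id", "outcome")],
                            by = "subject_id")
    dat$outcome <- factor(dat$outcome)
    p <- ggplot2::ggplot(dat, ggplot2::aes(.data$intercept, .data$slope,
                                           colour = .data$outcome))
  } else {
    p <- ggplot2::ggplot(dat, ggplot2::aes(.data$intercept, .data$slope))
  }
  p + ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "BLUP intercept (ln units)",
                  y = "BLUP slope (ln units / week)")
}
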