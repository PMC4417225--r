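#' Simulation scenarios
#'
#' A scenario bundles everything the generator needs: cohort size, visit
#' schedule, variance structure of the ln exposure, the outcome-generating
#' mechanism, and dropout behaviour. The `phthalate_like` preset mirrors a
#' pregnancy biomarker study: 480 subjects, up to four urine collections at
#' median gestational weeks 9.79 (range 4.71-16.1), 17.9 (14.9-21.9),
#' 26.0 (22.9-29.3) and 35.1 (33.1-38.3), a right-skewed exposure that is
#' lognormal with within-subject ICC 0.30 by default, roughly 27% cases
#' (130/482), and outcome-dependent loss of the final visit because cases
#' deliver before it.
#'
#' Four outcome mechanisms are supported, each a different way repeated
#' exposure can matter:
#' `"mean"` (generally elevated average), `"window"` (a single sensitive
#' visit), `"acute"` (the subject's maximum, a spike), `"slope"` (the
#' subject's random time trend), plus `"null"`. The effect feature is
#' centered at its cohort mean before entering the linear predictor so the
#' case fraction stays near its target across mechanisms.
#'
#' @param name `"phthalate_like"`, `"balanced_dense"`, or `"custom"`
#'   (starts from `phthalate_like` but forces you to override).
#' @param ... scenario fields to override, e.g. `icc_target = 0.57`,
#'   `effect_type = "mean"`, `effect_size = 0.3`, `n_subjects = 2000`.
#' @return a `lexp_scenario` list.
#' @examples
#' make_scenario("phthalate_like", icc_target = 0.57)
#' @export
make_scenario <- function(name = c("phthalate_like", "balanced_dense", "custom"), ...) {
  presets <- c("phthalate_like", "balanced_dense", "custom")
  if (!name[1] %in% presets) {
    stop_input("unknown preset '", name[1], "'; available: ",
               paste(presets, collapse = ", "))
  }
  name <- match.arg(name)
  base <- list(
    name = name,
    n_subjects = 480L,
    # (median, min, max) gestational weeks per visit
    visit_schedule = list(
      c(9.79, 4.71, 16.1), c(17.9, 14.9, 21.9),
      c(26.0, 22.9, 29.3), c(35.1, 33.1, 38.3)
    ),
    icc_target = 0.30,
    total_ln_variance = 1.0,
    slope_sd = 0,              # ln-units per gestational week
    mean_ln = 2.0,             # alpha0: grand mean of ln exposure
    time_slope = -0.02,        # alpha1: fixed drift, ln-units per week
    effect_type = "null",
    effect_size = 0,
    window_visit = 3L,
    baseline_logodds = qlogis(130 / 482),
    case_dropout_prob = 0.55,  # visit-4 loss among cases
    control_dropout_prob = 0.10,
    covariate_params = list(
      sg_mean = 1.015, sg_sd = 0.005, sg_slope = 30, # gamma_sg per SG unit
      tod_prob = 0.5, tod_slope = 0.1                # gamma_tod
    ),
    confounding_strength = 0
  )
  if (name == "balanced_dense") {
    base$n_subjects <- 100L
    base$visit_schedule <- lapply(seq(8, 36, length.out = 4),
                                  function(m) c(m, m - 1, m + 1))
    base$case_dropout_prob <- 0
    base$control_dropout_prob <- 0
  }
  sc <- modifyList(base, list(...))
  validate_scenario(sc)
  structure(sc, class = "lexp_scenario")
}

validate_scenario <- function(sc) {
  med <- vapply(sc$visit_schedule, `[`, numeric(1), 1)
  if (any(diff(med) <= 0)) stop_input("visit medians must be strictly increasing")
  if (sc$icc_target <= 0 || sc$icc_target >= 1) stop_input("icc_target must be in (0,1)")
  if (sc$total_ln_variance <= 0) stop_input("total_ln_variance must be positive")
  if (sc$slope_sd < 0) stop_input("slope_sd must be >= 0")
  for (p in c("case_dropout_prob", "control_dropout_prob")) {
    if (sc[[p]] < 0 || sc[[p]] > 1) stop_input(p, " must be a probability")
  }
  if (!sc$effect_type %in% c("null", "mean", "window", "acute", "slope")) {
    stop_input("effect_type must be one of null, mean, window, acute, slope")
  }
  invisible(sc)
}

#' @export
print.lexp_scenario <- function(x, ...) {
  cat(sprintf(
    "<lexp_scenario '%s'> N=%d, %d visits, ICC target %.2f, effect %s (%.2g)\n",
    x$name, x$n_subjects, length(x$visit_schedule), x$icc_target,
    x$effect_type, x$effect_size
  ))
  invisible(x)
}

#' Simulate a cohort under a scenario
#'
#' Per subject, visit times are drawn uniformly within each visit's stated
#' range (so the median matches the schedule's midpoint) and the ln
#' exposure follows a linear mixed process
#' `ln X_ij = alpha0 + alpha1 t_ij + a0i + a1i t_ij + g_sg SG_ij +
#' g_tod TOD_ij + e_ij`, with `Var(a0i) / (Var(a0i) + Var(e))` equal to the
#' target ICC when `slope_sd = 0` and time centred at the schedule
#' mid-pregnancy mean. The outcome is Bernoulli on the logit scale:
#' baseline log-odds plus `effect_size` times the (cohort-centred) effect
#' feature of the chosen mechanism. Cases then lose the final visit with
#' probability `case_dropout_prob` (controls with `control_dropout_prob`),
#' emulating deliveries that occur before the last collection.
#'
#' The returned cohort carries a `truth` attribute with the per-subject
#' random effects, the effect feature and the linear predictor, for
#' parameter-recovery checks; retrieve it with [cohort_truth()].
#'
#' @param scenario from [make_scenario()].
#' @param seed integer; the draw is deterministic given the seed.
#' @return an ln-scale cohort (exposure already on the log scale) with
#'   time-varying covariates `sg`, `tod` and baseline covariate `age_c`.
#' @export
simulate_cohort <- function(scenario, seed = 1) {
  validate_scenario(scenario)
  sc <- scenario
  with_seed(seed, {
    N <- sc$n_subjects
    nm <- length(sc$visit_schedule)
    var_b <- sc$icc_target * sc$total_ln_variance
    var_e <- (1 - sc$icc_target) * sc$total_ln_variance

    times_w <- vapply(sc$visit_schedule,
                      function(v) runif(N, v[2], v[3]), numeric(N))
    # adjacent visit windows can overlap slightly; keep per-subject order
    times_w <- t(apply(times_w, 1, sort))
    t_center <- mean(vapply(sc$visit_schedule, function(v) (v[2] + v[3]) / 2, numeric(1)))
    tc <- times_w - t_center

    a0 <- rnorm(N, 0, sqrt(var_b))
    a1 <- rnorm(N, 0, sc$slope_sd)
    eps <- matrix(rnorm(N * nm, 0, sqrt(var_e)), N, nm)
    cp <- sc$covariate_params
    sg <- matrix(rnorm(N * nm, cp$sg_mean, cp$sg_sd), N, nm)
    sg <- pmin(pmax(sg, 1.000), 1.040)
    tod <- matrix(rbinom(N * nm, 1, cp$tod_prob), N, nm)
    age_c <- rnorm(N, 0, 5) # centred maternal age, years

    lnx <- sc$mean_ln + sc$time_slope * tc + a0 + a1 * tc +
      cp$sg_slope * (sg - cp$sg_mean) + cp$tod_slope * tod + eps

    feature <- switch(sc$effect_type,
      null = rep(0, N),
      mean = rowMeans(lnx),
      window = lnx[, sc$window_visit],
      acute = apply(lnx, 1, max),
      slope = a1
    )
    feat_c <- feature - mean(feature)
    lp <- sc$baseline_logodds + sc$effect_size * feat_c +
      sc$confounding_strength * scale(rowMeans(sg))[, 1]
    y <- rbinom(N, 1, expit(lp))

    drop4 <- rbinom(N, 1, ifelse(y == 1, sc$case_dropout_prob,
                                 sc$control_dropout_prob)) == 1

    long <- tibble::tibble(
      subject_id = rep(sprintf("s%04d", seq_len(N)), each = nm),
      outcome = rep(y, each = nm),
      visit = rep(seq_len(nm), N),
      time_days = as.numeric(t(times_w)) * 7,
      exposure = as.numeric(t(lnx)),
      sg = as.numeric(t(sg)),
      tod = as.numeric(t(tod)),
      age_c = rep(age_c, each = nm)
    )
    long <- long[!(long$visit == nm & rep(drop4, each = nm)), ]

    cohort <- as_cohort(long,
      exposure_scale = "ln", tv_covariates = c("sg", "tod"),
      baseline_covariates = "age_c"
    )
    attr(cohort, "truth") <- list(
      scenario = sc, seed = seed,
      subjects = tibble::tibble(
        subject_id = sprintf("s%04d", seq_len(N)),
        outcome = y, a0 = a0, a1 = a1,
        feature = feature, linear_predictor = lp,
        dropped_final = drop4
      )
    )
    cohort
  })
}

#' Truth record of a simulated cohort
#' @param cohort a cohort produced by [simulate_cohort()].
#' @return list with the scenario, seed, and per-subject truth tibble.
#' @export
cohort_truth <- function(cohort) {
  tr <- attr(cohort, "truth")
  if (is.null(tr)) stop_input("cohort carries no truth record (not simulated?)")
  tr
}

#' Compare a simulated cohort to its scenario targets
#'
#' Reports the realized ICC, case fraction and per-visit sample sizes next
#' to the scenario's targets, as a quick generator diagnostic.
#'
#' @param cohort a simulated cohort.
#' @param icc_B bootstrap resamples for the ICC interval (0 = point only).
#' @return tibble of (quantity, target, realized) rows.
#' @export
truth_check <- function(cohort, icc_B = 0) {
  tr <- cohort_truth(cohort)
  sc <- tr$scenario
  icc <- cohort_icc(cohort, B = icc_B)
  subj <- cohort_subjects(cohort)
  per_visit <- table(factor(cohort$visit, levels = seq_along(sc$visit_schedule)))
  tibble::tibble(
    quantity = c("icc", "case_fraction",
                 paste0("n_visit", seq_along(sc$visit_schedule))),
    target = c(sc$icc_target, expit(sc$baseline_logodds),
               rep(sc$n_subjects, length(sc$visit_schedule))),
    realized = c(icc$icc, mean(subj$outcome), as.numeric(per_visit))
  )
}
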