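test_that("logistic IRLS matches the 2x2 cross-product ratio and glm", {
  # cells: x=1 -> 6 events / 4 non; x=0 -> 3 events / 7 non
  X <- cbind("(Intercept)" = 1, x = c(rep(1, 10), rep(0, 10)))
  y <- c(rep(1, 6), rep(0, 4), rep(1, 3), rep(0, 7))
  fit <- fit_logistic(y, X)
  expect_equal(unname(fit$coefficients["x"]), log((6 * 7) / (4 * 3)),
               tolerance = 1e-6)
  expect_true(fit$converged)
  # deviance trace is non-increasing
  expect_true(all(diff(fit$deviance_trace) <= 1e-8))

  # intercept-only symmetry
  f0 <- fit_logistic(c(1, 0, 1, 0), cbind(int = rep(1, 4)))
  expect_equal(unname(f0$coefficients), 0, tolerance = 1e-8)

  # agreement with glm on a richer design
  set.seed(42)
  n <- 200
  Z <- cbind(1, rnorm(n), rbinom(n, 1, 0.4))
  colnames(Z) <- c("int", "x1", "x2")
  yy <- rbinom(n, 1, plogis(Z %*% c(-0.5, 0.8, -0.3)))
  mine <- fit_logistic(yy, Z)
  ref <- glm(yy ~ 0 + Z, family = binomial())
  expect_equal(unname(mine$coefficients), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(unname(mine$se), unname(sqrt(diag(vcov(ref)))), tolerance = 1e-4)
  expect_equal(mine$loglik, as.numeric(logLik(ref)), tolerance = 1e-6)

  # separation is flagged, not silently returned
  Xs <- cbind(int = 1, x = c(rep(0, 5), rep(1, 5)))
  ys <- c(rep(0, 5), rep(1, 5))
  expect_warning(fs <- fit_logistic(ys, Xs), "separation")
  expect_false(fs$converged)

  expect_error(fit_logistic(yy, cbind(Z, Z[, 2])), "rank deficient")
})

test_that("MAP logistic spans the no-penalty and infinite-penalty limits", {
  set.seed(7)
  n <- 120
  E <- matrix(rnorm(n * 3), n, 3)
  colnames(E) <- paste0("e", 1:3)
  X <- cbind("(Intercept)" = 1, E, z = rnorm(n))
  y <- rbinom(n, 1, plogis(-0.3 + E %*% c(0.5, 0, -0.4) + 0.3 * X[, "z"]))

  mle <- fit_logistic(y, X)
  loose <- fit_map_logistic(y, X, exposure_block = colnames(E),
                            tau2 = 1e12, rho = 0)
  expect_equal(loose$coefficients, mle$coefficients, tolerance = 1e-4)

  tight <- fit_map_logistic(y, X, exposure_block = colnames(E),
                            tau2 = 1e-12, rho = 0)
  expect_lt(max(abs(tight$coefficients[colnames(E)])), 1e-4)
  # covariate and intercept stay free under the tight prior
  free <- fit_logistic(y, cbind(X[, c("(Intercept)", "z")]))
  expect_equal(tight$coefficients["z"], free$coefficients["z"], tolerance = 0.05)

  expect_error(fit_map_logistic(y, X, colnames(E), tau2 = -1, rho = 0), "tau2")
  expect_error(fit_map_logistic(y, X, colnames(E), tau2 = 1, rho = 1), "rho")
})

test_that("MAP solution equals a generic optimizer on a small dataset", {
  set.seed(8)
  n <- 40
  E <- matrix(rnorm(n * 3), n, 3)
  colnames(E) <- paste0("e", 1:3)
  X <- cbind("(Intercept)" = 1, E)
  y <- rbinom(n, 1, plogis(E %*% c(0.8, -0.2, 0.1)))
  tau2 <- 0.5
  rho <- 0.6
  fit <- fit_map_logistic(y, X, exposure_block = colnames(E),
                          tau2 = tau2, rho = rho)

  R <- rho^abs(outer(1:3, 1:3, "-"))
  P <- matrix(0, 4, 4)
  P[2:4, 2:4] <- solve(tau2 * R)
  obj <- function(b) {
    eta <- drop(X %*% b)
    -(sum(y * eta - log1p(exp(eta))) - 0.5 * drop(b %*% P %*% b))
  }
  opt <- optim(rep(0, 4), obj, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-14))
  expect_lt(max(abs(fit$coefficients - opt$par)), 1e-5)

  # penalized-norm shrinkage relative to the MLE exposure block
  mle <- fit_logistic(y, X)
  norm_in_prior <- function(b) drop(b %*% solve(R) %*% b)
  expect_lte(norm_in_prior(fit$coefficients[2:4]),
             norm_in_prior(mle$coefficients[2:4]) + 1e-10)
})

test_that("mixed model BLUPs obey the closed-form shrinkage formula", {
  co <- balanced_cohort(N = 60, n = 4, sd_b = 1, sd_e = 1, seed = 12)
  fit <- fit_lmm(co, random_slope = FALSE, fixed_covariates = character())
  df <- tibble::as_tibble(co)
  xbar <- tapply(df$exposure, df$subject_id, mean)
  mu <- unname(fit$fixed_effects["(Intercept)"])
  # time slope is estimated too; project it out by using the fitted values
  # of a model without time for the oracle instead: refit intercept-only lmm
  # oracle on the same estimated variance components
  k <- fit$var_intercept / (fit$var_intercept + fit$resid_var / 4)
  # centre xbar on the model-implied mean at each subject's times
  tcw <- df$time_days / 7 - fit$time_center
  mu_i <- mu + unname(fit$fixed_effects["time_c"]) * tapply(tcw, df$subject_id, mean)
  manual <- as.numeric(k * (xbar - mu_i))
  expect_equal(fit$blups$intercept[match(names(xbar), fit$blups$subject_id)],
               manual, tolerance = 1e-6)
  # information-weighted BLUPs centre at zero
  expect_lt(abs(mean(fit$blups$intercept)), 1e-6)
})

test_that("noiseless subject-constant data gives zero residual variance", {
  df <- tidyr::expand_grid(i = 1:20, j = 1:3)
  b <- seq(-2, 2, length.out = 20)
  df <- dplyr::mutate(df,
    subject_id = sprintf("s%02d", i), outcome = 0, visit = j,
    time_days = 50 + 45 * j, exposure = b[i]
  )
  co <- as_cohort(df[, -(1:2)], "ln")
  fit <- fit_lmm(co, random_slope = FALSE, fixed_covariates = character())
  expect_lt(fit$resid_var, 1e-8)
  expect_equal(sort(fit$blups$intercept), sort(b - mean(b)), tolerance = 1e-5)
})

test_that("REML optimum beats a grid of variance components", {
  co <- balanced_cohort(N = 6, n = 3, sd_b = 1, sd_e = 0.8, seed = 13)
  fit <- fit_lmm(co, random_slope = FALSE, fixed_covariates = character())
  df <- tibble::as_tibble(co)
  # evaluate the closed-form REML criterion on a grid; the fitted components
  # (which also profile out the time fixed effect; drop it here by fitting
  # intercept-only data) must not be beaten by more than numerical slack
  grid_vals <- expand.grid(vb = seq(0.05, 4, length.out = 20),
                           ve = seq(0.05, 4, length.out = 20))
  crit <- mapply(function(vb, ve) {
    reml_loglik_ri(df$exposure, df$subject_id, vb, ve)
  }, grid_vals$vb, grid_vals$ve)
  at_fit <- reml_loglik_ri(df$exposure, df$subject_id,
                           fit$var_intercept, fit$resid_var)
  expect_gte(at_fit, max(crit) - 0.05)
})

test_that("pooled GEE equals the separate cross-sectional fits", {
  co <- simulate_cohort(make_scenario("phthalate_like", n_subjects = 250),
                        seed = 17)
  gee <- fit_pooled_gee(co)
  cs <- cross_sectional_models(co, gee = FALSE)
  expect_equal(unname(gee$visit_betas), cs$estimates$estimate, tolerance = 1e-6)
  expect_equal(gee$equality_df, 3L)
  expect_true(gee$equality_p >= 0 && gee$equality_p <= 1)
  expect_true(isSymmetric(gee$sandwich_cov, tol = 1e-10))
  expect_true(all(eigen(gee$sandwich_cov, only.values = TRUE)$values > -1e-12))

  # single-visit cohort: equality skipped, estimate matches plain logistic
  one <- dplyr::filter(tibble::as_tibble(co), visit == 2)
  one$visit <- 1L
  co1 <- as_cohort(one, "ln", tv_covariates = c("sg", "tod"),
                   baseline_covariates = "age_c")
  g1 <- fit_pooled_gee(co1)
  expect_equal(g1$equality_df, 0L)
  X <- longexpo:::build_design(one, c("exposure", "sg", "tod", "age_c"))
  ref <- fit_logistic(one$outcome, X)
  expect_equal(unname(g1$visit_betas), unname(ref$coefficients["exposure"]),
               tolerance = 1e-8)
})

test_that("sandwich SEs agree with model-based SEs on independent data", {
  set.seed(19)
  df <- tibble::tibble(
    subject_id = sprintf("s%03d", 1:400), outcome = rbinom(400, 1, 0.3),
    visit = 1L, time_days = 100, exposure = rnorm(400)
  )
  co <- as_cohort(df, "ln")
  g <- fit_pooled_gee(co)
  X <- cbind("(Intercept)" = 1, exposure = df$exposure)
  ref <- fit_logistic(df$outcome, X)
  ratio <- g$estimates$se[1] / unname(ref$se["exposure"])
  expect_gt(ratio, 0.8)
  expect_lt(ratio, 1.25)
})
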