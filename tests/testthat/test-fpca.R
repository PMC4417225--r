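make_kl_cohort <- function(N = 400, lambda = c(4, 1), noise_sd = 0.3,
                           seed = 81, n_visits = 4) {
  # Karhunen-Loeve process on [0, 1] mapped to weeks 8..36:
  # X_i(t) = mu(t) + xi_1 sqrt(2) sin(2 pi s) + xi_2 sqrt(2) cos(2 pi s)
  set.seed(seed)
  xi1 <- rnorm(N, 0, sqrt(lambda[1]))
  xi2 <- rnorm(N, 0, sqrt(lambda[2]))
  df <- tidyr::expand_grid(i = seq_len(N), j = seq_len(n_visits))
  tw <- matrix(runif(N * n_visits, 8, 36), N, n_visits)
  tw <- t(apply(tw, 1, sort))
  df$time_w <- tw[cbind(df$i, df$j)]
  s <- (df$time_w - 8) / 28
  df <- dplyr::mutate(df,
    subject_id = sprintf("s%04d", i), outcome = rbinom(N, 1, 0.3)[i],
    visit = j, time_days = time_w * 7,
    exposure = 2 + 0.05 * time_w +
      xi1[i] * sqrt(2) * sin(2 * pi * s) +
      xi2[i] * sqrt(2) * cos(2 * pi * s) +
      rnorm(nrow(df), 0, noise_sd)
  )
  co <- as_cohort(df[, c("subject_id", "outcome", "visit", "time_days", "exposure")],
                  "ln")
  attr(co, "kl_truth") <- list(xi1 = xi1, xi2 = xi2)
  co
}

test_that("zero-variance curves give zero eigenvalues and scores", {
  df <- tidyr::expand_grid(i = 1:40, j = 1:4)
  df <- dplyr::mutate(df,
    subject_id = sprintf("s%02d", i), outcome = 0, visit = j,
    time_days = (6 + 8 * j) * 7 + i * 0.01,
    exposure = 1 + 0.1 * time_days / 7
  )
  co <- as_cohort(df[, -(1:2)], "ln")
  fit <- fpca_pace(co, n_basis = 6)
  expect_lt(max(fit$eigenvalues, 0), 1e-8)
  if (length(fit$eigenvalues)) {
    expect_lt(max(abs(as.matrix(fit$scores[, -1]))), 1e-4)
  }
  expect_lt(fit$noise_var, 1e-8)
})

test_that("eigenfunctions are orthonormal under the quadrature weights", {
  co <- make_kl_cohort(N = 250, seed = 82)
  fit <- fpca_pace(co)
  Phi <- fit$eigenfunctions
  G <- t(Phi) %*% (fit$quad_weights * Phi)
  expect_lt(max(abs(G - diag(ncol(Phi)))), 1e-6)
  expect_true(all(diff(fit$eigenvalues) <= 1e-12))
  fv <- fit$fraction_variance
  expect_true(all(diff(fv) >= -1e-12))
  expect_lte(max(fv), 1 + 1e-12)
})

test_that("dense noiseless data reproduces the sample-covariance eigenvectors", {
  # balanced design observed on a fixed fine grid, no noise
  set.seed(83)
  N <- 150
  tg <- seq(8, 36, length.out = 12)
  s <- (tg - 8) / 28
  xi1 <- rnorm(N, 0, 2)
  xi2 <- rnorm(N, 0, 1)
  X <- outer(rep(1, N), 2 + 0.05 * tg) +
    outer(xi1, sqrt(2) * sin(2 * pi * s)) +
    outer(xi2, sqrt(2) * cos(2 * pi * s))
  df <- tidyr::expand_grid(i = 1:N, j = 1:12)
  df <- dplyr::mutate(df,
    subject_id = sprintf("s%03d", i), outcome = 0, visit = j,
    time_days = tg[j] * 7, exposure = X[cbind(i, j)]
  )
  co <- as_cohort(df[, -(1:2)], "ln")
  fit <- fpca_pace(co, n_basis = 10, grid_size = 45)

  S <- cov(X)
  ev <- eigen(S, symmetric = TRUE)
  for (l in 1:2) {
    # sample eigenvector scaled to the quadrature normalization
    ref <- approx(tg, ev$vectors[, l], fit$grid, rule = 2)$y
    ref <- ref / sqrt(sum(ref^2 * fit$quad_weights))
    est <- fit$eigenfunctions[, l]
    if (sum(ref * est * fit$quad_weights) < 0) ref <- -ref
    expect_lt(max(abs(est - ref)), 0.05)
  }
})

test_that("a two-component generative model is recovered", {
  co <- make_kl_cohort(N = 400, lambda = c(4, 1), seed = 84)
  fit <- fpca_pace(co)
  expect_equal(fit$eigenvalues[1] / fit$eigenvalues[2], 4, tolerance = 1)
  truth <- attr(co, "kl_truth")
  ord <- match(fit$scores$subject_id, sprintf("s%04d", seq_along(truth$xi1)))
  expect_gte(abs(cor(fit$scores$xi_1, truth$xi1[ord])), 0.9)
})

test_that("scores reduce to direct projection for fully observed curves", {
  co <- make_kl_cohort(N = 200, seed = 85)
  fit <- fpca_pace(co)
  # build one synthetic subject observed at every grid point, exactly in the
  # span of the fitted components
  xi <- c(1.3, -0.7)
  x_full <- fit$mean_function +
    as.numeric(fit$eigenfunctions[, 1:2] %*% xi)
  direct <- vapply(1:2, function(l) {
    sum(fit$quad_weights * fit$eigenfunctions[, l] *
          (x_full - fit$mean_function))
  }, numeric(1))
  expect_equal(direct, xi, tolerance = 1e-6)
  dfg <- tibble::tibble(subject_id = "gridsub", t_w = fit$grid,
                        exposure = x_full)
  sc <- longexpo:::pace_scores(dfg, fit$grid, fit$mean_function,
                               fit$eigenfunctions[, 1:2, drop = FALSE],
                               fit$eigenvalues[1:2], noise_var = 0)
  expect_equal(unname(unlist(sc[1, c("xi_1", "xi_2")])), xi, tolerance = 1e-4)
})

test_that("model selection lands on the planted dimension most of the time", {
  hits <- vapply(1:6, function(r) {
    co <- make_kl_cohort(N = 250, lambda = c(4, 1), noise_sd = 0.25,
                         seed = 860 + r)
    sel <- select_fpca_model(co, n_basis_grid = 7, l_grid = 1:3,
                             criterion = "modified_bic")
    sel$L == 2
  }, logical(1))
  expect_gte(mean(hits), 0.65)

  # single-candidate grids return that pair with its criterion value
  co <- make_kl_cohort(N = 150, seed = 87)
  sel1 <- select_fpca_model(co, n_basis_grid = 7, l_grid = 2,
                            criterion = "modified_bic")
  expect_equal(sel1$n_basis, 7)
  expect_equal(sel1$L, 2)
  expect_equal(nrow(sel1$table), 1)
  expect_true(is.finite(sel1$table$value))

  sel2 <- select_fpca_model(co, n_basis_grid = 7, l_grid = 1:2,
                            criterion = "locv", folds = 4, seed = 2)
  expect_true(all(is.finite(sel2$table$value)))
})

test_that("functional logistic regression tests the score block", {
  co <- make_kl_cohort(N = 300, seed = 88)
  r <- functional_logistic_model(co, L = 2)
  expect_equal(r$global_tests$df, 2)
  expect_equal(nrow(r$estimates), 2)
  expect_equal(nrow(r$extra$beta_t), length(r$extra$fpca$grid))

  r0 <- functional_logistic_model(co, L = 0)
  expect_equal(r0$global_tests$p, 1)
  expect_equal(r0$global_tests$df, 0)

  expect_error(functional_logistic_model(co, L = 50), "exceeds")
})

test_that("score-driven outcomes are detected with high power", {
  hits <- vapply(1:10, function(r) {
    co <- make_kl_cohort(N = 700, lambda = c(4, 1), noise_sd = 0.3,
                         seed = 890 + r)
    truth <- attr(co, "kl_truth")
    df <- tibble::as_tibble(co)
    ids <- sprintf("s%04d", seq_along(truth$xi1))
    y <- rbinom(length(ids), 1, plogis(-1 + 0.8 * truth$xi1))
    df$outcome <- y[match(df$subject_id, ids)]
    co2 <- rebuild_cohort_for_test(df, co)
    functional_logistic_model(co2, L = 2)$global_tests$p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})
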