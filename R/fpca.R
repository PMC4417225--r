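#' Sparse functional principal component analysis by conditional expectation
#'
#' Treats each subject's ln-exposure measurements as sparse, noisy
#' observations of a smooth random curve X_i(t) and estimates the
#' process's mean function, covariance surface and eigenstructure from
#' the pooled data. Because subjects contribute only a handful of
#' irregular time points, FPC scores cannot be computed by direct
#' integration; instead they are the conditional expectations
#' `xi_il = lambda_l phi_l(t_i)' Sigma_i^{-1} (X_i - mu_i)` under a
#' Gaussian working model, with `Sigma_i = Phi Lambda Phi' + sigma^2 I`
#' evaluated at subject i's own time points.
#'
#' Estimation steps: (1) mean by penalized spline smoothing of the pooled
#' (t, x) scatter; (2) covariance surface by smoothing the off-diagonal
#' raw cross-products of centred residuals over the (t1, t2) plane (the
#' diagonal is excluded because it carries the measurement-error
#' variance); (3) noise variance as the average gap between the smoothed
#' diagonal variance and the surface's diagonal, over the central half of
#' the time range, floored at zero; (4) eigendecomposition of the
#' discretized surface under trapezoid quadrature weights. Negative
#' eigenvalues are truncated; a warning reports the count when they carry
#' non-trivial mass.
#'
#' @param cohort an ln-scale cohort with at least 50 pooled observations.
#' @param n_basis basis dimension for the mean smooth (and, capped at 8,
#'   for each margin of the covariance surface smooth).
#' @param grid_size evaluation grid resolution over the observed range.
#' @param max_components cap on the number of retained components.
#' @return an `fpca_fit`: `grid` (weeks), `mean_function`,
#'   `eigenfunctions` (grid_size x L matrix), `eigenvalues`, `noise_var`,
#'   `scores` (tibble subject_id, xi_1, ...), `fraction_variance`,
#'   `n_basis`.
#' @export
fpca_pace <- function(cohort, n_basis = 9, grid_size = 51, max_components = 6) {
  if (!identical(attr(cohort, "exposure_scale"), "ln")) {
    stop_input("fpca_pace expects an ln-scale cohort")
  }
  df <- tibble::as_tibble(cohort)
  if (nrow(df) < 50) stop_input("need at least 50 pooled observations")
  df$t_w <- df$time_days / 7
  grid <- seq(min(df$t_w), max(df$t_w), length.out = grid_size)

  mean_fit <- mgcv::gam(exposure ~ s(t_w, k = n_basis, bs = "cr"),
                        data = df, method = "REML")
  mu_grid <- as.numeric(predict(mean_fit, data.frame(t_w = grid)))
  df$resid <- df$exposure - as.numeric(predict(mean_fit))

  # raw off-diagonal cross-products, both orientations for symmetry
  idx <- split(seq_len(nrow(df)), df$subject_id)
  tt <- df$t_w
  rr <- df$resid
  blocks <- lapply(idx, function(ii) {
    n <- length(ii)
    if (n < 2) return(NULL)
    cmb <- utils::combn(n, 2)
    i1 <- ii[cmb[1, ]]
    i2 <- ii[cmb[2, ]]
    cbind(c(tt[i1], tt[i2]), c(tt[i2], tt[i1]), rep(rr[i1] * rr[i2], 2))
  })
  pm <- do.call(rbind, blocks)
  if (is.null(pm) || !nrow(pm)) stop_input("no subject contributes two or more visits")
  pairs <- data.frame(t1 = pm[, 1], t2 = pm[, 2], cc = pm[, 3])
  k_cov <- min(n_basis, 8)
  cov_fit <- mgcv::bam(cc ~ te(t1, t2, k = c(k_cov, k_cov)),
                       data = pairs, method = "fREML", discrete = TRUE)
  gg <- expand.grid(t1 = grid, t2 = grid)
  C <- matrix(predict(cov_fit, gg, discrete = FALSE), grid_size, grid_size)
  C <- (C + t(C)) / 2

  # noise variance from the diagonal gap over the central half of the range
  var_fit <- mgcv::gam(I(resid^2) ~ s(t_w, k = min(n_basis, 8), bs = "cr"),
                       data = df, method = "REML")
  V_diag <- as.numeric(predict(var_fit, data.frame(t_w = grid)))
  central <- grid >= quantile(grid, 0.25) & grid <= quantile(grid, 0.75)
  noise_var <- max(0, mean(V_diag[central] - diag(C)[central]))

  h <- diff(grid[1:2])
  w <- rep(h, grid_size)
  w[c(1, grid_size)] <- h / 2
  sw <- sqrt(w)
  eig <- eigen(t(C * sw) * sw, symmetric = TRUE)
  lambda <- eig$values
  n_neg <- sum(lambda < 0)
  if (n_neg && sum(pmax(-lambda, 0)) > 0.05 * sum(pmax(lambda, 0))) {
    warn(sprintf("covariance surface not positive semidefinite: %d negative eigenvalues truncated", n_neg))
  }
  keep <- which(lambda > max(1e-10, 1e-8 * max(lambda, 0)))
  keep <- head(keep, max_components)
  lambda <- lambda[keep]
  phi <- eig$vectors[, keep, drop = FALSE] / sw
  for (l in seq_along(lambda)) {
    s <- sum(phi[, l] * w)
    if (s == 0) s <- phi[1, l]
    if (s < 0) phi[, l] <- -phi[, l]
  }

  # with few visits per subject the covariance surface's diagonal is an
  # extrapolation and the gap estimator can collapse to zero even when
  # measurement error is present; fall back to the profile MLE of sigma^2
  # under the fitted eigenstructure in that case
  noise_source <- "diagonal_gap"
  if (noise_var < 1e-8 && length(lambda) && var(df$resid) > 0) {
    noise_var <- profile_noise_var(df, grid, mu_grid, phi, lambda)
    noise_source <- "profile_mle"
  }

  scores <- pace_scores(df, grid, mu_grid, phi, lambda, noise_var)

  structure(list(
    grid = grid, mean_function = mu_grid,
    eigenfunctions = phi, eigenvalues = lambda, noise_var = noise_var,
    noise_source = noise_source, scores = scores,
    fraction_variance = cumsum(lambda) / sum(lambda),
    n_basis = n_basis, quad_weights = w,
    mean_fit = mean_fit, cov_surface = C
  ), class = "fpca_fit")
}

# pooled Gaussian log-likelihood of the observations for a given noise
# variance under the fitted (mu, phi, lambda) process
pooled_process_loglik <- function(df, grid, mu_grid, phi, lambda, sigma2) {
  mu_obs <- approx(grid, mu_grid, df$t_w, rule = 2)$y
  Phi_obs <- matrix(vapply(seq_along(lambda), function(l) {
    approx(grid, phi[, l], df$t_w, rule = 2)$y
  }, numeric(nrow(df))), nrow = nrow(df))
  centered <- df$exposure - mu_obs
  idx <- split(seq_len(nrow(df)), df$subject_id)
  sum(vapply(idx, function(ii) {
    Phi_i <- Phi_obs[ii, , drop = FALSE]
    Sig <- Phi_i %*% (lambda * t(Phi_i)) + diag(sigma2, length(ii))
    ch <- tryCatch(chol(Sig), error = function(e) NULL)
    if (is.null(ch)) return(-1e10)
    q <- forwardsolve(t(ch), centered[ii])
    -0.5 * (length(ii) * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(q^2))
  }, numeric(1)))
}

profile_noise_var <- function(df, grid, mu_grid, phi, lambda) {
  tot <- var(df$resid)
  opt <- optimize(function(ls2) {
    -pooled_process_loglik(df, grid, mu_grid, phi, lambda, exp(ls2))
  }, interval = log(c(1e-6 * tot, tot)))
  exp(opt$minimum)
}

pace_scores <- function(df, grid, mu_grid, phi, lambda, noise_var) {
  L <- length(lambda)
  if (L == 0L) {
    return(tibble::tibble(subject_id = sort(unique(df$subject_id))))
  }
  ridge <- max(noise_var, 1e-8 * max(c(lambda, 0)), 1e-12)
  # interpolate mean and eigenfunctions at every observation time in one pass
  mu_obs <- approx(grid, mu_grid, df$t_w, rule = 2)$y
  Phi_obs <- vapply(seq_len(L), function(l) {
    approx(grid, phi[, l], df$t_w, rule = 2)$y
  }, numeric(nrow(df)))
  Phi_obs <- matrix(Phi_obs, nrow = nrow(df))
  centered <- df$exposure - mu_obs
  idx <- split(seq_len(nrow(df)), df$subject_id)
  out <- lapply(idx, function(ii) {
    Phi_i <- Phi_obs[ii, , drop = FALSE]
    Sig_i <- Phi_i %*% (lambda * t(Phi_i)) + diag(ridge, length(ii))
    drop(lambda * t(Phi_i) %*% solve(Sig_i, centered[ii]))
  })
  scores <- do.call(rbind, out)
  colnames(scores) <- paste0("xi_", seq_len(L))
  dplyr::bind_cols(tibble::tibble(subject_id = names(idx)),
                   tibble::as_tibble(scores))
}

#' @export
print.fpca_fit <- function(x, ...) {
  cat(sprintf(
    "<fpca_fit> %d components, noise var %.4g; variance fractions: %s\n",
    length(x$eigenvalues), x$noise_var,
    paste(sprintf("%.2f", x$fraction_variance[seq_len(min(3, length(x$eigenvalues)))]),
          collapse = ", ")
  ))
  invisible(x)
}

#' @export
#' @rdname tidiers
tidy.fpca_fit <- function(x, ...) x$scores

#' Plot FPCA mean and leading eigenfunctions
#' @param object an `fpca_fit`.
#' @param n_show number of eigenfunctions to draw.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.fpca_fit <- function(object, n_show = 2, ...) {
  n_show <- min(n_show, ncol(object$eigenfunctions))
  dat <- dplyr::bind_rows(
    tibble::tibble(week = object$grid, value = object$mean_function,
                   curve = "mean"),
    purrr::map_dfr(seq_len(n_show), function(l) {
      tibble::tibble(week = object$grid, value = object$eigenfunctions[, l],
                     curve = sprintf("phi_%d (%.0f%%)", l,
                                     100 * object$eigenvalues[l] / sum(object$eigenvalues)))
    })
  )
  ggplot2::ggplot(dat, ggplot2::aes(.data$week, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~curve, scales = "free_y") +
    ggplot2::labs(x = "gestational week", y = NULL)
}

#' Choose the FPCA basis dimension and number of components
#'
#' Two criteria are offered. `"locv"` approximates leave-one-curve-out
#' cross-validation by ten folds (exact LOCV would refit the mean and
#' covariance N times): for each held-out subject the observations are
#' reconstructed from the model fitted without their fold, and the summed
#' squared reconstruction error is minimized. `"modified_bic"` scores
#' each (n_basis, L) by the pooled Gaussian marginal log-likelihood of
#' the observations under the fitted process minus
#' `0.5 * m * log(n_obs)`, with `m` counting mean coefficients,
#' eigenfunction coefficients, eigenvalues and the noise variance; it is
#' maximized.
#'
#' @param cohort an ln-scale cohort.
#' @param n_basis_grid candidate basis dimensions.
#' @param l_grid candidate numbers of leading components.
#' @param criterion `"modified_bic"` or `"locv"`.
#' @param folds fold count for the locv approximation.
#' @param seed fold assignment seed.
#' @return list with `n_basis`, `L`, and the full criterion `table`.
#' @export
select_fpca_model <- function(cohort, n_basis_grid = c(5, 7, 9, 11),
                              l_grid = 1:3,
                              criterion = c("modified_bic", "locv"),
                              folds = 10, seed = 1) {
  criterion <- match.arg(criterion)
  if (!length(n_basis_grid) || !length(l_grid)) stop_input("empty candidate grid")
  rows <- list()
  for (nb in n_basis_grid) {
    if (criterion == "modified_bic") {
      fit <- fpca_pace(cohort, n_basis = nb, max_components = max(l_grid))
      for (L in l_grid) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          n_basis = nb, L = L,
          value = fpca_marginal_bic(cohort, fit, L)
        )
      }
    } else {
      err <- fpca_locv(cohort, nb, l_grid, folds, seed)
      for (L in l_grid) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          n_basis = nb, L = L, value = err[as.character(L)]
        )
      }
    }
  }
  tab <- dplyr::bind_rows(rows)
  best <- if (criterion == "modified_bic") which.max(tab$value) else which.min(tab$value)
  list(n_basis = tab$n_basis[best], L = tab$L[best], table = tab,
       criterion = criterion)
}

fpca_marginal_bic <- function(cohort, fit, L) {
  L <- min(L, length(fit$eigenvalues))
  df <- tibble::as_tibble(cohort)
  df$t_w <- df$time_days / 7
  mu_obs <- approx(fit$grid, fit$mean_function, df$t_w, rule = 2)$y
  df$resid <- df$exposure - mu_obs
  lam <- fit$eigenvalues[seq_len(L)]
  phi <- fit$eigenfunctions[, seq_len(L), drop = FALSE]
  # profile the working-model noise variance for each candidate L so a
  # degenerate plug-in sigma^2 cannot distort the comparison
  tot <- var(df$resid)
  opt <- optimize(function(ls2) {
    -pooled_process_loglik(df, fit$grid, fit$mean_function, phi, lam, exp(ls2))
  }, interval = log(c(1e-6 * tot, 2 * tot)))
  ll <- -opt$objective
  m <- fit$n_basis + L * fit$n_basis + L + 1
  ll - 0.5 * m * log(nrow(df))
}

fpca_locv <- function(cohort, n_basis, l_grid, folds, seed) {
  df <- tibble::as_tibble(cohort)
  ids <- unique(df$subject_id)
  fold_of <- with_seed(seed, sample(rep(seq_len(folds), length.out = length(ids))))
  names(fold_of) <- ids
  err <- setNames(numeric(length(l_grid)), as.character(l_grid))
  for (f in seq_len(folds)) {
    held <- ids[fold_of == f]
    train <- rebuild_cohort(df[!df$subject_id %in% held, ], cohort)
    fit <- tryCatch(
      fpca_pace(train, n_basis = n_basis, max_components = max(l_grid)),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    test <- df[df$subject_id %in% held, ]
    test$t_w <- test$time_days / 7
    for (L in l_grid) {
      Lc <- min(L, length(fit$eigenvalues))
      lam <- fit$eigenvalues[seq_len(Lc)]
      e <- sum(vapply(split(test[, c("t_w", "exposure")], test$subject_id),
                      function(g) {
        mu_i <- approx(fit$grid, fit$mean_function, g$t_w, rule = 2)$y
        Phi_i <- matrix(vapply(seq_len(Lc), function(l) {
          approx(fit$grid, fit$eigenfunctions[, l], g$t_w, rule = 2)$y
        }, numeric(nrow(g))), nrow = nrow(g))
        Sig <- Phi_i %*% (lam * t(Phi_i)) +
          diag(max(fit$noise_var, 1e-8), nrow(g))
        xi <- drop(lam * t(Phi_i) %*% solve(Sig, g$exposure - mu_i))
        sum((g$exposure - (mu_i + drop(Phi_i %*% xi)))^2)
      }, numeric(1)))
      err[as.character(L)] <- err[as.character(L)] + e
    }
  }
  err
}

#' Functional logistic regression on FPC scores
#'
#' Regresses the outcome on the leading L conditional-expectation FPC
#' scores plus baseline covariates; the time-varying coefficient is
#' reconstructed as `beta(t) = sum_l beta_l phi_l(t)`. A global L-df
#' likelihood-ratio test against the covariate-only model asks whether the
#' exposure process as a whole is associated with the outcome. This is the
#' two-step variant (scores first, then logistic regression); the
#' pointwise band on `beta(t)` is a plug-in that ignores FPCA estimation
#' uncertainty, and is flagged as such.
#'
#' @param cohort an ln-scale cohort.
#' @param L number of leading scores, or `"auto"` to select by the
#'   modified BIC of [select_fpca_model()]. `L = 0` reduces to the
#'   covariate-only model (LRT df 0, p = 1 by convention).
#' @param n_basis mean/covariance basis dimension (ignored with `"auto"`).
#' @param fpca optionally a precomputed [fpca_pace()] fit.
#' @return a [method_result()]; `extra$fpca` is the FPCA fit and
#'   `extra$beta_t` the reconstructed coefficient curve with plug-in SE.
#' @export
functional_logistic_model <- function(cohort, L = 2, n_basis = 9, fpca = NULL) {
  if (identical(L, "auto")) {
    sel <- select_fpca_model(cohort, criterion = "modified_bic")
    n_basis <- sel$n_basis
    L <- sel$L
    fpca <- NULL
  }
  fpca <- fpca %||% fpca_pace(cohort, n_basis = n_basis,
                              max_components = max(L, 2))
  if (L > length(fpca$eigenvalues)) {
    stop_input("L = ", L, " exceeds the ", length(fpca$eigenvalues),
               " available components")
  }
  bc <- active_baseline(cohort)
  dat <- dplyr::inner_join(fpca$scores,
                           cohort_subjects(cohort)[, c("subject_id", "outcome", bc)],
                           by = "subject_id")
  score_cols <- if (L > 0) paste0("xi_", seq_len(L)) else character()
  X1 <- build_design(dat, c(score_cols, bc))
  X0 <- build_design(dat, bc)
  fit0 <- fit_logistic(dat$outcome, X0)
  if (L == 0) {
    return(method_result(
      method = "functional_logistic", estimates = empty_estimates(),
      global_tests = tibble::tibble(test = "lrt", statistic = 0, df = 0, p = 1),
      n_used = nrow(dat), notes = "L = 0: covariate-only model",
      extra = list(fpca = fpca, fit = fit0)
    ))
  }
  fit1 <- fit_logistic(dat$outcome, X1)
  lr <- max(0, 2 * (fit1$loglik - fit0$loglik))
  gt <- tibble::tibble(test = "lrt", statistic = lr, df = L,
                       p = pchisq(lr, df = L, lower.tail = FALSE))
  bl <- fit1$coefficients[score_cols]
  Vb <- fit1$covariance[score_cols, score_cols, drop = FALSE]
  Phi <- fpca$eigenfunctions[, seq_len(L), drop = FALSE]
  beta_t <- tibble::tibble(
    week = fpca$grid,
    estimate = drop(Phi %*% bl),
    se = sqrt(rowSums((Phi %*% Vb) * Phi))
  )
  method_result(
    method = "functional_logistic",
    estimates = wald_row(fit1, score_cols),
    global_tests = gt, n_used = nrow(dat),
    notes = c(fit1$notes,
              "beta(t) band is plug-in and ignores FPCA estimation uncertainty"),
    extra = list(fpca = fpca, fit = fit1, beta_t = beta_t)
  )
}
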