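#' Logistic regression by iteratively reweighted least squares
#'
#' Core maximum-likelihood fitter used by every disease-risk model in the
#' package. Kept explicit (rather than delegated) so that the iteration
#' trace is available for diagnostics and so that separation is flagged
#' rather than silently producing huge coefficients.
#'
#' @param y binary 0/1 response vector.
#' @param design numeric model matrix with column names (include the
#'   intercept column yourself, e.g. via [build_design()]).
#' @param offset optional linear-predictor offset.
#' @param tol convergence tolerance on the deviance change.
#' @param max_iter maximum IRLS iterations.
#' @param separation_threshold flag the fit as non-converged when any
#'   coefficient, scaled by its column's SD, exceeds this value (a
#'   pragmatic divergence marker).
#' @return a `glm_fit` list: `coefficients`, `covariance` (inverse observed
#'   information), `se`, `loglik`, `deviance`, `deviance_trace`, `n_used`,
#'   `converged`, `iterations`, `notes`.
#' @examples
#' X <- cbind(intercept = 1, x = c(rep(1, 10), rep(0, 10)))
#' y <- c(rep(1, 6), rep(0, 4), rep(1, 3), rep(0, 7))
#' fit_logistic(y, X)$coefficients["x"] # ln((6*7)/(4*3))
#' @export
fit_logistic <- function(y, design, offset = NULL, tol = 1e-11, max_iter = 100,
                         separation_threshold = 10) {
  design <- as.matrix(design)
  if (is.null(colnames(design))) colnames(design) <- paste0("x", seq_len(ncol(design)))
  if (!is_binary01(y)) stop_input("y must be 0/1")
  if (nrow(design) != length(y)) stop_input("design rows must match length(y)")
  if (qr(design)$rank < ncol(design)) stop_input("design matrix is rank deficient")
  offset <- offset %||% rep(0, length(y))

  beta <- rep(0, ncol(design))
  dev_trace <- numeric(0)
  dev_old <- Inf
  converged <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    eta <- drop(design %*% beta) + offset
    mu <- expit(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    z <- eta - offset + (y - mu) / w
    fit <- lm.wfit(design, z, w)
    beta <- fit$coefficients
    eta <- drop(design %*% beta) + offset
    mu <- expit(eta)
    dev <- -2 * sum(y * log(pmax(mu, 1e-300)) + (1 - y) * log(pmax(1 - mu, 1e-300)))
    dev_trace <- c(dev_trace, dev)
    if (is.finite(dev_old) && abs(dev_old - dev) < tol) {
      converged <- TRUE
      break
    }
    dev_old <- dev
  }
  W <- pmax(mu * (1 - mu), 1e-12)
  info <- crossprod(design * sqrt(W))
  covariance <- tryCatch(solve(info), error = function(e) {
    matrix(NA_real_, ncol(design), ncol(design))
  })
  dimnames(covariance) <- list(colnames(design), colnames(design))
  se <- sqrt(diag(covariance))

  notes <- character()
  # scale by column SD so the check is unit-free; constant (intercept-like)
  # columns are excluded — their coefficient absorbs covariate means and can
  # legitimately be large
  col_sd <- apply(design, 2, sd)
  if (any(abs(beta[col_sd > 0] * col_sd[col_sd > 0]) > separation_threshold)) {
    converged <- FALSE
    notes <- c(notes, "possible separation: a standardized coefficient exceeds the divergence threshold")
    warn(notes[length(notes)])
  }
  structure(list(
    coefficients = setNames(beta, colnames(design)),
    covariance = covariance, se = setNames(se, colnames(design)),
    loglik = -dev / 2, deviance = dev, deviance_trace = dev_trace,
    n_used = length(y), converged = converged, iterations = iter,
    notes = notes, y = y, design = design, offset = offset
  ), class = "glm_fit")
}

#' @export
print.glm_fit <- function(x, ...) {
  cat(sprintf("<glm_fit> n=%d, loglik=%.3f, %s in %d iterations\n",
              x$n_used, x$loglik,
              if (x$converged) "converged" else "NOT converged", x$iterations))
  print(tidy_glm(x))
  invisible(x)
}

tidy_glm <- function(fit, conf = 0.95) {
  zq <- qnorm(1 - (1 - conf) / 2)
  tibble::tibble(
    term = names(fit$coefficients),
    estimate = unname(fit$coefficients),
    se = unname(fit$se),
    or = exp(.data$estimate),
    ci_low = exp(.data$estimate - zq * .data$se),
    ci_high = exp(.data$estimate + zq * .data$se),
    p = 2 * pnorm(-abs(.data$estimate / .data$se))
  )
}

penalized_loglik <- function(beta, y, X, P, offset = 0) {
  eta <- drop(X %*% beta) + offset
  sum(y * eta - log1p(exp(eta))) - 0.5 * drop(beta %*% P %*% beta)
}

ar1_corr <- function(n, rho) rho^abs(outer(seq_len(n), seq_len(n), "-"))

#' MAP logistic regression with a temporally correlated Gaussian prior
#'
#' Ridge-like shrinkage for the visit-specific exposure coefficients in the
#' simultaneous logistic model. The exposure block gets a mean-zero
#' Gaussian prior with covariance `tau2 * R(rho)`, where `R(rho)` is AR(1)
#' correlation over the visit order, encoding the belief that temporally
#' proximate visit effects are similar; the intercept and covariates are
#' unpenalized. Estimation is penalized IRLS; the posterior covariance is
#' the Laplace approximation (inverse of the penalized information).
#'
#' When `tau2` or `rho` is `NULL` both are chosen on a small grid
#' (`tau2` in 0.01/0.1/1/10, `rho` in 0/0.3/0.6/0.9) by maximizing the
#' Laplace approximation to the marginal likelihood.
#'
#' @inheritParams fit_logistic
#' @param exposure_block column names of the visit-exposure coefficients,
#'   ordered by visit.
#' @param tau2 prior variance (> 0) or `NULL` to select by grid.
#' @param rho AR(1) prior correlation (|rho| < 1) or `NULL` to select.
#' @return a `glm_fit` with extra elements `tau2`, `rho`, `log_marginal`.
#' @export
fit_map_logistic <- function(y, design, exposure_block, tau2 = NULL, rho = NULL,
                             offset = NULL, tol = 1e-10, max_iter = 200) {
  design <- as.matrix(design)
  if (!all(exposure_block %in% colnames(design))) {
    stop_input("exposure_block names not all present in design")
  }
  if (!is.null(tau2) && tau2 <= 0) stop_input("tau2 must be > 0")
  if (!is.null(rho) && abs(rho) >= 1) stop_input("|rho| must be < 1")
  offset <- offset %||% rep(0, length(y))

  grid <- if (is.null(tau2) || is.null(rho)) {
    expand.grid(tau2 = tau2 %||% c(0.01, 0.1, 1, 10),
                rho = rho %||% c(0, 0.3, 0.6, 0.9))
  } else {
    data.frame(tau2 = tau2, rho = rho)
  }
  best <- NULL
  for (g in seq_len(nrow(grid))) {
    cand <- map_logistic_one(y, design, exposure_block,
                             grid$tau2[g], grid$rho[g], offset, tol, max_iter)
    if (is.null(best) || cand$log_marginal > best$log_marginal) best <- cand
  }
  best
}

map_logistic_one <- function(y, X, block, tau2, rho, offset, tol, max_iter) {
  p <- ncol(X)
  idx <- match(block, colnames(X))
  R <- ar1_corr(length(idx), rho)
  Pblock <- solve(tau2 * R)
  P <- matrix(0, p, p)
  P[idx, idx] <- Pblock

  beta <- rep(0, p)
  obj_old <- -Inf
  converged <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    eta <- drop(X %*% beta) + offset
    mu <- expit(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    H <- crossprod(X * sqrt(w)) + P
    score <- drop(crossprod(X, y - mu)) - drop(P %*% beta)
    step <- solve(H, score)
    # halved Newton steps guarantee ascent of the penalized log-likelihood
    lam <- 1
    repeat {
      cand <- beta + lam * step
      if (penalized_loglik(cand, y, X, P, offset) >=
            penalized_loglik(beta, y, X, P, offset) - 1e-12 || lam < 1e-6) break
      lam <- lam / 2
    }
    beta <- beta + lam * step
    obj <- penalized_loglik(beta, y, X, P, offset)
    if (abs(obj - obj_old) < tol) {
      converged <- TRUE
      break
    }
    obj_old <- obj
  }
  eta <- drop(X %*% beta) + offset
  mu <- expit(eta)
  w <- pmax(mu * (1 - mu), 1e-12)
  H <- crossprod(X * sqrt(w)) + P
  covariance <- solve(H)
  dimnames(covariance) <- list(colnames(X), colnames(X))
  ll <- sum(y * eta - log1p(exp(eta)))
  bE <- beta[idx]
  # Laplace approximation to log p(y | tau2, rho)
  log_marg <- ll - 0.5 * drop(bE %*% Pblock %*% bE) -
    0.5 * determinant(2 * pi * tau2 * R, logarithm = TRUE)$modulus -
    0.5 * determinant(H / (2 * pi), logarithm = TRUE)$modulus
  structure(list(
    coefficients = setNames(beta, colnames(X)),
    covariance = covariance, se = sqrt(diag(covariance)),
    loglik = ll, deviance = -2 * ll, deviance_trace = numeric(0),
    n_used = length(y), converged = converged, iterations = iter,
    notes = character(), tau2 = tau2, rho = rho,
    log_marginal = as.numeric(log_marg),
    exposure_block = block, y = y, design = X, offset = offset
  ), class = "glm_fit")
}
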