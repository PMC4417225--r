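#' Gaussian mixture clustering of complete exposure vectors
#'
#' Treats each subject's exposure vector across visits as one draw from a
#' mixture of K multivariate normals with unstructured covariances, fitted
#' by EM. Because the vector is indexed by visit, only complete-case
#' subjects (all visits observed) can be used. For each candidate K the EM
#' is initialized from seeded k-means (10 restarts) and run to
#' convergence; K is chosen by BIC in the "larger is better" convention
#' `BIC = 2 loglik - m log N` (m = free parameters). Subjects are hard-
#' assigned by maximum posterior responsibility, and clusters are
#' relabelled by ascending overall mean level so labels are stable.
#'
#' A diagonal ridge proportional to `tr(S)/d` is added to a component
#' covariance only when it becomes numerically singular (e.g. duplicated
#' visit columns).
#'
#' @param cohort an ln-scale cohort.
#' @param k fixed number of components, or `NULL` to select from
#'   `1:k_max` by BIC.
#' @param k_max largest candidate K.
#' @param seed seed for the k-means initializations.
#' @param max_iter,tol EM iteration cap and relative log-likelihood
#'   convergence tolerance (`|dll| < tol * (1 + |ll|)`).
#' @return a `cluster_model` with `kind = "gmm"`: `k`, `assignment`
#'   (tibble subject_id/cluster), `component_summary` (per-cluster
#'   per-visit means), `selection` (BIC table), `means`, `covariances`,
#'   `proportions`, `loglik`, `loglik_trace`, `n_used`.
#' @export
gmm_cluster <- function(cohort, k = NULL, k_max = 5, seed = 1,
                        max_iter = 500, tol = 1e-6) {
  wide <- pivot_exposure_wide(cohort, require_complete = TRUE)
  X <- wide$exposure
  candidates <- if (is.null(k)) seq_len(k_max) else as.integer(k)
  need <- 10 * max(candidates)
  if (nrow(X) < need) {
    stop_input(
      "Gaussian mixture needs a balanced complete-case matrix with at least ",
      need, " subjects; only ", nrow(X), " have all ", ncol(X), " visits"
    )
  }
  fits <- lapply(candidates, function(K) {
    with_seed(mix_seed(seed, K), gmm_em(X, K, max_iter = max_iter, tol = tol))
  })
  bic <- vapply(fits, `[[`, numeric(1), "bic")
  best <- fits[[which.max(bic)]]
  K <- best$K

  # relabel components by ascending overall mean level
  lev <- rowMeans(best$means)
  relabel <- order(lev)
  cl <- match(best$assignment, relabel)
  means <- best$means[relabel, , drop = FALSE]
  rownames(means) <- paste0("cluster", seq_len(K))
  colnames(means) <- colnames(X)

  structure(list(
    kind = "gmm", k = K,
    assignment = tibble::tibble(subject_id = rownames(X), cluster = cl),
    component_summary = tibble::as_tibble(means, rownames = "cluster"),
    selection = tibble::tibble(k = candidates, bic = bic,
                               loglik = vapply(fits, `[[`, numeric(1), "loglik")),
    means = means,
    covariances = best$covariances[relabel],
    proportions = best$proportions[relabel],
    loglik = best$loglik, loglik_trace = best$trace,
    seed = seed, n_used = nrow(X)
  ), class = "cluster_model")
}

# EM for a K-component full-covariance Gaussian mixture
gmm_em <- function(X, K, max_iter = 500, tol = 1e-8) {
  N <- nrow(X)
  d <- ncol(X)
  if (K == 1L) {
    mu <- colMeans(X)
    S <- crossprod(sweep(X, 2, mu)) / N
    ll <- sum(mvn_logdens(X, mu, S))
    m <- d + d * (d + 1) / 2
    return(list(
      K = 1L, means = matrix(mu, 1, d), covariances = list(S),
      proportions = 1, assignment = rep(1L, N),
      loglik = ll, bic = 2 * ll - m * log(N), trace = ll
    ))
  }
  km <- kmeans(X, centers = K, nstart = 10)
  z <- km$cluster
  prop <- as.numeric(table(factor(z, levels = 1:K))) / N
  mu <- km$centers
  Sig <- lapply(1:K, function(g) {
    Xg <- X[z == g, , drop = FALSE]
    if (nrow(Xg) > d) crossprod(sweep(Xg, 2, colMeans(Xg))) / nrow(Xg)
    else diag(apply(X, 2, var))
  })

  trace <- numeric(0)
  ll_old <- -Inf
  resp <- NULL
  for (it in seq_len(max_iter)) {
    logd <- vapply(1:K, function(g) {
      log(prop[g]) + mvn_logdens(X, mu[g, ], Sig[[g]])
    }, numeric(N))
    mx <- apply(logd, 1, max)
    lse <- mx + log(rowSums(exp(logd - mx)))
    ll <- sum(lse)
    if (!is.finite(ll)) { # degenerate step; keep the last finite state
      ll <- ll_old
      break
    }
    trace <- c(trace, ll)
    resp <- exp(logd - lse)
    if (abs(ll - ll_old) < tol * (1 + abs(ll))) break
    ll_old <- ll
    nk <- colSums(resp)
    if (any(nk < d + 1)) break # a component collapsed onto too few points
    prop <- nk / N
    for (g in 1:K) {
      mu[g, ] <- colSums(resp[, g] * X) / nk[g]
      Xc <- sweep(X, 2, mu[g, ])
      Sig[[g]] <- crossprod(Xc * sqrt(resp[, g])) / nk[g]
    }
  }
  if (is.null(resp)) stop_input("mixture EM failed at initialization")
  m <- (K - 1) + K * d + K * d * (d + 1) / 2
  list(
    K = K, means = mu, covariances = Sig, proportions = prop,
    assignment = apply(resp, 1, which.max),
    loglik = ll, bic = 2 * ll - m * log(N), trace = trace
  )
}

# multivariate normal log-density rows of X; ridges the covariance only if
# the Cholesky fails (duplicate columns etc.)
mvn_logdens <- function(X, mu, S) {
  d <- ncol(X)
  ridge <- max(1e-6 * sum(diag(S)) / d, 1e-8)
  if (!all(is.finite(S))) stop_input("component covariance irreparably singular")
  ch <- NULL
  for (tries in 0:8) {
    ch <- tryCatch(chol(S + diag(ridge * (tries > 0) * 10^tries, d)),
                   error = function(e) NULL)
    if (!is.null(ch)) break
  }
  if (is.null(ch)) stop_input("component covariance irreparably singular")
  Xc <- sweep(X, 2, mu)
  Q <- forwardsolve(t(ch), t(Xc))
  -0.5 * (d * log(2 * pi) + 2 * sum(log(diag(ch))) + colSums(Q^2))
}

#' Functional k-means clustering of exposure curves
#'
#' Clusters subjects by the shape and level of their exposure-versus-time
#' relationship without requiring balance. Each subject's observations are
#' reduced to a least-squares line over gestational weeks (a constant when
#' only one visit is available), evaluated on a common grid spanning the
#' observed time range; k-means on the discretized curves then
#' approximates the principal points of the curve distribution. Optionally
#' the exposure is first residualized on covariates (see
#' [residualize_exposure()]) so the clustering reflects exposure rather
#' than, say, demographics.
#'
#' @param cohort an ln-scale cohort.
#' @param k number of clusters.
#' @param residualize regress the exposure on `covariate_names` first.
#' @param covariate_names covariates to residualize on (defaults to all
#'   declared covariates).
#' @param grid_size evaluation grid resolution.
#' @param seed seed for the k-means restarts.
#' @return a `cluster_model` with `kind = "functional"`; centroid curves
#'   are in `component_summary` (one row per cluster, grid in `grid`).
#' @export
functional_cluster <- function(cohort, k = 2, residualize = FALSE,
                               covariate_names = NULL, grid_size = 20, seed = 1) {
  work <- cohort
  if (residualize) {
    covariate_names <- covariate_names %||%
      c(active_tv(cohort), active_baseline(cohort))
    work <- residualize_exposure(cohort, covariate_names)
  }
  df <- tibble::as_tibble(work)
  N <- length(unique(df$subject_id))
  if (k < 1 || k >= N / 10) stop_input("k must satisfy 1 <= k < N/10")
  df$time_w <- df$time_days / 7
  rng <- range(df$time_w)
  grid <- seq(rng[1], rng[2], length.out = grid_size)
  # closed-form per-subject least-squares lines (constant when n_i = 1)
  lines <- df |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(
      n = dplyr::n(), mt = mean(.data$time_w), mx = mean(.data$exposure),
      sxx = sum((.data$time_w - .data$mt)^2),
      sxy = sum((.data$time_w - .data$mt) * (.data$exposure - .data$mx)),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      slope = ifelse(.data$n >= 2 & .data$sxx > 0, .data$sxy / .data$sxx, 0),
      intercept = .data$mx - .data$slope * .data$mt
    )
  M <- outer(lines$intercept, rep(1, grid_size)) + outer(lines$slope, grid)
  ids <- lines$subject_id
  rownames(M) <- ids
  km <- with_seed(seed, kmeans(M, centers = k, nstart = 20))
  relabel <- order(rowMeans(km$centers))
  cl <- match(km$cluster, relabel)
  centers <- km$centers[relabel, , drop = FALSE]
  rownames(centers) <- paste0("cluster", seq_len(k))
  colnames(centers) <- paste0("t", seq_len(grid_size))

  structure(list(
    kind = "functional", k = k,
    assignment = tibble::tibble(subject_id = ids, cluster = cl),
    component_summary = tibble::as_tibble(centers, rownames = "cluster"),
    grid = grid, residualized = if (residualize) covariate_names else character(),
    selection = tibble::tibble(k = k, bic = NA_real_,
                               loglik = NA_real_),
    seed = seed, n_used = N
  ), class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("<cluster_model: %s> K=%d, n=%d, sizes: %s\n",
              x$kind, x$k, x$n_used,
              paste(table(x$assignment$cluster), collapse = "/")))
  invisible(x)
}

#' @export
#' @rdname tidiers
tidy.cluster_model <- function(x, ...) x$assignment

#' Plot cluster profiles
#' @param object a `cluster_model`.
#' @param ... unused.
#' @return a ggplot of per-visit component means (gmm) or centroid curves
#'   (functional), one line per cluster.
#' @export
autoplot.cluster_model <- function(object, ...) {
  cs <- object$component_summary
  long <- tidyr::pivot_longer(cs, -"cluster", names_to = "at", values_to = "mean")
  long$x <- if (object$kind == "functional") {
    object$grid[as.integer(gsub("\\D", "", long$at))]
  } else {
    as.numeric(gsub("\\D", "", long$at))
  }
  ggplot2::ggplot(long, ggplot2::aes(.data$x, .data$mean, colour = .data$cluster)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = if (object$kind == "functional") "gestational week" else "visit",
      y = "cluster mean ln exposure"
    )
}

#' Associate a clustering with the outcome
#'
#' Stage 2 for both clustering strategies: (a) a chi-square test of
#' independence on the K x 2 cluster-by-outcome table (df = K - 1;
#' Pearson, no continuity correction), with a warning note when an
#' expected count falls below 5 and an exact-test fallback when the table
#' is degenerate; (b) a logistic regression of the outcome on K - 1
#' cluster indicators plus baseline covariates, reporting each cluster's
#' odds ratio against cluster 1. A cluster holding under 5% of subjects
#' triggers an instability note.
#'
#' @param model a `cluster_model`.
#' @param cohort the cohort the clustering came from.
#' @return a [method_result()].
#' @export
cluster_association <- function(model, cohort) {
  subj <- cohort_subjects(cohort)
  dat <- dplyr::inner_join(model$assignment, subj, by = "subject_id")
  dat$cluster <- factor(dat$cluster, levels = seq_len(model$k))
  tab <- table(dat$cluster, dat$outcome)
  notes <- character()

  if (model$k < 2) {
    chi <- tibble::tibble(test = "cluster_chisq", statistic = NA_real_,
                          df = 0, p = NA_real_)
    notes <- c(notes, "single cluster: association test undefined")
  } else {
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expected == 0) || any(rowSums(tab) == 0)) {
      ft <- fisher.test(tab)
      chi <- tibble::tibble(test = "cluster_exact", statistic = NA_real_,
                            df = model$k - 1, p = ft$p.value)
      notes <- c(notes, "degenerate table: exact-test fallback used")
    } else {
      ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
      chi <- tibble::tibble(test = "cluster_chisq",
                            statistic = unname(ct$statistic),
                            df = model$k - 1, p = ct$p.value)
      if (any(expected < 5)) {
        notes <- c(notes, "expected cell count < 5 in the cluster-outcome table")
      }
    }
  }
  sizes <- table(dat$cluster)
  if (any(sizes < 0.05 * nrow(dat))) {
    notes <- c(notes, sprintf(
      "unstable clustering: cluster sizes %s include one below 5%% of subjects",
      paste(sizes, collapse = "/")
    ))
  }

  est <- empty_estimates()
  fit <- NULL
  if (model$k >= 2 && all(sizes > 0)) {
    X <- build_design(dat, c("cluster", active_baseline(cohort)))
    fit <- tryCatch(fit_logistic(dat$outcome, X), error = function(e) NULL)
    if (!is.null(fit)) {
      est <- wald_row(fit, paste0("cluster", 2:model$k))
      notes <- c(notes, fit$notes)
    } else {
      notes <- c(notes, "stage-2 logistic fit failed; chi-square test only")
    }
  }
  method_result(
    method = paste0(model$kind, "_cluster"),
    estimates = est, global_tests = chi, n_used = nrow(dat), notes = notes,
    extra = list(table = tab, model = model, fit = fit)
  )
}

empty_estimates <- function() {
  tibble::tibble(term = character(), estimate = numeric(), se = numeric(),
                 or = numeric(), ci_low = numeric(), ci_high = numeric(),
                 p = numeric())
}

#' Screen a clustering for covariate dependence
#'
#' Diagnostic for the functional clustering: per covariate, a one-way
#' ANOVA F test (numeric) or chi-square test (categorical) of whether the
#' covariate differs across clusters. A clustering strongly driven by
#' demographics suggests clustering residual curves instead.
#'
#' @param model a `cluster_model`.
#' @param cohort the source cohort.
#' @return tibble of (covariate, test, statistic, p).
#' @export
cluster_covariate_screen <- function(model, cohort) {
  subj <- cohort_subjects(cohort)
  tvm <- tibble::as_tibble(cohort) |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(attr(cohort, "tv_covariates")),
                                   mean), .groups = "drop")
  dat <- model$assignment |>
    dplyr::inner_join(subj, by = "subject_id") |>
    dplyr::inner_join(tvm, by = "subject_id")
  covs <- c(attr(cohort, "tv_covariates"), attr(cohort, "baseline_covariates"))
  purrr::map_dfr(covs, function(v) {
    if (is.numeric(dat[[v]]) && length(unique(dat[[v]])) > 5) {
      fit <- stats::oneway.test(dat[[v]] ~ factor(dat$cluster), var.equal = TRUE)
      tibble::tibble(covariate = v, test = "anova_F",
                     statistic = unname(fit$statistic), p = fit$p.value)
    } else {
      ct <- suppressWarnings(chisq.test(table(dat[[v]], dat$cluster)))
      tibble::tibble(covariate = v, test = "chisq",
                     statistic = unname(ct$statistic), p = ct$p.value)
    }
  })
}
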