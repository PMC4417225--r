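# Small cohorts and utilities shared across tests. All fixtures are built
# in code; nothing is read from disk.

toy_cohort_df <- function() {
  tibble::tibble(
    subject_id = c("a", "a", "b", "b", "b", "c"),
    outcome = c(1, 1, 0, 0, 0, 1),
    visit = c(1, 2, 1, 2, 3, 1),
    time_days = c(70, 120, 65, 125, 180, 80),
    exposure = c(1.2, 2.1, 0.7, 0.9, 1.4, 3.0),
    sg = c(1.01, 1.02, 1.015, 1.013, 1.02, 1.011),
    tod = c(0, 1, 0, 0, 1, 1),
    age_c = c(2, 2, -1, -1, -1, 0.5)
  )
}

toy_cohort <- function(scale = "raw") {
  as_cohort(toy_cohort_df(), exposure_scale = scale,
            tv_covariates = c("sg", "tod"), baseline_covariates = "age_c")
}

# balanced cohort with exposure = subject effect + noise, no covariates
balanced_cohort <- function(N = 40, n = 4, sd_b = 1, sd_e = 1, seed = 1,
                            outcome_p = 0.3) {
  set.seed(seed)
  b <- rnorm(N, 0, sd_b)
  y <- rbinom(N, 1, outcome_p)
  df <- tidyr::expand_grid(i = seq_len(N), j = seq_len(n))
  df <- dplyr::mutate(df,
    subject_id = sprintf("s%03d", .data$i),
    outcome = y[.data$i],
    visit = .data$j,
    time_days = 60 + 60 * (.data$j - 1) + .data$i * 0.01,
    exposure = b[.data$i] + rnorm(nrow(df), 0, sd_e)
  )
  as_cohort(df[, -(1:2)], exposure_scale = "ln")
}

adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  (sum_ij - expected) / (maxi - expected)
}

# closed-form REML log-likelihood for the balanced random-intercept model,
# used as an independent oracle against the mixed-model fitter
reml_loglik_ri <- function(x, id, var_b, var_e) {
  ids <- unique(id)
  X <- matrix(1, length(x), 1)
  V_logdet <- 0
  quad <- 0
  XtViX <- 0
  XtViy <- 0
  for (s in ids) {
    ii <- which(id == s)
    n_i <- length(ii)
    Vi <- diag(var_e, n_i) + matrix(var_b, n_i, n_i)
    ch <- chol(Vi)
    V_logdet <- V_logdet + 2 * sum(log(diag(ch)))
    Vinv <- chol2inv(ch)
    XtViX <- XtViX + sum(Vinv)
    XtViy <- XtViy + sum(Vinv %*% x[ii])
  }
  beta <- XtViy / XtViX
  for (s in ids) {
    ii <- which(id == s)
    n_i <- length(ii)
    Vi <- diag(var_e, n_i) + matrix(var_b, n_i, n_i)
    r <- x[ii] - beta
    quad <- quad + drop(r %*% solve(Vi, r))
  }
  n <- length(x)
  -0.5 * (V_logdet + log(XtViX) + quad + (n - 1) * log(2 * pi))
}

rebuild_cohort_for_test <- function(df, template) {
  longexpo:::rebuild_cohort(df, template)
}
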