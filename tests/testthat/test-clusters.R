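test_that("one-component mixture equals the sample moments", {
  co <- simulate_cohort(
    make_scenario("phthalate_like", n_subjects = 60,
                  case_dropout_prob = 0, control_dropout_prob = 0),
    seed = 71
  )
  m <- gmm_cluster(co, k = 1)
  X <- pivot_exposure_wide(co, TRUE)$exposure
  expect_equal(unname(m$means[1, ]), unname(colMeans(X)), tolerance = 1e-8)
  S <- crossprod(sweep(X, 2, colMeans(X))) / nrow(X)
  expect_equal(unname(m$covariances[[1]]), unname(S), tolerance = 1e-8)
})

test_that("BIC selects the planted number of well-separated components", {
  set.seed(72)
  N <- 300
  grp <- rep(1:2, each = N / 2)
  centers <- rbind(rep(0, 4), rep(5, 4)) # 5 SD apart at unit variance
  df <- tidyr::expand_grid(i = 1:N, j = 1:4)
  df <- dplyr::mutate(df,
    subject_id = sprintf("s%03d", i), outcome = rbinom(N, 1, 0.3)[i],
    visit = j, time_days = 50 + 45 * j,
    exposure = centers[cbind(grp[i], j)] + rnorm(nrow(df))
  )
  co <- as_cohort(df[, -(1:2)], "ln")
  m <- gmm_cluster(co, k_max = 4, seed = 5)
  expect_equal(m$k, 2)
  expect_gte(adjusted_rand_index(m$assignment$cluster, grp), 0.95)
  # selected K maximizes the reported BIC table
  expect_equal(m$selection$k[which.max(m$selection$bic)], m$k)
  # EM log-likelihood is monotone non-decreasing
  expect_true(all(diff(m$loglik_trace) >= -1e-10))
  # labels ordered by ascending overall mean
  expect_lt(mean(m$means[1, ]), mean(m$means[2, ]))
})

test_that("a duplicated visit column engages the ridge instead of failing", {
  co <- simulate_cohort(
    make_scenario("phthalate_like", n_subjects = 80,
                  case_dropout_prob = 0, control_dropout_prob = 0),
    seed = 73
  )
  df <- tibble::as_tibble(co)
  df$exposure[df$visit == 2] <- df$exposure[df$visit == 1] # visit copied
  co2 <- rebuild_cohort_for_test(df, co)
  m <- gmm_cluster(co2, k = 2, seed = 1)
  expect_true(is.finite(m$loglik))
})

test_that("mixture model refuses clearly insufficient complete cases", {
  co <- simulate_cohort(make_scenario("phthalate_like", n_subjects = 30),
                        seed = 74)
  expect_error(gmm_cluster(co, k_max = 5), "balanced complete-case")
})

test_that("functional k-means separates flat curves and keeps singletons", {
  df <- tidyr::expand_grid(i = 1:60, j = 1:3)
  lev <- rep(c(0, 10), each = 30)
  df <- dplyr::mutate(df,
    subject_id = sprintf("s%03d", i), outcome = rep(c(1, 0), 30)[i],
    visit = j, time_days = 50 + 45 * j,
    exposure = lev[i] + rnorm(nrow(df), 0, 0.3)
  )
  # one extra single-visit subject near the low group
  df <- dplyr::bind_rows(
    df[, -(1:2)],
    tibble::tibble(subject_id = "zz1", outcome = 0, visit = 1,
                   time_days = 100, exposure = 0.2)
  )
  co <- as_cohort(df, "ln")
  m <- functional_cluster(co, k = 2, seed = 3)
  expect_equal(adjusted_rand_index(
    m$assignment$cluster[m$assignment$subject_id != "zz1"], lev
  ), 1)
  expect_true("zz1" %in% m$assignment$subject_id)
  # the singleton lands with the low-level cluster
  expect_equal(m$assignment$cluster[m$assignment$subject_id == "zz1"], 1L)
  # given a seed, reproducible and invariant to subject order
  m2 <- functional_cluster(co, k = 2, seed = 3)
  expect_identical(m$assignment, m2$assignment)
  perm <- df[sample(nrow(df)), ]
  m3 <- functional_cluster(as_cohort(perm, "ln"), k = 2, seed = 3)
  expect_identical(dplyr::arrange(m3$assignment, subject_id),
                   dplyr::arrange(m$assignment, subject_id))
})

test_that("residualizing removes covariate-driven clustering", {
  clean <- vapply(1:12, function(r) {
    set.seed(800 + r)
    N <- 150
    race <- rbinom(N, 1, 0.5) # binary covariate driving the level
    df <- tidyr::expand_grid(i = 1:N, j = 1:3)
    df <- dplyr::mutate(df,
      subject_id = sprintf("s%03d", i), outcome = rbinom(N, 1, 0.3)[i],
      visit = j, time_days = 50 + 45 * j,
      exposure = 2 * race[i] + rnorm(nrow(df), 0, 0.7),
      race = race[i]
    )
    co <- as_cohort(df[, -(1:2)], "ln", baseline_covariates = "race")
    m <- functional_cluster(co, k = 2, residualize = TRUE,
                            covariate_names = "race", seed = r)
    p <- suppressWarnings(chisq.test(table(
      m$assignment$cluster,
      race[match(m$assignment$subject_id, sprintf("s%03d", 1:N))]
    ))$p.value)
    p > 0.05
  }, logical(1))
  expect_gte(mean(clean), 0.9)
})

test_that("cluster association reproduces the closed-form chi-square", {
  # table [[20,10],[10,20]] -> chi2 = 20/3, df 1
  df <- tibble::tibble(
    subject_id = sprintf("s%02d", 1:60),
    outcome = c(rep(1, 20), rep(0, 10), rep(1, 10), rep(0, 20)),
    visit = 1L, time_days = 100,
    exposure = rnorm(60)
  )
  co <- as_cohort(df, "ln")
  model <- structure(list(
    kind = "functional", k = 2L,
    assignment = tibble::tibble(subject_id = df$subject_id,
                                cluster = rep(1:2, each = 30)),
    component_summary = NULL, selection = NULL, seed = 1, n_used = 60
  ), class = "cluster_model")
  r <- cluster_association(model, co)
  expect_equal(r$global_tests$statistic, 20 / 3, tolerance = 1e-10)
  expect_equal(r$global_tests$df, 1)
})

test_that("a tiny cluster triggers the instability note", {
  df <- tibble::tibble(
    subject_id = sprintf("s%03d", 1:280),
    outcome = rbinom(280, 1, 0.3),
    visit = 1L, time_days = 100, exposure = rnorm(280)
  )
  co <- as_cohort(df, "ln")
  model <- structure(list(
    kind = "gmm", k = 2L,
    assignment = tibble::tibble(subject_id = df$subject_id,
                                cluster = c(rep(1, 274), rep(2, 6))),
    component_summary = NULL, selection = NULL, seed = 1, n_used = 280
  ), class = "cluster_model")
  r <- cluster_association(model, co)
  expect_match(paste(r$notes, collapse = " "), "unstable clustering")
})

test_that("EM solution matches reference model-based clustering on separated data", {
  set.seed(75)
  N <- 200
  grp <- rep(1:2, each = N / 2)
  centers <- rbind(rep(0, 4), rep(4, 4))
  df <- tidyr::expand_grid(i = 1:N, j = 1:4)
  df <- dplyr::mutate(df,
    subject_id = sprintf("s%03d", i), outcome = rbinom(N, 1, 0.3)[i],
    visit = j, time_days = 50 + 45 * j,
    exposure = centers[cbind(grp[i], j)] + rnorm(nrow(df))
  )
  co <- as_cohort(df[, -(1:2)], "ln")
  m <- gmm_cluster(co, k = 2, seed = 2)
  X <- pivot_exposure_wide(co, TRUE)$exposure
  mclustBIC <- mclust::mclustBIC # Mclust looks this up in the calling frame
  ref <- mclust::Mclust(X, G = 2, modelNames = "VVV", verbose = FALSE)
  # both maximize the same unstructured-covariance mixture likelihood
  expect_lt(abs(m$loglik - ref$loglik), 1)
  expect_equal(adjusted_rand_index(m$assignment$cluster, ref$classification), 1)
})
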