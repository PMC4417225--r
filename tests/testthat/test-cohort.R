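test_that("long CSV round-trips through read/write and enforces invariants", {
  co <- toy_cohort()
  expect_equal(sort(cohort_subjects(co)$n_visits), c(1, 2, 3))

  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort_long(co, path)
  co2 <- read_cohort_long(path, schema = list(
    tv_covariates = c("sg", "tod"), baseline_covariates = "age_c"
  ))
  expect_equal(tibble::as_tibble(co2), tibble::as_tibble(co))

  # outcome flip within subject
  bad <- toy_cohort_df()
  bad$outcome[2] <- 0
  expect_error(as_cohort(bad, "raw"), "outcome not constant")

  # duplicate (subject, visit)
  bad <- toy_cohort_df()
  bad$visit[2] <- 1
  expect_error(as_cohort(bad, "raw"), "duplicate")

  # non-positive raw exposure lists offending rows
  bad <- toy_cohort_df()
  bad$exposure[3] <- -1
  expect_error(as_cohort(bad, "raw"), "non-positive raw exposure.*3")

  # missing exposure rows dropped with message
  miss <- toy_cohort_df()
  miss$exposure[5] <- NA
  path2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(miss, path2, row.names = FALSE)
  expect_message(co3 <- read_cohort_long(path2), "dropping 1 rows")
  expect_equal(nrow(co3), 5)
})

test_that("ln_transform is exact, guarded and idempotent-checked", {
  df <- toy_cohort_df()[1:3, ]
  df$subject_id <- c("a", "a", "b")
  df$visit <- c(1, 2, 1)
  df$exposure <- c(1, exp(1), exp(2))
  co <- as_cohort(df, "raw")
  lt <- ln_transform(co)
  expect_equal(lt$exposure, c(0, 1, 2))
  expect_error(ln_transform(lt), "already transformed")
  df$exposure[1] <- 0
  expect_error(as_cohort(df, "raw"), "non-positive")
})

test_that("residualize_exposure is a no-op on the empty set and orthogonalizes", {
  co <- ln_transform(toy_cohort())
  expect_identical(residualize_exposure(co, character()), co)

  # exposure exactly linear in sg -> residuals ~ 0
  df <- tibble::as_tibble(co)
  df$exposure <- 3 + 5 * df$sg
  lin <- rebuild_cohort_for_test(df, co)
  r <- residualize_exposure(lin, "sg")
  expect_lt(max(abs(r$exposure)), 1e-10)

  # least-squares orthogonality against each regressor
  set.seed(11)
  co2 <- balanced_cohort(N = 30, seed = 11)
  df2 <- tibble::as_tibble(co2)
  df2$sg <- rnorm(nrow(df2), 1.015, 0.005)
  df2$tod <- rbinom(nrow(df2), 1, 0.5)
  co2 <- as_cohort(df2, "ln", tv_covariates = c("sg", "tod"))
  r2 <- residualize_exposure(co2, c("sg", "tod"))
  expect_lt(abs(cor(r2$exposure, r2$sg)), 1e-10)
  expect_lt(abs(cor(r2$exposure, r2$tod)), 1e-10)
  # residualized covariates excluded downstream
  expect_false("sg" %in% longexpo:::active_tv(r2))

  # collinear design errors with the offending column named
  df3 <- tibble::as_tibble(co2)
  df3$sg2 <- df3$sg
  co3 <- as_cohort(df3, "ln", tv_covariates = c("sg", "sg2"))
  expect_error(residualize_exposure(co3, c("sg", "sg2")), "collinear.*sg2")
})

test_that("pivot_exposure_wide counts and masks unbalanced cohorts", {
  co <- ln_transform(toy_cohort())
  full <- pivot_exposure_wide(co, require_complete = FALSE)
  expect_equal(dim(full$exposure), c(3, 3))
  expect_equal(sum(!full$observed), 3)
  cc <- pivot_exposure_wide(co, require_complete = TRUE)
  expect_equal(nrow(cc$exposure), 1)
  expect_equal(rownames(cc$exposure), "b")

  bal <- balanced_cohort(N = 12, seed = 2)
  a <- pivot_exposure_wide(bal, FALSE)
  b <- pivot_exposure_wide(bal, TRUE)
  expect_identical(a$exposure, b$exposure)
})

test_that("ICC recovers its generating value and its degenerate limits", {
  # constant-within-subject exposure: icc -> 1
  df <- tidyr::expand_grid(i = 1:10, j = 1:3)
  df <- dplyr::mutate(df,
    subject_id = paste0("s", i), outcome = 0, visit = j,
    time_days = 50 + 50 * j, exposure = i * 0.5
  )
  co <- as_cohort(df[, -(1:2)], "ln")
  est <- cohort_icc(co, B = 0)
  expect_gt(est$icc, 1 - 1e-6)

  # shared mean, iid noise: icc ~ 0
  co0 <- balanced_cohort(N = 250, sd_b = 0, sd_e = 1, seed = 3)
  expect_lt(cohort_icc(co0, B = 0)$icc, 0.05)

  # var_b = var_e = 1: icc ~ 0.5, bootstrap CI brackets the point
  co5 <- balanced_cohort(N = 400, sd_b = 1, sd_e = 1, seed = 4)
  est5 <- cohort_icc(co5, B = 40, seed = 9)
  expect_lt(abs(est5$icc - 0.5), 0.1)
  expect_lte(est5$ci_low, est5$icc)
  expect_gte(est5$ci_high, est5$icc)
  expect_equal(est5$icc, est5$between_var / (est5$between_var + est5$within_var))

  # invariance to exposure shift
  dfs <- tibble::as_tibble(co5)
  dfs$exposure <- dfs$exposure + 7
  shifted <- as_cohort(dfs, "ln")
  expect_equal(cohort_icc(shifted, B = 0)$icc, est5$icc, tolerance = 1e-6)

  # all-singleton cohort is unidentifiable
  one <- dplyr::filter(tibble::as_tibble(co5), visit == 1)
  expect_error(cohort_icc(as_cohort(one, "ln"), B = 0), "unidentifiable")
})

test_that("visit correlations reflect the exchangeable structure", {
  # identical values across visits -> all off-diagonals 1
  df <- tidyr::expand_grid(i = 1:8, j = 1:3)
  df <- dplyr::mutate(df,
    subject_id = paste0("s", i), outcome = 0, visit = j,
    time_days = 50 + 40 * j, exposure = sin(i)
  )
  co <- as_cohort(df[, -(1:2)], "ln")
  V <- visit_correlations(co)
  expect_true(all(abs(V - 1) < 1e-12))

  # independent noise: off-diagonals near zero
  co0 <- balanced_cohort(N = 400, sd_b = 0, sd_e = 1, seed = 5)
  V0 <- visit_correlations(co0)
  expect_lt(max(abs(V0[upper.tri(V0)])), 0.1)
  expect_identical(V0, t(V0))
})

test_that("exchangeable correlation of the generator matches the target ICC", {
  sc <- make_scenario("phthalate_like", icc_target = 0.57, n_subjects = 700,
                      case_dropout_prob = 0, control_dropout_prob = 0)
  co <- simulate_cohort(sc, seed = 21)
  V <- visit_correlations(co)
  expect_lt(abs(mean(V[upper.tri(V)]) - 0.57), 0.06)
})
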