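#' Run every modelling strategy on one cohort
#'
#' Applies the selected strategies to the same cohort and collects their
#' uniform results. A strategy that cannot run on this cohort (for
#' example the Gaussian mixture when too few subjects are complete-case)
#' contributes a failure row with the reason instead of aborting the
#' comparison.
#'
#' @param cohort an ln-scale cohort.
#' @param methods character vector of strategy labels; the default runs
#'   all of `multiple`, `bayes_multiple`, `cross_sectional`, `mean`,
#'   `max`, `two_stage`, `two_stage_cluster`, `trajectory`, `gmm`,
#'   `functional_cluster`, `functional_logistic`.
#' @param k number of clusters for the clustering strategies.
#' @param L number of FPC scores for the functional logistic model.
#' @param seed seed shared by all seeded internals.
#' @return a `method_comparison`: list with `results` (named list of
#'   method results), `failures` (tibble of method/reason), and `summary`
#'   (one glance row per method that ran).
#' @export
compare_methods <- function(cohort, methods = NULL, k = 2, L = 2, seed = 1) {
  all_methods <- c(
    "multiple", "bayes_multiple", "cross_sectional", "mean", "max",
    "two_stage", "two_stage_cluster", "trajectory", "gmm",
    "functional_cluster", "functional_logistic"
  )
  methods <- methods %||% all_methods
  bad <- setdiff(methods, all_methods)
  if (length(bad)) stop_input("unknown methods: ", paste(bad, collapse = ", "))

  runners <- list(
    multiple = function() multiple_logistic_model(cohort),
    bayes_multiple = function() multiple_logistic_model(cohort, bayes = TRUE),
    cross_sectional = function() cross_sectional_models(cohort, correction = "bonferroni"),
    mean = function() mean_summary_model(cohort),
    max = function() max_summary_model(cohort),
    two_stage = function() two_stage_blup_model(cohort),
    two_stage_cluster = function() two_stage_cluster_model(cohort, k = k, seed = seed),
    trajectory = function() trajectory_method_result(trajectory_contrast(cohort)),
    gmm = function() cluster_association(gmm_cluster(cohort, k = k, seed = seed), cohort),
    functional_cluster = function() cluster_association(
      functional_cluster(cohort, k = k, residualize = TRUE, seed = seed), cohort
    ),
    functional_logistic = function() functional_logistic_model(cohort, L = L)
  )

  results <- list()
  failures <- tibble::tibble(method = character(), reason = character())
  for (m in methods) {
    res <- tryCatch(suppressWarnings(runners[[m]]()), error = function(e) e)
    if (inherits(res, "error")) {
      failures <- dplyr::bind_rows(failures,
                                   tibble::tibble(method = m, reason = conditionMessage(res)))
    } else {
      results[[m]] <- res
    }
  }
  if (!length(results)) {
    stop_input("no method could run; first failure: ",
               failures$reason[1] %||% "unknown")
  }
  structure(list(
    results = results, failures = failures,
    summary = purrr::map_dfr(results, glance),
    seed = seed
  ), class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, ...) {
  cat(sprintf("<method_comparison> %d methods ran, %d failed\n",
              length(x$results), nrow(x$failures)))
  print(x$summary)
  if (nrow(x$failures)) {
    cat("failures:\n")
    print(x$failures)
  }
  invisible(x)
}

#' @export
#' @rdname tidiers
tidy.method_comparison <- function(x, ...) {
  purrr::map_dfr(x$results, tidy)
}

#' Serialize a comparison to TSV and JSON
#'
#' Writes `comparison.tsv` (the per-term estimates across methods) and
#' `comparison.json` (estimates, global tests, notes and failures) into
#' `dir`. Output is byte-stable for a fixed cohort and seed.
#'
#' @param x a `method_comparison`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_comparison <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  est <- tidy(x)
  utils::write.table(est, file.path(dir, "comparison.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  payload <- list(
    summary = x$summary,
    estimates = est,
    global_tests = purrr::map_dfr(x$results, function(r) {
      dplyr::mutate(r$global_tests, method = r$method, .before = 1)
    }),
    notes = purrr::map(x$results, "notes"),
    failures = x$failures,
    seed = x$seed
  )
  writeLines(
    jsonlite::toJSON(payload, digits = 10, auto_unbox = TRUE, na = "null"),
    file.path(dir, "comparison.json")
  )
  invisible(dir)
}

#' Headline p-values of every strategy on one cohort
#'
#' The single decision-making test per strategy, as used by the
#' simulation harness: Bonferroni-corrected smallest per-visit Wald p for
#' the simultaneous and the parallel cross-sectional models, the GEE
#' equality test, the exposure Wald test for the mean / max / two-stage
#' models (the two-stage slope term is reported separately when
#' retained), the approximate interaction LRT for the trajectory
#' contrast, the cluster chi-square tests at fixed K, and the L-df LRT
#' for the functional logistic model.
#'
#' @param cohort an ln-scale cohort.
#' @param methods which headline tests to compute (default all).
#' @param k,L clustering / score dimensions used by the harness.
#' @param seed seed for seeded internals.
#' @return tibble of (test, p, estimate, n_used); `estimate` is filled
#'   where a single exposure coefficient exists.
#' @export
headline_tests <- function(cohort, methods = NULL, k = 2, L = 2, seed = 1) {
  all_tests <- c("multiple_any_visit", "cross_any_visit", "gee_equality",
                 "mean_wald", "max_wald", "two_stage_wald", "two_stage_slope",
                 "gamm_interaction", "gmm_chisq", "fclust_chisq", "flr_lrt")
  methods <- methods %||% all_tests
  nm <- n_visits(cohort)
  rows <- list()
  add <- function(test, p, estimate = NA_real_, n_used = NA_integer_) {
    rows[[length(rows) + 1]] <<- tibble::tibble(
      test = test, p = p, estimate = estimate, n_used = n_used
    )
  }
  want <- function(x) any(x %in% methods)

  if (want("multiple_any_visit")) {
    r <- multiple_logistic_model(cohort)
    add("multiple_any_visit", min(pmin(r$estimates$p * nm, 1)), n_used = r$n_used)
  }
  if (want(c("cross_any_visit", "gee_equality"))) {
    r <- cross_sectional_models(cohort, correction = "bonferroni")
    if (want("cross_any_visit")) {
      add("cross_any_visit", min(r$estimates$p_adjusted), n_used = r$n_used)
    }
    if (want("gee_equality") && nrow(r$global_tests)) {
      add("gee_equality", r$global_tests$p[1], n_used = r$n_used)
    }
  }
  if (want("mean_wald")) {
    r <- mean_summary_model(cohort)
    add("mean_wald", r$estimates$p[1], r$estimates$estimate[1], r$n_used)
  }
  if (want("max_wald")) {
    r <- max_summary_model(cohort)
    add("max_wald", r$estimates$p[1], r$estimates$estimate[1], r$n_used)
  }
  if (want(c("two_stage_wald", "two_stage_slope"))) {
    r <- two_stage_blup_model(cohort)
    ei <- r$estimates[r$estimates$term == "blup_intercept", ]
    if (want("two_stage_wald")) {
      add("two_stage_wald", ei$p[1], ei$estimate[1], r$n_used)
    }
    es <- r$estimates[r$estimates$term == "blup_slope", ]
    if (want("two_stage_slope") && nrow(es)) {
      add("two_stage_slope", es$p[1], es$estimate[1], r$n_used)
    }
  }
  if (want("gamm_interaction")) {
    f <- trajectory_contrast(cohort, test_only = TRUE)
    add("gamm_interaction", f$interaction_test$p, n_used = f$n_used)
  }
  if (want("gmm_chisq")) {
    r <- cluster_association(gmm_cluster(cohort, k = k, seed = seed), cohort)
    add("gmm_chisq", r$global_tests$p[1], n_used = r$n_used)
  }
  if (want("fclust_chisq")) {
    r <- cluster_association(
      functional_cluster(cohort, k = k, residualize = FALSE, seed = seed), cohort
    )
    add("fclust_chisq", r$global_tests$p[1], n_used = r$n_used)
  }
  if (want("flr_lrt")) {
    r <- functional_logistic_model(cohort, L = L)
    add("flr_lrt", r$global_tests$p[1], n_used = r$n_used)
  }
  dplyr::bind_rows(rows)
}

#' Operating characteristics by simulation
#'
#' For each scenario and each headline test, simulates `reps` cohorts and
#' measures the rejection rate at level `alpha`, plus bias and RMSE of
#' the exposure estimate where the scenario defines a target parameter
#' (the mean-effect scenario targets the mean-model coefficient; the
#' slope scenario the two-stage slope coefficient). Per-rep results can
#' be streamed to a CSV so long runs are resumable.
#'
#' @param scenarios named list of scenarios from [make_scenario()].
#' @param methods headline test labels (see [headline_tests()]).
#' @param reps replicates per scenario; below 100 a low-rep note is
#'   attached.
#' @param alpha test level.
#' @param seed base seed; each (scenario, rep) derives its own stream.
#' @param k,L harness clustering / score dimensions.
#' @param stream optional CSV path for per-rep streaming/resume.
#' @return an `operating_characteristics` tibble: scenario, test,
#'   rejection_rate, mc_se, bias, rmse, mean_n_used, reps, n_failed,
#'   seed; attribute `notes` carries warnings.
#' @export
simulation_study <- function(scenarios, methods = NULL, reps = 200,
                             alpha = 0.05, seed = 1, k = 2, L = 2,
                             stream = NULL) {
  if (!is.list(scenarios) || is.null(names(scenarios)) ||
        inherits(scenarios, "lexp_scenario")) {
    scenarios <- list(scenario = scenarios)
  }
  notes <- character()
  if (reps < 100) {
    notes <- c(notes, sprintf("low replicate count (%d); published tables use >= 100", reps))
    warn(notes[length(notes)])
  }
  done <- NULL
  if (!is.null(stream) && file.exists(stream)) {
    done <- tibble::as_tibble(read.csv(stream, stringsAsFactors = FALSE))
  }
  per_rep <- list(if (!is.null(done)) done)
  for (s in seq_along(scenarios)) {
    sc_name <- names(scenarios)[s]
    sc <- scenarios[[s]]
    for (r in seq_len(reps)) {
      if (!is.null(done) &&
            any(done$scenario == sc_name & done$rep == r)) next
      rep_seed <- mix_seed(seed + s * 131071, r)
      cohort <- simulate_cohort(sc, seed = rep_seed)
      row <- tryCatch(
        suppressWarnings(
          headline_tests(cohort, methods = methods, k = k, L = L, seed = rep_seed)
        ),
        error = function(e) tibble::tibble(
          test = "ALL", p = NA_real_, estimate = NA_real_,
          n_used = NA_integer_
        )
      )
      row <- dplyr::mutate(row, scenario = sc_name, rep = r, .before = 1)
      per_rep[[length(per_rep) + 1]] <- row
      if (!is.null(stream)) {
        utils::write.table(row, stream, sep = ",", row.names = FALSE,
                           col.names = !file.exists(stream), append = file.exists(stream),
                           quote = FALSE)
      }
    }
  }
  raw <- dplyr::bind_rows(per_rep)
  target_for <- function(sc_name, test) {
    sc <- scenarios[[sc_name]]
    if (is.null(sc) || is.null(sc$effect_type)) return(NA_real_)
    if (sc$effect_type == "mean" && test == "mean_wald") return(sc$effect_size)
    if (sc$effect_type == "slope" && test == "two_stage_slope") return(sc$effect_size)
    NA_real_
  }
  oc <- raw |>
    dplyr::filter(.data$test != "ALL") |>
    dplyr::group_by(.data$scenario, .data$test) |>
    dplyr::summarise(
      rejection_rate = mean(.data$p < alpha, na.rm = TRUE),
      reps_used = sum(!is.na(.data$p)),
      mean_estimate = mean(.data$estimate, na.rm = TRUE),
      sd_estimate = sd(.data$estimate, na.rm = TRUE),
      mean_n_used = mean(.data$n_used, na.rm = TRUE),
      n_failed = sum(is.na(.data$p)),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      mc_se = sqrt(.data$rejection_rate * (1 - .data$rejection_rate) /
                     pmax(.data$reps_used, 1)),
      target = purrr::map2_dbl(.data$scenario, .data$test, target_for),
      bias = .data$mean_estimate - .data$target,
      rmse = sqrt(.data$bias^2 + .data$sd_estimate^2),
      seed = seed
    )
  fail_all <- raw |>
    dplyr::filter(.data$test == "ALL") |>
    dplyr::count(.data$scenario, name = "n_failed_reps")
  if (nrow(fail_all)) {
    notes <- c(notes, sprintf("scenario %s: %d replicate(s) failed entirely",
                              fail_all$scenario, fail_all$n_failed_reps))
  }
  structure(oc, class = c("operating_characteristics", class(oc)),
            notes = notes, per_rep = raw)
}
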