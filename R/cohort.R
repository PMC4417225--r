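#' Longitudinal exposure cohorts
#'
#' A cohort is a long-format tibble with one row per subject-visit and the
#' columns `subject_id`, `outcome` (binary, constant within subject),
#' `visit` (integer index), `time_days` (gestational days), `exposure`,
#' followed by covariate columns. Covariates are declared either
#' time-varying (measured at each visit, e.g. urinary specific gravity,
#' time of day of sample collection) or baseline (constant within subject,
#' e.g. maternal age, BMI). The object carries its exposure scale
#' (`"raw"` or `"ln"`) so that models can insist on ln-scale input, and a
#' record of covariates already regressed out of the exposure (see
#' [residualize_exposure()]).
#'
#' A missing exposure measurement is an absent row, never an `NA`: each
#' modelling strategy defines its own subject-inclusion rule, so no
#' imputation happens anywhere in the package.
#'
#' @param data a data frame with the columns described above.
#' @param exposure_scale `"raw"` (strictly positive concentrations) or
#'   `"ln"` (natural-log transformed).
#' @param tv_covariates character vector of time-varying covariate columns.
#' @param baseline_covariates character vector of subject-level covariate
#'   columns (must be constant within subject).
#' @param residualized character vector of covariate names already removed
#'   from the exposure by regression (normally set by
#'   [residualize_exposure()], not by hand).
#' @return a `lexp_cohort` tibble.
#' @examples
#' df <- tibble::tibble(
#'   subject_id = rep(c("a", "b"), each = 2), outcome = rep(c(1, 0), each = 2),
#'   visit = c(1, 2, 1, 2), time_days = c(70, 180, 80, 190),
#'   exposure = c(1.2, 2.1, 0.7, 0.9)
#' )
#' as_cohort(df, exposure_scale = "raw")
#' @export
as_cohort <- function(data, exposure_scale = c("raw", "ln"),
                      tv_covariates = character(), baseline_covariates = character(),
                      residualized = character()) {
  exposure_scale <- match.arg(exposure_scale)
  need <- c("subject_id", "outcome", "visit", "time_days", "exposure")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop_input("missing required columns: ", paste(miss, collapse = ", "))
  miss <- setdiff(c(tv_covariates, baseline_covariates), names(data))
  if (length(miss)) stop_input("declared covariates absent from data: ", paste(miss, collapse = ", "))
  df <- tibble::as_tibble(data)[, c(need, tv_covariates, baseline_covariates)]
  df$visit <- as.integer(df$visit)
  out <- tibble::new_tibble(
    df,
    class = "lexp_cohort",
    exposure_scale = exposure_scale,
    tv_covariates = tv_covariates,
    baseline_covariates = baseline_covariates,
    residualized = residualized
  )
  validate_cohort(out)
  out
}

# rebuild a cohort from a plain data frame, inheriting metadata from template
rebuild_cohort <- function(data, template, ...) {
  meta <- list(
    exposure_scale = attr(template, "exposure_scale"),
    tv_covariates = attr(template, "tv_covariates"),
    baseline_covariates = attr(template, "baseline_covariates"),
    residualized = attr(template, "residualized")
  )
  meta <- modifyList(meta, list(...))
  as_cohort(data,
    exposure_scale = meta$exposure_scale, tv_covariates = meta$tv_covariates,
    baseline_covariates = meta$baseline_covariates, residualized = meta$residualized
  )
}

validate_cohort <- function(x) {
  if (!is_binary01(x$outcome)) stop_input("outcome must be coded 0/1")
  if (any(!is.finite(x$time_days)) || any(x$time_days <= 0)) {
    stop_input("time_days must be positive and finite")
  }
  by_subj <- split(seq_len(nrow(x)), x$subject_id)
  for (idx in by_subj) {
    sid <- x$subject_id[idx[1]]
    if (length(unique(x$outcome[idx])) > 1L) {
      stop_input("outcome not constant within subject '", sid, "'")
    }
    v <- x$visit[idx]
    if (anyDuplicated(v)) {
      stop_input("duplicate (subject, visit) pair: subject '", sid,
                 "' visit ", v[anyDuplicated(v)])
    }
    tt <- x$time_days[idx][order(v)]
    if (any(diff(tt) <= 0)) {
      stop_input("observation times not strictly increasing for subject '", sid, "'")
    }
  }
  if (any(x$visit < 1L)) stop_input("visit indices must be >= 1")
  if (identical(attr(x, "exposure_scale"), "raw")) {
    bad <- which(x$exposure <= 0 | !is.finite(x$exposure))
    if (length(bad)) {
      stop_input("non-positive raw exposure in rows: ",
                 paste(head(bad, 10), collapse = ", "))
    }
  } else if (any(!is.finite(x$exposure))) {
    stop_input("non-finite ln exposure present")
  }
  for (bc in attr(x, "baseline_covariates")) {
    n_distinct <- vapply(split(x[[bc]], x$subject_id),
                         function(v) length(unique(v)), integer(1))
    if (any(n_distinct > 1L)) {
      stop_input("baseline covariate '", bc, "' varies within subject")
    }
  }
  invisible(x)
}

#' @export
print.lexp_cohort <- function(x, ...) {
  cat(sprintf(
    "<lexp_cohort> %d subjects, %d observations, scale=%s\n",
    length(unique(x$subject_id)), nrow(x), attr(x, "exposure_scale")
  ))
  if (length(attr(x, "residualized"))) {
    cat("  exposure residualized on:",
        paste(attr(x, "residualized"), collapse = ", "), "\n")
  }
  NextMethod()
}

#' Number of visits in the cohort design
#' @param cohort a [as_cohort()] object.
#' @return integer, the largest visit index present.
#' @export
n_visits <- function(cohort) max(cohort$visit)

#' Per-subject summary of a cohort
#' @param cohort a cohort.
#' @return tibble with one row per subject: outcome, number of visits, and
#'   baseline covariates.
#' @export
cohort_subjects <- function(cohort) {
  bc <- attr(cohort, "baseline_covariates")
  dplyr::distinct(
    tibble::as_tibble(cohort)[, c("subject_id", "outcome", bc)]
  ) |>
    dplyr::left_join(
      dplyr::count(tibble::as_tibble(cohort), .data$subject_id, name = "n_visits"),
      by = "subject_id"
    )
}

#' Read a long-format cohort CSV
#'
#' Expects a header row and, by default, the columns `subject_id`,
#' `outcome`, `visit`, `time_days`, `exposure`. A schema list can remap
#' column names and declare covariate roles.
#'
#' Rows with missing exposure are dropped (with a message reporting the
#' count); subjects left with no visits are dropped with a warning.
#'
#' @param path CSV path.
#' @param schema optional list with elements `columns` (named character
#'   vector mapping standard names to file columns), `tv_covariates`,
#'   `baseline_covariates`, `categorical` (columns to read as factors), and
#'   `exposure_scale`. May also be a path to a YAML file with those keys.
#' @return a cohort.
#' @seealso [write_cohort_long()] for the inverse.
#' @export
read_cohort_long <- function(path, schema = NULL) {
  if (is.character(schema)) schema <- yaml::read_yaml(schema)
  schema <- schema %||% list()
  cols <- c(
    subject_id = "subject_id", outcome = "outcome", visit = "visit",
    time_days = "time_days", exposure = "exposure"
  )
  if (!is.null(schema$columns)) cols[names(schema$columns)] <- unlist(schema$columns)
  raw <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(unname(cols), names(raw))
  if (length(miss)) stop_input("file lacks required columns: ", paste(miss, collapse = ", "))
  for (std in names(cols)) names(raw)[names(raw) == cols[[std]]] <- std
  for (cc in schema$categorical %||% character()) raw[[cc]] <- factor(raw[[cc]])
  n_missing <- sum(is.na(raw$exposure))
  if (n_missing > 0) {
    inform(sprintf("dropping %d rows with missing exposure", n_missing))
    raw <- raw[!is.na(raw$exposure), , drop = FALSE]
  }
  if (!nrow(raw)) warn("no rows with observed exposure remain")
  as_cohort(raw,
    exposure_scale = schema$exposure_scale %||% "raw",
    tv_covariates = schema$tv_covariates %||% character(),
    baseline_covariates = schema$baseline_covariates %||% character()
  )
}

#' Write a cohort to a long-format CSV
#' @param cohort a cohort.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort_long <- function(cohort, path) {
  write.csv(tibble::as_tibble(cohort), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Natural-log transform the exposure
#'
#' Biomarker concentrations are right-skewed; all models in this package
#' work on the natural-log scale.
#'
#' @param cohort a raw-scale cohort with strictly positive exposures.
#' @return the cohort with `exposure` replaced by `log(exposure)` and the
#'   scale flag set to `"ln"`.
#' @export
ln_transform <- function(cohort) {
  if (identical(attr(cohort, "exposure_scale"), "ln")) {
    stop_input("exposure already transformed to ln scale")
  }
  bad <- which(cohort$exposure <= 0)
  if (length(bad)) {
    stop_input("cannot ln-transform non-positive exposures in rows: ",
               paste(head(bad, 10), collapse = ", "))
  }
  df <- tibble::as_tibble(cohort)
  df$exposure <- log(df$exposure)
  rebuild_cohort(df, cohort, exposure_scale = "ln")
}

#' Replace the exposure by residuals from a covariate regression
#'
#' Two-step adjustment strategy: regress ln-exposure on the named
#' covariates by pooled least squares over all subject-visits and carry the
#' residuals forward as the exposure. Downstream models then omit those
#' covariates (the cohort records them in its `residualized` attribute).
#'
#' @param cohort an ln-scale cohort.
#' @param covariate_names covariates (time-varying and/or baseline) to
#'   regress out; the empty vector is the identity operation.
#' @return the cohort with residualized exposure.
#' @export
residualize_exposure <- function(cohort, covariate_names) {
  if (!identical(attr(cohort, "exposure_scale"), "ln")) {
    stop_input("residualize_exposure expects an ln-scale cohort")
  }
  if (!length(covariate_names)) return(cohort)
  miss <- setdiff(covariate_names, names(cohort))
  if (length(miss)) stop_input("unknown covariates: ", paste(miss, collapse = ", "))
  df <- tibble::as_tibble(cohort)
  X <- model.matrix(
    as.formula(paste("~", paste(covariate_names, collapse = "+"))), df
  )
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop_cols <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop_input("rank-deficient adjustment design; collinear columns: ",
               paste(drop_cols, collapse = ", "))
  }
  df$exposure <- as.numeric(qr.resid(qrX, df$exposure))
  rebuild_cohort(df, cohort,
                 residualized = union(attr(cohort, "residualized"), covariate_names))
}

#' Exposure matrix aligned by visit index
#'
#' Several strategies (the simultaneous logistic model, the Gaussian
#' mixture) need the exposures as an N x n_max matrix aligned by visit.
#'
#' @param cohort a cohort.
#' @param require_complete keep only subjects observed at every visit.
#' @return a list with `exposure` (matrix, `NA` for unobserved cells),
#'   `observed` (logical mask), and `subjects` (tibble of subject_id,
#'   outcome and baseline covariates, one row per matrix row).
#' @export
pivot_exposure_wide <- function(cohort, require_complete = FALSE) {
  nm <- n_visits(cohort)
  wide <- tidyr::pivot_wider(
    tibble::as_tibble(cohort)[, c("subject_id", "visit", "exposure")],
    names_from = "visit", values_from = "exposure",
    names_prefix = "v", names_sort = TRUE
  )
  # ensure every visit column 1..n_max exists even if a visit index is empty
  for (j in seq_len(nm)) {
    cn <- paste0("v", j)
    if (!cn %in% names(wide)) wide[[cn]] <- NA_real_
  }
  wide <- wide[, c("subject_id", paste0("v", seq_len(nm)))]
  mat <- as.matrix(wide[, -1])
  rownames(mat) <- wide$subject_id
  keep <- rep(TRUE, nrow(mat))
  if (require_complete) keep <- stats::complete.cases(mat)
  if (!any(keep)) warn("no subjects satisfy the completeness requirement")
  subjects <- cohort_subjects(cohort)
  subjects <- subjects[match(wide$subject_id[keep], subjects$subject_id), ]
  list(
    exposure = mat[keep, , drop = FALSE],
    observed = !is.na(mat[keep, , drop = FALSE]),
    subjects = subjects
  )
}

#' Within-subject reproducibility of the exposure (ICC)
#'
#' Fits a random-intercept-only mixed model to the ln exposure (intercept
#' as the sole fixed effect) and reports the intraclass correlation
#' ICC = sigma_b^2 / (sigma_b^2 + sigma_e^2), the share of total variance
#' attributable to between-subject differences. A biomarker with low ICC
#' (e.g. 0.30) is poorly reproducible within subject; one near 0.57 is
#' moderately stable. The confidence interval is a nonparametric bootstrap
#' over subjects, since no closed form is assumed.
#'
#' @param cohort an ln-scale cohort with at least two subjects having two
#'   or more visits.
#' @param B number of bootstrap resamples for the CI (0 skips the CI).
#' @param seed seed for the bootstrap.
#' @param conf confidence level.
#' @return an `icc_estimate` tibble with columns `icc`, `between_var`,
#'   `within_var`, `ci_low`, `ci_high`.
#' @export
cohort_icc <- function(cohort, B = 500, seed = 1, conf = 0.95) {
  if (!identical(attr(cohort, "exposure_scale"), "ln")) {
    stop_input("cohort_icc expects an ln-scale cohort")
  }
  df <- tibble::as_tibble(cohort)
  nvis <- table(df$subject_id)
  if (sum(nvis >= 2) < 2) {
    stop_input("within-subject variance unidentifiable: need >= 2 subjects with >= 2 visits")
  }
  point <- icc_point(df)
  ci <- c(NA_real_, NA_real_)
  if (B > 0) {
    ids <- unique(df$subject_id)
    split_df <- split(df, df$subject_id)
    boots <- with_seed(seed, vapply(seq_len(B), function(b) {
      take <- sample(ids, length(ids), replace = TRUE)
      # re-key drawn subjects so duplicates stay distinct subjects
      dd <- dplyr::bind_rows(
        setNames(split_df[take], sprintf("b%05d", seq_along(take))),
        .id = ".draw"
      )
      dd$subject_id <- dd$.draw
      tryCatch(icc_point(dd)[["icc"]], error = function(e) NA_real_)
    }, numeric(1)))
    alpha <- (1 - conf) / 2
    ci <- unname(quantile(boots, c(alpha, 1 - alpha), na.rm = TRUE))
    # percentile intervals can miss the point estimate at small B; clip so
    # the reported interval always brackets it
    ci <- c(min(ci[1], point[["icc"]]), max(ci[2], point[["icc"]]))
  }
  tibble::new_tibble(
    tibble::tibble(
      icc = point[["icc"]], between_var = point[["between"]],
      within_var = point[["within"]], ci_low = ci[1], ci_high = ci[2]
    ),
    class = "icc_estimate"
  )
}

icc_point <- function(df) {
  fit <- suppressWarnings(suppressMessages(lme4::lmer(
    exposure ~ 1 + (1 | subject_id), data = df, REML = TRUE,
    control = lme4::lmerControl(check.conv.singular = "ignore")
  )))
  vc <- as.data.frame(lme4::VarCorr(fit))
  between <- vc$vcov[vc$grp == "subject_id"]
  within <- vc$vcov[vc$grp == "Residual"]
  c(icc = between / (between + within), between = between, within = within)
}

#' Pairwise between-visit correlation of the exposure
#'
#' Pearson correlations of ln exposure between every pair of visits, each
#' computed on the subjects observed at both visits (pairwise-complete).
#' Under an exchangeable within-subject correlation structure every
#' off-diagonal entry estimates the ICC.
#'
#' @param cohort a cohort.
#' @param min_pairs smallest number of common subjects for which a
#'   correlation is reported; sparser pairs are `NA`.
#' @return symmetric `n_max` x `n_max` correlation matrix.
#' @export
visit_correlations <- function(cohort, min_pairs = 3) {
  wide <- pivot_exposure_wide(cohort, require_complete = FALSE)$exposure
  nm <- ncol(wide)
  out <- diag(1, nm)
  dimnames(out) <- list(paste0("visit", 1:nm), paste0("visit", 1:nm))
  for (j in seq_len(nm - 1)) {
    for (k in (j + 1):nm) {
      ok <- !is.na(wide[, j]) & !is.na(wide[, k])
      out[j, k] <- out[k, j] <-
        if (sum(ok) >= min_pairs) cor(wide[ok, j], wide[ok, k]) else NA_real_
    }
  }
  out
}
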