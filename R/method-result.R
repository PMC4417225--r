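#' Uniform result container for the modelling strategies
#'
#' Every strategy returns a `method_result` so that results can be
#' compared, tabulated and serialized uniformly: a tidy `estimates` table
#' (coefficient, SE, OR with 95% CI, Wald p per exposure term), an
#' optional `global_tests` table (statistic, df, p), the number of
#' subjects actually used, and free-text notes recording demotions,
#' fallbacks and stability warnings.
#'
#' @param method method label.
#' @param estimates tibble with columns term, estimate, se, or, ci_low,
#'   ci_high, p.
#' @param global_tests tibble with columns test, statistic, df, p (or NULL).
#' @param n_used number of subjects used.
#' @param notes character vector of caveats.
#' @param extra named list of method-specific payload (fits, clusterings).
#' @return a `method_result`.
#' @keywords internal
method_result <- function(method, estimates, global_tests = NULL, n_used,
                          notes = character(), extra = list()) {
  stopifnot(all(c("term", "estimate", "se", "or", "ci_low", "ci_high", "p")
                %in% names(estimates)))
  structure(list(
    method = method, estimates = estimates,
    global_tests = global_tests %||%
      tibble::tibble(test = character(), statistic = numeric(),
                     df = numeric(), p = numeric()),
    n_used = n_used, notes = notes, extra = extra
  ), class = "method_result")
}

#' @export
print.method_result <- function(x, ...) {
  cat(sprintf("<method_result: %s> n_used=%d\n", x$method, x$n_used))
  print(x$estimates)
  if (nrow(x$global_tests)) {
    cat("global tests:\n")
    print(x$global_tests)
  }
  if (length(x$notes)) cat("notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

#' Tidy and summarize fitted objects
#'
#' Broom-style accessors: `tidy()` returns the per-term estimates table,
#' `glance()` a one-row model summary.
#'
#' @param x a fitted object from this package.
#' @param ... unused.
#' @return a tibble.
#' @name tidiers
NULL

#' @export
#' @rdname tidiers
tidy.method_result <- function(x, ...) {
  dplyr::mutate(x$estimates, method = x$method, .before = 1)
}

#' @export
#' @rdname tidiers
glance.method_result <- function(x, ...) {
  gt <- x$global_tests
  tibble::tibble(
    method = x$method, n_used = x$n_used,
    n_terms = nrow(x$estimates),
    min_p = if (nrow(x$estimates)) min(x$estimates$p, na.rm = TRUE) else NA_real_,
    global_test = if (nrow(gt)) gt$test[1] else NA_character_,
    global_p = if (nrow(gt)) gt$p[1] else NA_real_,
    n_notes = length(x$notes)
  )
}

#' Forest-style plot of a method's odds ratios
#' @param object a `method_result`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.method_result <- function(object, ...) {
  ggplot2::ggplot(object$estimates,
                  ggplot2::aes(.data$or, .data$term)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high), height = 0.2
    ) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "odds ratio (95% CI)", y = NULL, title = object$method)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

# ---- shared design helpers -------------------------------------------------

active_tv <- function(cohort) {
  setdiff(attr(cohort, "tv_covariates"), attr(cohort, "residualized"))
}

active_baseline <- function(cohort) {
  setdiff(attr(cohort, "baseline_covariates"), attr(cohort, "residualized"))
}

# model matrix from named columns of `data`; factors dummy-coded
build_design <- function(data, cols = character(), intercept = TRUE) {
  X <- if (length(cols)) {
    model.matrix(as.formula(paste("~", paste(cols, collapse = "+"))),
                 as.data.frame(data))[, -1, drop = FALSE]
  } else {
    matrix(numeric(0), nrow(as.data.frame(data)), 0)
  }
  if (intercept) X <- cbind("(Intercept)" = rep(1, nrow(X)), X)
  X
}

wald_row <- function(fit, terms, conf = 0.95) {
  td <- tidy_glm(fit, conf)
  td[td$term %in% terms, , drop = FALSE]
}
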