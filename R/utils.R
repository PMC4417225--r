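#' @importFrom rlang %||% .data abort warn inform
#' @importFrom stats as.formula binomial coef glm lm logLik model.matrix
#'   pchisq plogis pnorm predict qlogis qnorm quantile resid rnorm runif
#'   rbinom sd setNames var vcov kmeans chisq.test fisher.test cor optim
#'   complete.cases approx dnorm median fitted p.adjust terms lm.wfit
#' @importFrom utils head read.csv write.csv modifyList
NULL

expit <- function(x) plogis(x)

#' Evaluate code with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded internals (k-means
#' restarts, bootstraps, simulation reps) do not disturb the caller's RNG
#' stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(seed)
  force(code)
}

# Mix a base seed with a replicate index, staying inside 32-bit integer range.
mix_seed <- function(seed, r) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(r) * 104729) %% 2147483647L)
}

stop_input <- function(...) abort(paste0(...), class = "longexpo_error")

is_binary01 <- function(x) all(x %in% c(0, 1))
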