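#' @keywords internal
"_PACKAGE"

#' @importFrom stats aggregate as.formula binomial chisq.test coef glm logLik
#'   na.omit pchisq plogis pnorm predict qnorm quantile rbinom rnorm runif sd
#'   t.test update var vcov AIC
#' @importFrom utils read.csv write.csv packageVersion modifyList
NULL

# Deterministic per-stage substreams derived from one user-facing seed.
# Stage names hash to an offset so that, e.g., attrition draws do not shift
# when the number of participants changes the cohort stream's consumption.
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)) * 2654435761) %% 1000003
  as.integer((abs(as.numeric(seed)) * 7919 + h) %% 2147483647L)
}

with_stage_seed <- function(seed, stage, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(stage_seed(seed, stage))
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  force(expr)
}

# round half away from zero (R's round() rounds half to even)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) {
  stop(structure(
    class = c("drs_config_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

assert_prob <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop_config(what, " must be a probability in [0, 1]")
  }
  invisible(x)
}
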