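#' @importFrom rlang abort warn inform %||% .data
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   left_join inner_join anti_join bind_rows bind_cols rename n across
#'   distinct pull row_number all_of
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom stats median qt pt setNames lm coef wilcox.test p.adjust cor
#'   rnorm rlnorm runif quantile t.test complete.cases
#' @importFrom utils head tail
#' @importFrom Rcpp sourceCpp
#' @useDynLib intronarray, .registration = TRUE
NULL

# Shared error conditions: "invalid input" for bad arguments/config,
# "validation" for data that breaks a structural invariant.
stop_invalid <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "intronarray_invalid_input")
}

stop_validation <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "intronarray_validation_error")
}

assert_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max) {
    stop_invalid("`%s` must be a single number in [%s, %s]", name, min, max)
  }
  invisible(x)
}

# Deterministic child seeds: derive per-stage streams from one master seed so
# that independent stages do not share a random state.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(offset) * 104729) %% 2147483629)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
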