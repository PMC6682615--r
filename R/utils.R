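# Internal helpers shared across modules.

#' @importFrom rlang abort warn inform
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr %>%
NULL

# Stop with a classed condition so callers/tests can match on class.
stop_spatgeno <- function(msg, class = "spatgeno_error", ...) {
  rlang::abort(msg, class = c(class, "spatgeno_error"), ...)
}

assert_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_spatgeno(sprintf("`%s` must be a single finite number", name),
                  class = "spatgeno_invalid_input")
  }
  if (x < min || x > max) {
    stop_spatgeno(sprintf("`%s` must be in [%s, %s], got %s", name, min, max, x),
                  class = "spatgeno_invalid_input")
  }
  invisible(x)
}

# Canonical unordered pair: lexicographically smaller id first.
canonical_pair <- function(a, b) {
  swap <- a > b
  tmp <- a[swap]
  a[swap] <- b[swap]
  b[swap] <- tmp
  list(a = a, b = b)
}

# Deterministic child seed from (master seed, index); stays below 2^31.
child_seed <- function(seed, index) {
  as.integer((as.double(seed) * 7919 + as.double(index) * 104729) %% 2147483629)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
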