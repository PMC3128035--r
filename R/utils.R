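#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor loess loess.control median predict pt quantile rexp
#'   rnorm runif sd setNames var mad hclust
#' @importFrom utils read.delim write.table head
NULL

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("degrank_config_error", "error")))
}

stop_input <- function(...) {
  stop(errorCondition(paste0(...), class = c("degrank_input_error", "error")))
}

assert_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_config(name, " must be a single finite number")
  if (x < min || x > max)
    stop_config(name, " must be in [", min, ", ", max, "]")
  invisible(x)
}

assert_count <- function(x, name, min = 0L) {
  assert_scalar_number(x, name, min = min)
  if (x != round(x)) stop_config(name, " must be an integer")
  invisible(as.integer(x))
}

# Deterministic sub-seed derivation: a fixed LCG step keyed by stream index,
# independent of the global RNG state.  Result always in [1, 2^31 - 2].
derive_seed <- function(master, stream) {
  m <- 2147483647
  x <- (as.double(master) %% m)
  for (k in c(stream, 104729L)) {
    x <- (x * 48271 + as.double(k)) %% m
  }
  as.integer(x %% (m - 1)) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
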