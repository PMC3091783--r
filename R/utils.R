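#' @importFrom rlang .data abort warn inform %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

# Internal: stop with a classed condition so callers/tests can target errors.
stop_dister <- function(msg, class = "dister_error", ...) {
  rlang::abort(msg, class = c(class, "dister_error"), ...)
}

# Internal: check a scalar probability.
check_prob <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop_dister(sprintf("`%s` must be a single probability in [0, 1], got %s.",
                        what, paste(format(x), collapse = ", ")),
                class = "dister_domain_error")
  }
  invisible(x)
}

utils::globalVariables(".")
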