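# Classed error conditions so callers and tests can distinguish failure modes
# without matching on message text.

ftl_stop <- function(message, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "ftl_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

assert_fraction <- function(x, name, max = 1) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 || x > max) {
    ftl_stop(
      sprintf("`%s` must be a single finite number in [0, %g], got %s",
              name, max, deparse(x)),
      "ftl_domain_error"
    )
  }
  invisible(x)
}

assert_count <- function(x, name, min = 0) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min) {
    ftl_stop(
      sprintf("`%s` must be a single finite number >= %g, got %s",
              name, min, deparse(x)),
      "ftl_domain_error"
    )
  }
  invisible(x)
}
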