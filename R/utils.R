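# Nearest-integer rounding with halves away from zero (for nonnegative
# inputs), used for pool counts and point values so discretization never
# depends on IEEE round-half-even.
round_half_up <- function(x) floor(x + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a

check_scalar_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop("`", name, "` must be a single positive, finite number.",
      call. = FALSE
    )
  }
  invisible(x)
}
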