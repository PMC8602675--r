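#' Round half away from zero
#'
#' Rounds to a fixed number of decimals with halves carried away from zero,
#' the convention used when comparing computed quantities against numbers
#' printed to a fixed precision. Base [round()] uses round-half-to-even,
#' which disagrees on exact halves (e.g. `round(0.5) == 0`).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 1).
#' @return Numeric vector rounded half away from zero.
#' @examples
#' round_half_up(33.65, 1) # 33.7
#' round_half_up(-0.45, 1) # -0.5
#' @export
round_half_up <- function(x, digits = 1) {
  stopifnot(is.numeric(x), is.numeric(digits), length(digits) == 1)
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# Internal: stop with a consistent error class so callers/tests can match on
# the offending field rather than on message wording.
ab_stop <- function(msg, class, ...) {
  rlang::abort(msg, class = c(class, "airburden_error"), ...)
}

assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    ab_stop(sprintf("`%s` must be a single finite number.", name),
            "airburden_argument_error")
  }
  invisible(x)
}
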