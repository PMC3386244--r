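# Shared internal helpers.

#' Round half away from zero
#'
#' Printed tables in the source experiments round .5 up (e.g. a female mating
#' share of 0.525 prints as 0.53), unlike base [round()], which rounds half to
#' even. All report-stage rounding in this package goes through this helper;
#' computations keep full precision.
#'
#' @param x numeric vector.
#' @param digits integer, decimal places.
#' @return numeric vector rounded half-up.
#' @export
#' @examples
#' round_half_up(0.525, 2) # 0.53, where round(0.525, 2) gives 0.52
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Derive a child seed from a base seed and an index
#'
#' Deterministic stream splitting used throughout the package (per-replicate
#' seeds, per-grid-cell seeds): maps a base seed and an index to a value usable
#' by [set.seed()]. Results stay below 2^31 - 1 and the arithmetic is exact in
#' doubles, so identical inputs give identical seeds on any platform.
#'
#' @param base integer base seed.
#' @param index integer stream index.
#' @return a single integer seed.
#' @export
derive_seed <- function(base, index) {
  as.integer(((as.double(base) %% 1000003) * 10007 +
                (as.double(index) %% 1000003) * 7919 + 1) %% 2147483587)
}

# Classed conditions so callers can distinguish failure modes programmatically.
abort <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "introgressim_error", "error"),
                      call = sys.call(-1)))
}

abort_extinction <- function(msg, survivors = NULL) {
  stop(errorCondition(msg,
                      class = c("extinction_error", "introgressim_error", "error"),
                      survivors = survivors))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == trunc(x)
}

stopifnot_proportion <- function(x, name, upper = 1) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > upper) {
    abort(sprintf("`%s` must be a single value in [0, %s], got %s",
                  name, format(upper), deparse(x)),
          "validation_error")
  }
  invisible(x)
}
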