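#' Round half away from zero
#'
#' Clinical tables round 5 up, unlike [round()]'s round-half-even. A small
#' relative guard absorbs values stored one ULP below the .5 boundary
#' (e.g. `0.03945` at 4 decimals).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded half-up (half away from zero).
#' @export
#' @examples
#' round_half_up(0.44885, 4)  # 0.4489
#' round_half_up(44.5, 0)     # 45
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# Evaluate expr under a private RNG stream: seeds, runs, then restores
# whatever global .Random.seed existed before. All package randomness
# funnels through here so no call leaks RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(expr)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

# scalar checks used throughout the constructors
assert_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    stopf("'%s' must be a single number in [%g, %g]", name, lower, upper)
  }
  invisible(x)
}
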