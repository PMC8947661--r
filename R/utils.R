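#' Round half away from zero
#'
#' Decimal rounding in which ties go away from zero (600.5 -> 601), the
#' convention used on clinical validation reports, as opposed to base R's
#' IEEE half-to-even. A tiny relative tolerance absorbs binary
#' representation error in decimal ties.
#'
#' @param x numeric vector.
#' @param digits integer, decimal places.
#' @return numeric vector rounded to `digits` places.
#' @export
#' @examples
#' round_half_up(600.5, 0)  # 601, not 600
round_half_up <- function(x, digits = 0) {
  stopifnot(is.numeric(x), length(digits) == 1L, digits >= 0)
  z <- abs(x) * 10^digits
  sign(x) * floor(z + 0.5 + 1e-9 * pmax(1, z)) / 10^digits
}

#' Fixed-decimal display string
#'
#' @param x numeric vector.
#' @param digits decimal places shown.
#' @return character vector, half-away-from-zero rounded.
#' @export
fmt_fixed <- function(x, digits = 0) {
  formatC(round_half_up(x, digits), format = "f", digits = digits)
}

# Evaluate `code` under `seed` without disturbing the caller's RNG stream.
# All package randomness flows through here: seeds are explicit arguments,
# never global state.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministic sub-seed from a base seed and an integer offset, kept inside
# 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1021 + as.numeric(offset)) %% 2147483647)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == floor(x)
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

`%||%` <- function(a, b) if (is.null(a)) b else a
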