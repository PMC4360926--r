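# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Rounds to the nearest integer with ties going away from zero, the
#' convention used when reconstructing death counts from printed
#' percentages (e.g. 14.25 -> 14, 12.96 -> 13, 0.5 -> 1).
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @export
#' @examples
#' round_half_away(c(0.5, 1.5, -0.5, 14.25, 12.96))
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
# afterwards so library functions never perturb user-level randomness.
with_seed <- function(seed, code) {
  code <- substitute(code)
  orig <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(orig)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", orig, envir = globalenv())
    }
  })
  set.seed(seed)
  eval(code, parent.frame())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
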