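## Internal helpers shared across modules.

#' @importFrom stats rnorm rpois rnbinom rgamma rmultinom runif rlnorm sd lm coef
#' @importFrom utils head
NULL

#' Evaluate an expression under a fixed RNG seed
#'
#' Saves and restores the caller's RNG state so generators are
#' deterministic without clobbering the session stream.
#' @noRd
withSeed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Round half away from zero (printed-table convention)
#'
#' Base `round()` rounds half to even; published percentage tables round
#' half up, so 74.65 prints as 74.7.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @examples
#' roundHalfUp(74.65, 1)  # 74.7, where round() gives 74.6
#' @export
roundHalfUp <- function(x, digits = 1L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

assertScalarNumeric <- function(x, name, lower = -Inf, upper = Inf,
                                allow_inf = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      (!allow_inf && !is.finite(x)))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  if (x < lower || x > upper)
    stop(sprintf("'%s' must be in [%s, %s]", name, lower, upper),
         call. = FALSE)
  invisible(x)
}

assertCount <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != as.integer(x) ||
      x < min)
    stop(sprintf("'%s' must be an integer >= %d", name, min), call. = FALSE)
  invisible(as.integer(x))
}

## reverse complement for plain character vectors (thin Biostrings wrapper)
revComp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
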