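#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded package internals do
#' not perturb the caller's random number stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Derive a per-stage seed from a global seed
#'
#' Deterministic and independent of which other stages run, so toggling
#' unrelated stages does not shift a stage's randomness. Kept below 2^31.
#'
#' @param global_seed integer global seed.
#' @param stage stage name.
#' @return integer seed.
#' @export
stage_seed <- function(global_seed, stage) {
  stopifnot(is.numeric(global_seed), length(global_seed) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(global_seed) * 7919 + h * 104729) %% 2147483629L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round a fraction the way report percentages are printed
#'
#' @param num,den numerator and denominator counts.
#' @param digits decimal digits to keep (0 for whole percent).
#' @return percentage, rounded.
#' @export
#' @examples
#' summarize_fractions(10532, 14385)  # 73
#' summarize_fractions(404, 2846)     # 14
summarize_fractions <- function(num, den, digits = 0) {
  stopifnot(length(num) == length(den))
  out <- ifelse(den > 0, round(100 * num / den, digits), NA_real_)
  names(out) <- names(num)
  out
}
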