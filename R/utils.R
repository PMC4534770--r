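`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded helpers never perturb the
#' caller's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Derive a per-stage seed from a master seed
#'
#' Each pipeline stage draws from its own stream, derived from the master
#' seed and the stage name, so adding or skipping a stage never perturbs
#' the draws of the others.
#'
#' @param seed master integer seed.
#' @param stage stage name (character scalar).
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  codes <- utf8ToInt(stage)
  h <- sum(codes * seq_along(codes))
  as.integer((abs(as.numeric(seed)) + 10007 * h) %% 2147483629)
}

# Round a vector of nonnegative real targets to integers that sum to
# `total`, by the largest-remainder rule. Deterministic; ties broken by
# position.
largest_remainder <- function(weights, total) {
  stopifnot(all(weights >= 0), sum(weights) > 0, total >= 0)
  exact <- weights / sum(weights) * total
  base <- floor(exact)
  short <- total - sum(base)
  if (short > 0) {
    ord <- order(exact - base, decreasing = TRUE)
    base[ord[seq_len(short)]] <- base[ord[seq_len(short)]] + 1
  }
  as.integer(base)
}
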