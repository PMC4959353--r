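# Internal helpers shared across modules.

#' Evaluate an expression under a fixed RNG seed
#'
#' Runs `expr` with the RNG seeded to `seed` and restores the caller's
#' RNG state afterwards.  All stochastic code in the package funnels
#' through this, so results are reproducible from explicit seeds only
#' and never disturb (or depend on) the global random stream.
#'
#' @param seed a single finite number, used via [set.seed()].
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("'seed' must be a single finite number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
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
  set.seed(as.integer(seed))
  expr
}

# Pearson correlation with the degenerate-case convention used throughout:
# a zero-variance argument yields correlation 0 rather than NA.
safe_cor <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 2L) return(0)
  sx <- stats::sd(x)
  sy <- stats::sd(y)
  if (sx == 0 || sy == 0) return(0)
  stats::cor(x, y)
}

# Full-precision numeric formatting for text serialization (round-trips
# doubles exactly through read.table).
fmt_num <- function(x) sprintf("%.17g", x)

`%||%` <- function(a, b) if (is.null(a)) b else a
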