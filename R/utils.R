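## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores the caller's RNG state so that seeded package
#' internals never perturb user-level random streams.
#'
#' @param seed integer seed
#' @param expr expression to evaluate
#' @return value of `expr`
#' @keywords internal
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

## lower median of a numeric multiset: element ceiling(n/2) of the sorted
## values, so an actual observation is always returned.
lower_median <- function(x) {
  n <- length(x)
  if (n == 0L) return(NA_real_)
  sort(x, partial = ceiling(n / 2))[ceiling(n / 2)]
}

## Strand-oriented window around an anchor position (0-based, half-open).
## "up" bases upstream and "down" bases downstream of (and including) the
## anchor, where upstream means 5' of the anchor on the given strand.
oriented_window <- function(anchor, strand, up, down) {
  stopifnot(strand %in% c("+", "-"))
  if (strand == "+") {
    c(start = anchor - up, end = anchor + down)
  } else {
    c(start = anchor - down + 1L, end = anchor + up + 1L)
  }
}

## entropy (bits) of a probability vector; 0 * log 0 := 0
entropy_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

stop_procapr <- function(...) stop(..., call. = FALSE)
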