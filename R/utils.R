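`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so package functions taking an explicit
#' `seed` argument never leak state into (or depend on) the caller's RNG.
#'
#' @param seed Integer seed, or `NULL` to use the current RNG stream.
#' @param code Code to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

## Derive a stream seed from a master seed; kept below 2^31.
derive_seed <- function(seed, i) {
  as.integer((as.double(seed) * 48271 + i * 16807) %% 2147483629)
}

## Plain (unfitted) coordinate RMSD between two N x 3 matrices.
rmsd_coords <- function(a, b) {
  stopifnot(all(dim(a) == dim(b)))
  sqrt(mean(rowSums((a - b)^2)))
}

## Scatter-add per-pair force contributions into an N x 3 force matrix.
accumulate_rows <- function(F, idx, contrib) {
  s <- rowsum(contrib, group = idx, reorder = FALSE)
  rows <- as.integer(rownames(s))
  F[rows, ] <- F[rows, ] + s
  F
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
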