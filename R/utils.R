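# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so package functions that take an explicit
#' `seed` argument do not disturb the caller's RNG stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
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
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

#' Derive a child seed from a run seed
#'
#' Fixed affine map modulo 2^31 - 1 so every stochastic stage of a pipeline
#' gets its own reproducible stream from one run seed.
#' @noRd
derive_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 48271 + 7919 * as.double(offset)) %% 2147483647)
}

#' Global field power: standard deviation across channels
#' @param x numeric vector of channel values at one time point.
#' @return scalar standard deviation.
#' @export
gfp <- function(x) stats::sd(x)

#' Common-average reference a channels x time matrix (column-wise demean)
#' @noRd
car_ref <- function(x) {
  if (is.null(dim(x))) return(x - mean(x))
  sweep(x, 2, colMeans(x))
}

#' Pairwise Euclidean distances between two point sets
#' @param a n x 3 matrix.
#' @param b m x 3 matrix.
#' @return n x m distance matrix.
#' @export
pairwise_dist <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  an <- rowSums(a^2); bn <- rowSums(b^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

#' Cheap content fingerprint of a numeric matrix row (leakage checks)
#' @noRd
row_fingerprint <- function(x) {
  apply(round(x, 10), 1, function(r) paste(r, collapse = "|"))
}

unit_rows <- function(x) x / sqrt(rowSums(x^2))
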