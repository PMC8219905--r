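# Source-vector transfer between two source spaces sharing a coordinate
# frame (e.g., AGM simulation grid to GM inversion grid): k-nearest-neighbor
# interpolation with energy renormalization.

#' Precompute a k-nearest-neighbor map between source spaces
#'
#' For each destination vertex, the indices of its `k` nearest source-space
#' vertices by Euclidean distance (ties broken by vertex index).
#'
#' @param src_space,dst_space `source_space` objects in one coordinate frame.
#' @param k number of neighbors (default 5).
#' @return integer matrix p_dst x k.
#' @export
knn_map <- function(src_space, dst_space, k = 5) {
  p_src <- n_dipoles(src_space)
  if (k > p_src) stop("k exceeds the number of source-space vertices")
  d <- pairwise_dist(dst_space$positions, src_space$positions)
  t(apply(d, 1, function(row) order(row)[seq_len(k)]))
}

#' Map a source vector between source spaces
#'
#' Each destination vertex receives the unweighted mean of the values at its
#' `k` nearest source-space vertices; the result is rescaled so the total
#' energy (sum of dipole moments) equals that of the input. An all-zero input
#' maps to zero without rescaling.
#'
#' @param j_src numeric p_src-vector (or `source_activity`) of moments, or a
#'   p_src x t matrix (mapped and renormalized column-wise).
#' @param src_space,dst_space `source_space` objects in one coordinate frame.
#' @param k number of neighbors (default 5).
#' @param map optional precomputed [knn_map()] (recomputed when NULL).
#' @return numeric vector (or matrix) on the destination space.
#' @export
map_sources <- function(j_src, src_space, dst_space, k = 5, map = NULL) {
  j <- if (inherits(j_src, "source_activity")) j_src$moments else j_src
  if (is.null(map)) map <- knn_map(src_space, dst_space, k)
  map_one <- function(v) {
    out <- rowMeans(matrix(v[map], nrow = nrow(map)))
    s_in <- sum(v); s_out <- sum(out)
    if (s_in != 0 && s_out != 0) out * (s_in / s_out) else out
  }
  if (is.null(dim(j))) map_one(j) else apply(j, 2, map_one)
}
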