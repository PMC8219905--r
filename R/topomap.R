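# Scalp topography interpolation: electrodes are projected to 2D by an
# azimuthal-equidistant projection about the vertex (Cz apex) and interpolated
# onto a 7 x 11 pixel lattice with a Gaussian radial-basis interpolant plus a
# constant term (exact at electrodes, reproduces constants). The whole map is
# linear in the channel values, so it is precomputed once per montage as a
# pixels x channels operator.

#' Precompute the topomap interpolation operator for a montage
#'
#' @param montage a `montage`.
#' @param nrow,ncol lattice size (default 7 x 11).
#' @param margin fractional margin of the lattice around the projected
#'   electrode cloud (default 0.05).
#' @return object of class `topo_operator`: `T` ((nrow*ncol) x q matrix),
#'   `mask` (nrow x ncol logical, pixels inside the head disk), projected
#'   electrode and pixel coordinates, lattice size.
#' @export
topomap_operator <- function(montage, nrow = 7, ncol = 11, margin = 0.05) {
  u <- unit_rows(montage$positions)
  theta <- acos(pmin(pmax(u[, 3], -1), 1))
  phi <- atan2(u[, 2], u[, 1])
  e2d <- cbind(theta * cos(phi), theta * sin(phi))
  xr <- max(abs(e2d[, 1])) * (1 + margin)
  yr <- max(abs(e2d[, 2])) * (1 + margin)
  gx <- seq(-xr, xr, length.out = ncol)
  gy <- seq(yr, -yr, length.out = nrow)          # row 1 = front of the head
  px <- cbind(rep(gx, each = nrow), rep(gy, times = ncol))
  # head disk: pixels not farther from the projection origin than the
  # outermost electrode ring (small tolerance)
  rim <- max(sqrt(rowSums(e2d^2))) * (1 + margin)
  mask_vec <- sqrt(rowSums(px^2)) <= rim
  de <- pairwise_dist(cbind(e2d, 0), cbind(e2d, 0))
  h <- stats::median(de[upper.tri(de)]) / 3
  q <- nrow(e2d)
  A <- rbind(cbind(exp(-de^2 / (2 * h^2)) + diag(1e-10, q), rep(1, q)),
             c(rep(1, q), 0))
  B <- cbind(exp(-pairwise_dist(cbind(px, 0), cbind(e2d, 0))^2 / (2 * h^2)),
             rep(1, nrow(px)))
  Tm <- B %*% solve(A)[, seq_len(q)]
  Tm[!mask_vec, ] <- 0
  structure(
    list(T = Tm, mask = matrix(mask_vec, nrow, ncol), electrodes_2d = e2d,
         pixels_2d = px, nrow = nrow, ncol = ncol, bandwidth = h),
    class = "topo_operator"
  )
}

#' Interpolate a scalp vector to a 7 x 11 topographic image
#'
#' Deterministic linear interpolation of the q channel values onto the pixel
#' lattice; pixels outside the head disk are zero. The interpolation adds no
#' information: it is a fixed linear re-arrangement of the channel values into
#' an image the convolutional network can consume.
#'
#' @param m numeric q-vector of potentials (no NAs).
#' @param montage a `montage` (ignored when `op` is given).
#' @param op optional precomputed [topomap_operator()].
#' @return object of class `topo_grid`: `values` (nrow x ncol), `mask`.
#' @export
interpolate_topomap <- function(m, montage = NULL, op = NULL) {
  if (is.null(op)) op <- topomap_operator(montage)
  if (any(!is.finite(m))) stop("non-finite values in the scalp vector")
  v <- matrix(as.vector(op$T %*% m), op$nrow, op$ncol)
  structure(list(values = v, mask = op$mask), class = "topo_grid")
}

#' Plot a topographic map
#' @param x a `topo_grid`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.topo_grid <- function(x, ...) {
  df <- expand.grid(row = seq_len(nrow(x$values)), col = seq_len(ncol(x$values)))
  df$value <- as.vector(x$values)
  df$value[!as.vector(x$mask)] <- NA
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient2(na.value = "grey90") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = "V")
}
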