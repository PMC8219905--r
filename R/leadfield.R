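# Forward model: analytic current-dipole potential in an infinite homogeneous
# medium, followed by common-average referencing. The generative model (GM)
# and a deliberately perturbed alternative generative model (AGM) are kept
# separate so that simulation and inversion never share one forward model
# (the "inverse crime" guard).

#' Compute the leadfield and assemble a head model
#'
#' The gain of a unit dipole at `r_d` with orientation `n_d` (the vertex
#' normal) at electrode `r_e` is the infinite homogeneous-medium potential
#' `phi = (1 / (4 pi sigma)) * n_d . (r_e - r_d) / |r_e - r_d|^3`.
#' Each leadfield column is then common-average referenced (sums to zero
#' across electrodes), matching the referencing applied to simulated data.
#'
#' @param space a `source_space`.
#' @param montage a `montage`; all electrodes must lie strictly outside the
#'   source sphere.
#' @param conductivity tissue conductivity sigma in S/m (default 0.3).
#' @param tag "GM" or "AGM" provenance tag.
#' @param seed optional seed recorded for provenance (set by [perturb_to_agm()]).
#' @return object of class `head_model`: source_space, montage, leadfield
#'   (q x p), conductivity, tag, seed.
#' @export
compute_leadfield <- function(space, montage, conductivity = 0.3,
                              tag = "GM", seed = NULL) {
  pos_s <- space$positions
  pos_e <- montage$positions
  if (min(sqrt(rowSums(pos_e^2))) <= space$radius) {
    stop("electrodes must lie outside the source sphere")
  }
  q <- nrow(pos_e)
  p <- nrow(pos_s)
  K <- matrix(0, q, p)
  for (e in seq_len(q)) {
    d <- sweep(-pos_s, 2, -pos_e[e, ])            # r_e - r_d, p x 3
    r2 <- rowSums(d^2)
    if (any(r2 < 1e-12)) stop("electrode coincides with a source point")
    K[e, ] <- rowSums(d * space$normals) / (r2^1.5 * 4 * pi * conductivity)
  }
  if (any(!is.finite(K))) stop("non-finite leadfield entries")
  K <- sweep(K, 2, colMeans(K))                   # common-average reference
  structure(
    list(source_space = space, montage = montage, leadfield = K,
         conductivity = conductivity, tag = tag, seed = seed),
    class = "head_model"
  )
}

#' @export
print.head_model <- function(x, ...) {
  cat(sprintf("<head_model:%s> %d electrodes x %d dipoles, sigma = %g S/m\n",
              x$tag, nrow(x$leadfield), ncol(x$leadfield), x$conductivity))
  invisible(x)
}

#' Perturb a generative model into an alternative generative model (AGM)
#'
#' Applies the three perturbations that decouple the evaluation forward model
#' from the one used for training/inversion: per-axis Gaussian jitter of the
#' electrode coordinates, a change of tissue conductivity, and a finer source
#' grid (one additional icosahedral subdivision by default), then recomputes
#' the leadfield.
#'
#' @param gm a `head_model` with tag "GM".
#' @param electrode_jitter_sd standard deviation in mm of the independent
#'   Gaussian noise added to each electrode coordinate (default 2).
#' @param conductivity_new conductivity of the perturbed model in S/m
#'   (default 0.332).
#' @param finer_level source-space subdivision level; must exceed the GM level
#'   (default GM level + 1).
#' @param seed RNG seed for the jitter.
#' @return a `head_model` tagged "AGM".
#' @export
perturb_to_agm <- function(gm, electrode_jitter_sd = 2, conductivity_new = 0.332,
                           finer_level = gm$source_space$subdivision_level + 1L,
                           seed = 1L) {
  stopifnot(inherits(gm, "head_model"))
  if (finer_level < gm$source_space$subdivision_level) {
    stop("finer_level must be at least the GM subdivision level")
  }
  pos <- gm$montage$positions
  jit <- with_seed(seed, matrix(stats::rnorm(length(pos), 0, electrode_jitter_sd),
                                nrow = nrow(pos)))
  montage <- structure(list(labels = gm$montage$labels, positions = pos + jit),
                       class = "montage")
  space <- build_source_space(finer_level, radius = gm$source_space$radius)
  compute_leadfield(space, montage, conductivity = conductivity_new,
                    tag = "AGM", seed = seed)
}

#' Save / load a head model container
#'
#' Single-file serialized container holding the leadfield, source space,
#' montage and provenance attributes.
#' @param model a `head_model`.
#' @param path file path (conventionally `.rds`).
#' @export
save_head_model <- function(model, path) {
  stopifnot(inherits(model, "head_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_head_model
#' @export
load_head_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "head_model"))
  model
}
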