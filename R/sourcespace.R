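# Source space: two hemispherical caps of a sphere, each meshed by a
# recursively subdivided icosahedron mapped onto the cap. Adjacency never
# crosses the midline, mirroring the topology of the two cortical sheets.

# Base icosahedron (unit sphere), pre-rotated by a fixed generic rotation so
# that no vertex of any subdivision level falls exactly on the +-x axis where
# the cap mapping is singular.
icosahedron <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  v <- unit_rows(v)
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  a1 <- 0.41; a2 <- 0.23
  rz <- rbind(c(cos(a1), -sin(a1), 0), c(sin(a1), cos(a1), 0), c(0, 0, 1))
  ry <- rbind(c(cos(a2), 0, sin(a2)), c(0, 1, 0), c(-sin(a2), 0, cos(a2)))
  list(vertices = v %*% t(rz %*% ry), faces = f)
}

# One loop of midpoint subdivision with re-projection to the unit sphere.
subdivide_once <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  nv <- nrow(v)
  midpoint_key <- function(i, j) paste0(pmin(i, j), "_", pmax(i, j))
  cache <- new.env(parent = emptyenv())
  verts <- vector("list", nv + 3L * nrow(f))
  for (i in seq_len(nv)) verts[[i]] <- v[i, ]
  nxt <- nv
  getmid <- function(i, j) {
    key <- midpoint_key(i, j)
    idx <- cache[[key]]
    if (!is.null(idx)) return(idx)
    m <- (v[i, ] + v[j, ]) / 2
    m <- m / sqrt(sum(m^2))
    nxt <<- nxt + 1L
    verts[[nxt]] <<- m
    cache[[key]] <- nxt
    nxt
  }
  newf <- matrix(0L, nrow = 4L * nrow(f), ncol = 3)
  for (t in seq_len(nrow(f))) {
    a <- f[t, 1]; b <- f[t, 2]; c <- f[t, 3]
    ab <- getmid(a, b); bc <- getmid(b, c); ca <- getmid(c, a)
    newf[(t - 1L) * 4L + 1:4, ] <- rbind(
      c(a, ab, ca), c(b, bc, ab), c(c, ca, bc), c(ab, bc, ca)
    )
  }
  list(vertices = do.call(rbind, verts[seq_len(nxt)]), faces = newf)
}

icosphere <- function(level) {
  mesh <- icosahedron()
  for (i in seq_len(level)) mesh <- subdivide_once(mesh)
  mesh
}

# Map a full unit sphere onto the spherical cap x > 0 by halving the polar
# angle measured from the +x axis. Injective because no mesh vertex sits at
# the -x pole (guaranteed by the fixed pre-rotation of the base icosahedron).
squash_to_cap <- function(v) {
  x <- pmin(pmax(v[, 1], -1), 1)
  theta <- acos(x)
  s <- sin(theta)
  wy <- ifelse(s > 1e-12, v[, 2] / s, 1)
  wz <- ifelse(s > 1e-12, v[, 3] / s, 0)
  th2 <- theta / 2
  cbind(cos(th2), sin(th2) * wy, sin(th2) * wz)
}

adjacency_from_faces <- function(faces, n_vertices) {
  e <- rbind(faces[, 1:2], faces[, 2:3], faces[, c(3, 1)])
  e <- rbind(e, e[, 2:1])
  e <- unique(e)
  e <- e[e[, 1] != e[, 2], , drop = FALSE]
  adj <- split(e[, 2], factor(e[, 1], levels = seq_len(n_vertices)))
  lapply(adj, function(x) sort(unique(as.integer(x))))
}

#' Build a two-hemisphere spherical source space
#'
#' Constructs a toy cortical source space: each hemisphere is a recursively
#' subdivided icosahedral mesh mapped onto one hemispherical cap of a sphere
#' of the given radius (midline at x = 0). Dipole normals are radial, standing
#' in for the surface-orthogonal orientation of cortical pyramidal cells.
#' Adjacency is taken from mesh edges and never crosses the midline, so
#' region-grown clusters cannot span hemispheres.
#'
#' A subdivision level `n` yields `10 * 4^n + 2` vertices per hemisphere,
#' hence `2 * (10 * 4^n + 2)` dipoles in total (level 4 gives 5124).
#'
#' @param subdivision_level integer >= 0; icosahedral subdivision level per
#'   hemisphere. Levels above 7 are rejected as a memory guard.
#' @param radius sphere radius in mm (default 79, a typical adult cortex
#'   radius in a spherical head model).
#' @return an object of class `source_space`: positions (p x 3, mm), normals
#'   (p x 3, unit), adjacency (list of integer neighbor vectors), faces per
#'   hemisphere, `hemisphere` label per vertex, `subdivision_level`, `radius`.
#' @export
build_source_space <- function(subdivision_level, radius = 79) {
  stopifnot(subdivision_level >= 0)
  if (subdivision_level > 7) {
    stop("subdivision_level > 7 refused (memory guard)")
  }
  mesh <- icosphere(subdivision_level)
  nv <- nrow(mesh$vertices)
  right <- squash_to_cap(mesh$vertices)
  left <- right
  left[, 1] <- -left[, 1]
  positions <- rbind(right, left) * radius
  faces_r <- mesh$faces
  faces_l <- mesh$faces + nv
  adj <- adjacency_from_faces(rbind(faces_r, faces_l), 2L * nv)
  normals <- unit_rows(positions)
  structure(
    list(
      positions = positions,
      normals = normals,
      adjacency = adj,
      faces = list(right = faces_r, left = faces_l),
      hemisphere = rep(c("R", "L"), each = nv),
      subdivision_level = as.integer(subdivision_level),
      radius = radius
    ),
    class = "source_space"
  )
}

#' @export
print.source_space <- function(x, ...) {
  cat(sprintf(
    "<source_space> level %d, %d dipoles (2 hemispheres), radius %.1f mm\n",
    x$subdivision_level, nrow(x$positions), x$radius
  ))
  invisible(x)
}

#' Number of dipoles in a source space
#' @param space a `source_space`.
#' @return integer count.
#' @export
n_dipoles <- function(space) nrow(space$positions)

#' Breadth-first vertex neighborhood of a seed
#'
#' All vertices within `hops` adjacency steps of `seed` (the neighborhood
#' order `s` corresponds to `hops = s - 1`).
#' @param space a `source_space`.
#' @param seed seed vertex index.
#' @param hops number of adjacency steps (>= 0).
#' @return sorted integer vector of vertex indices, including the seed.
#' @export
bfs_neighborhood <- function(space, seed, hops) {
  visited <- rep(FALSE, n_dipoles(space))
  visited[seed] <- TRUE
  frontier <- seed
  if (hops > 0) {
    for (h in seq_len(hops)) {
      nxt <- unique(unlist(space$adjacency[frontier], use.names = FALSE))
      nxt <- nxt[!visited[nxt]]
      if (length(nxt) == 0) break
      visited[nxt] <- TRUE
      frontier <- nxt
    }
  }
  which(visited)
}
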