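#' Per-face unit normals and areas
#'
#' The normal of each triangular face is the normalized cross product of its
#' edge vectors `(p1 - p0) x (p2 - p0)`, so orientation follows the winding
#' order of the face; the face area is half the cross-product magnitude.
#' Faces whose (squared-length-unit) area falls below
#' `degenerate_area_epsilon` are flagged degenerate: their normal is set to
#' `NA` and downstream metrics exclude them.
#'
#' @param mesh a [tri_mesh()].
#' @param degenerate_area_epsilon area threshold below which a face is
#'   flagged degenerate.
#' @return list with `normals` (m x 3, unit rows; `NA` for degenerate
#'   faces), `areas` (length m), and `degenerate` (logical, length m).
#' @export
face_normals <- function(mesh, degenerate_area_epsilon = 1e-12) {
  stopifnot_mesh(mesh)
  v <- mesh$vertices
  f <- mesh$faces
  u <- v[f[, 2L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  w <- v[f[, 3L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  cr <- cbind(u[, 2L] * w[, 3L] - u[, 3L] * w[, 2L],
              u[, 3L] * w[, 1L] - u[, 1L] * w[, 3L],
              u[, 1L] * w[, 2L] - u[, 2L] * w[, 1L])
  nrm <- sqrt(rowSums(cr^2))
  areas <- nrm / 2
  degenerate <- areas <= degenerate_area_epsilon
  if (any(degenerate))
    warning(sum(degenerate), " degenerate face(s) flagged and excluded")
  normals <- cr / nrm
  normals[degenerate, ] <- NA_real_
  list(normals = normals, areas = areas, degenerate = degenerate)
}

#' Per-vertex unit normals
#'
#' Approximates the discrete normal map at each vertex as the normalized
#' (by default unweighted) arithmetic mean of the unit normals of the
#' incident non-degenerate faces. Area-weighted averaging is available as an
#' option. Vertices whose incident normals cancel to a (numerically) zero
#' average are flagged; faces touching a flagged vertex are excluded from
#' Dirichlet normal energy.
#'
#' @param mesh a [tri_mesh()].
#' @param fn optional output of [face_normals()] (recomputed if `NULL`).
#' @param area_weighted logical; weight the average by face area.
#' @return list with `normals` (n x 3 unit rows; `NA` rows for flagged
#'   vertices) and `flagged` (logical, length n: isolated vertices or
#'   cancelled averages).
#' @export
vertex_normals <- function(mesh, fn = NULL, area_weighted = FALSE) {
  stopifnot_mesh(mesh)
  if (is.null(fn)) fn <- face_normals(mesh)
  keep <- !fn$degenerate
  f <- mesh$faces[keep, , drop = FALSE]
  nrm <- fn$normals[keep, , drop = FALSE]
  w <- if (area_weighted) fn$areas[keep] else rep(1, nrow(f))
  idx <- c(f[, 1L], f[, 2L], f[, 3L])
  stacked <- rbind(nrm, nrm, nrm) * rep(w, 3L)
  sums <- rowsum(stacked, group = idx)
  vn <- matrix(0, n_vertices(mesh), 3L)
  vn[as.integer(rownames(sums)), ] <- sums
  len <- sqrt(rowSums(vn^2))
  flagged <- len < 1e-12
  vn <- vn / len
  vn[flagged, ] <- NA_real_
  list(normals = vn, flagged = flagged)
}

#' Edge-based mesh adjacency
#'
#' Builds the connectivity index shared by the boundary rule and the patch
#' search: the faces incident to every undirected edge, the edge-sharing
#' face neighbor pairs, and the faces incident to every vertex.
#'
#' @param mesh a [tri_mesh()].
#' @return list with:
#'   * `edge_faces`: list mapping each undirected edge to the integer vector
#'     of faces containing it (names are `"i-j"` vertex pairs, `i < j`);
#'   * `boundary_edge_faces`: integer vector of faces owning an edge that
#'     belongs to only one face;
#'   * `face_pairs`: 2-column matrix of unordered face pairs sharing an edge;
#'   * `vertex_faces`: list of incident faces per vertex index (as names).
#' @export
build_adjacency <- function(mesh) {
  stopifnot_mesh(mesh)
  f <- mesh$faces
  m <- nrow(f)
  a <- c(f[, 1L], f[, 2L], f[, 3L])
  b <- c(f[, 2L], f[, 3L], f[, 1L])
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "-")
  fid <- rep.int(seq_len(m), 3L)
  edge_faces <- split(fid, key)
  nf_per_edge <- lengths(edge_faces)
  boundary_edge_faces <- unique(unlist(edge_faces[nf_per_edge == 1L],
                                       use.names = FALSE))
  pairs <- edge_faces[nf_per_edge == 2L]
  face_pairs <- if (length(pairs))
    matrix(unlist(pairs, use.names = FALSE), ncol = 2L, byrow = TRUE)
  else matrix(integer(), ncol = 2L)
  vertex_faces <- split(fid, as.vector(f))
  list(edge_faces = edge_faces,
       boundary_edge_faces = boundary_edge_faces,
       face_pairs = face_pairs,
       vertex_faces = vertex_faces)
}

#' Faces on the boundary of a hole
#'
#' A boundary face owns at least one edge shared by no other face — the rim
#' of a hole, e.g. the large inferior hole left when a tooth crown is
#' cropped at the cervical margin. On a closed surface the result is empty.
#'
#' @param mesh a [tri_mesh()].
#' @param adjacency optional output of [build_adjacency()].
#' @return sorted integer vector of face indices.
#' @export
boundary_faces <- function(mesh, adjacency = NULL) {
  stopifnot_mesh(mesh)
  if (is.null(adjacency)) adjacency <- build_adjacency(mesh)
  sort(adjacency$boundary_edge_faces)
}

rotation_matrix <- function(angles_deg) {
  th <- angles_deg * pi / 180
  cx <- cos(th[1L]); sx <- sin(th[1L])
  cy <- cos(th[2L]); sy <- sin(th[2L])
  cz <- cos(th[3L]); sz <- sin(th[3L])
  rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  rz %*% ry %*% rx
}

#' Rigidly transform a mesh
#'
#' Rotates the vertex coordinates about the X, then Y, then Z axes (applied
#' in that order, i.e. `v' = Rz Ry Rx v`), then adds an optional
#' translation. Topology is untouched and all pairwise distances are
#' preserved.
#'
#' @param mesh a [tri_mesh()].
#' @param angles_deg numeric length-3: rotation angles about X, Y, Z in degrees.
#' @param translation numeric length-3 offset added after rotation.
#' @return the transformed [tri_mesh()].
#' @export
rotate_mesh <- function(mesh, angles_deg = c(0, 0, 0), translation = c(0, 0, 0)) {
  stopifnot_mesh(mesh)
  stopifnot(length(angles_deg) == 3L, length(translation) == 3L)
  r <- rotation_matrix(angles_deg)
  v <- mesh$vertices %*% t(r)
  v <- sweep(v, 2L, translation, `+`)
  tri_mesh(v, mesh$faces, name = mesh$name)
}

#' Translate a mesh centroid to the origin
#'
#' The centroid is the unweighted mean of the vertex coordinates. Metrics
#' that rotate the mesh about the Z axis call this first so that rotation
#' pivots about the specimen itself.
#'
#' @param mesh a [tri_mesh()].
#' @return the translated [tri_mesh()].
#' @export
center_on_origin <- function(mesh) {
  stopifnot_mesh(mesh)
  ctr <- colMeans(mesh$vertices)
  tri_mesh(sweep(mesh$vertices, 2L, ctr), mesh$faces, name = mesh$name)
}

#' Implicit fairing smooth
#'
#' Smooths vertex positions by implicit integration of Laplacian diffusion:
#' each iteration solves the sparse linear system `(I - lambda * L) X' = X`,
#' with `L` the uniform-weight umbrella Laplacian
#' `(L X)_i = mean_j(x_j) - x_i` over the edge neighbors `j` of vertex `i`.
#' Implicit integration is unconditionally stable, so `lambda` may exceed 1.
#' Face topology is unchanged. Smoothing a noisy surface reduces its
#' Dirichlet normal energy; a flat plane is a fixed point.
#'
#' @param mesh a [tri_mesh()].
#' @param iterations number of implicit steps (0 returns the mesh unchanged).
#' @param lambda positive diffusion step size per iteration.
#' @return the smoothed [tri_mesh()].
#' @export
implicit_fair_smooth <- function(mesh, iterations = 10L, lambda = 0.6) {
  stopifnot_mesh(mesh)
  iterations <- as.integer(iterations)
  if (iterations < 0L) stop("`iterations` must be nonnegative")
  if (lambda <= 0) stop("`lambda` must be positive")
  if (iterations == 0L) return(mesh)
  n <- n_vertices(mesh)
  f <- mesh$faces
  a <- c(f[, 1L], f[, 2L], f[, 3L])
  b <- c(f[, 2L], f[, 3L], f[, 1L])
  ij <- unique(cbind(pmin(a, b), pmax(a, b)))
  i <- c(ij[, 1L], ij[, 2L])
  j <- c(ij[, 2L], ij[, 1L])
  deg <- tabulate(i, nbins = n)
  if (any(deg == 0L)) stop("mesh has isolated vertices; cannot smooth")
  w <- 1 / deg[i]
  lap <- Matrix::sparseMatrix(i = i, j = j, x = w, dims = c(n, n)) -
    Matrix::Diagonal(n)
  sys <- Matrix::Diagonal(n) - lambda * lap
  x <- mesh$vertices
  scale <- max(1, max(abs(x)))
  for (k in seq_len(iterations)) {
    xnew <- as.matrix(Matrix::solve(sys, x))
    resid <- max(abs(as.matrix(sys %*% xnew) - x))
    if (!is.finite(resid) || resid > 1e-6 * scale)
      stop(sprintf("implicit fairing solve failed at iteration %d (residual %g)",
                   k, resid))
    x <- xnew
  }
  tri_mesh(x, mesh$faces, name = mesh$name)
}
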