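#' Options for Dirichlet normal energy
#'
#' Collects the tunable parameters of [compute_dne()].
#'
#' The three energy-discard rules are: (1) boundary faces (faces on the rim
#' of a hole) are dropped because their vertices lack a full complement of
#' incident faces for normal averaging; (2) faces whose edge Gram matrix `G`
#' has a high condition number are dropped because their energy is
#' numerically unstable; (3) faces whose energy (or energy density) exceeds
#' a high percentile of the surviving distribution are dropped as scanner
#' noise. Outlier removal above the 99.9th percentile is on by default.
#'
#' @param boundary_discard drop faces on the boundary of a hole (default on).
#' @param condition_check drop faces whose `G` condition number exceeds
#'   `condition_threshold` (default on).
#' @param condition_threshold positive condition-number cutoff (> 1).
#' @param outlier_discard drop outlier faces (default on).
#' @param outlier_percentile percentile in (0, 100] above which faces are
#'   discarded.
#' @param outlier_basis `"energy"` (energy density times area, the default)
#'   or `"energy_density"`: the quantity whose percentile is taken.
#' @param smooth_first apply an implicit fairing smooth before computing
#'   energies (off by default; provided for compatibility with older DNE
#'   tools that force the smooth).
#' @param smooth_iterations,smooth_lambda parameters passed to
#'   [implicit_fair_smooth()] when `smooth_first` is on.
#' @return a list of class `dne_options`.
#' @export
dne_options <- function(boundary_discard = TRUE,
                        condition_check = TRUE,
                        condition_threshold = 1e5,
                        outlier_discard = TRUE,
                        outlier_percentile = 99.9,
                        outlier_basis = c("energy", "energy_density"),
                        smooth_first = FALSE,
                        smooth_iterations = 10L,
                        smooth_lambda = 0.6) {
  outlier_basis <- match.arg(outlier_basis)
  if (!(outlier_percentile > 0 && outlier_percentile <= 100))
    stop("`outlier_percentile` must lie in (0, 100]")
  if (condition_threshold <= 1)
    stop("`condition_threshold` must exceed 1")
  structure(list(boundary_discard = isTRUE(boundary_discard),
                 condition_check = isTRUE(condition_check),
                 condition_threshold = condition_threshold,
                 outlier_discard = isTRUE(outlier_discard),
                 outlier_percentile = outlier_percentile,
                 outlier_basis = outlier_basis,
                 smooth_first = isTRUE(smooth_first),
                 smooth_iterations = smooth_iterations,
                 smooth_lambda = smooth_lambda),
            class = "dne_options")
}

# Vectorized e(p) = tr(G^-1 H) over faces.
# u = p1-p0, v = p2-p0 span the face; nu = n1-n0, nv = n2-n0 span its
# normal-map image. G and H are the 2x2 Gram matrices of (u,v) and (nu,nv).
energy_density_faces <- function(verts, faces, vnormals) {
  p0 <- verts[faces[, 1L], , drop = FALSE]
  p1 <- verts[faces[, 2L], , drop = FALSE]
  p2 <- verts[faces[, 3L], , drop = FALSE]
  n0 <- vnormals[faces[, 1L], , drop = FALSE]
  n1 <- vnormals[faces[, 2L], , drop = FALSE]
  n2 <- vnormals[faces[, 3L], , drop = FALSE]
  u <- p1 - p0
  v <- p2 - p0
  nu <- n1 - n0
  nv <- n2 - n0
  g11 <- rowSums(u * u); g12 <- rowSums(u * v); g22 <- rowSums(v * v)
  h11 <- rowSums(nu * nu); h12 <- rowSums(nu * nv); h22 <- rowSums(nv * nv)
  det_g <- g11 * g22 - g12^2
  e <- (g22 * h11 - 2 * g12 * h12 + g11 * h22) / det_g
  # condition number of symmetric PSD G = ratio of its eigenvalues
  tr <- g11 + g22
  disc <- sqrt(pmax((g11 - g22)^2 + 4 * g12^2, 0))
  lmax <- (tr + disc) / 2
  lmin <- (tr - disc) / 2
  cond <- ifelse(lmin > 0, lmax / lmin, Inf)
  e[!is.finite(e) | det_g <= 0] <- NA_real_
  list(energy_density = e, condition_number = cond)
}

#' Energy density of a single polygon
#'
#' Computes the Dirichlet normal energy density `e(p) = tr(G^-1 H)` of one
#' triangle from its vertex coordinates and the unit normals at its
#' vertices. With edge vectors `u = p1 - p0`, `v = p2 - p0` and normal-map
#' differences `nu = n1 - n0`, `nv = n2 - n0`, `G` is the symmetric Gram
#' matrix of `(u, v)` and `H` the Gram matrix of `(nu, nv)`; `e(p)` measures
#' the spreading of the normal map relative to the spreading of the
#' polygon, and is invariant to the choice of edge basis (hence to cyclic
#' reordering of the vertices).
#'
#' @param face_coords 3 x 3 numeric matrix, one vertex per row.
#' @param face_vertex_normals 3 x 3 numeric matrix of unit normals, one per
#'   vertex row.
#' @return list with `energy_density` (nonnegative; `NA` if `G` is
#'   singular) and `condition_number` (ratio of the largest to smallest
#'   singular value of `G`; `Inf` if singular).
#' @examples
#' p <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
#' n <- rbind(c(0, 0, 1), c(1, 0, 1) / sqrt(2), c(0, 1, 1) / sqrt(2))
#' polygon_energy(p, n)$energy_density  # ~1.17157
#' @export
polygon_energy <- function(face_coords, face_vertex_normals) {
  face_coords <- as.matrix(face_coords)
  face_vertex_normals <- as.matrix(face_vertex_normals)
  stopifnot(all(dim(face_coords) == c(3L, 3L)),
            all(dim(face_vertex_normals) == c(3L, 3L)))
  res <- energy_density_faces(face_coords, matrix(1:3, 1L),
                              face_vertex_normals)
  list(energy_density = res$energy_density[1L],
       condition_number = res$condition_number[1L])
}

#' Dirichlet normal energy of a mesh
#'
#' DNE quantifies how much a surface bends: it is the integral of the
#' Dirichlet energy of the surface's normal map, which in the continuum
#' limit equals the integral of the sum of squared principal curvatures
#' (so a unit sphere has DNE `8 * pi`). Both convex and concave bending
#' increase it, and it is invariant to rigid motion and uniform scaling.
#'
#' The discrete computation: per-face unit normals are averaged into vertex
#' normals ([vertex_normals()]); each face's energy density
#' `e(p) = tr(G^-1 H)` is evaluated ([polygon_energy()]); faces are then
#' excluded in the fixed order degenerate, boundary, ill-conditioned,
#' outlier (each face records the first reason that applied, and the
#' outlier percentile is taken over the faces surviving the earlier
#' filters); finally `total_dne` is the sum of `e(p) * area` over included
#' faces.
#'
#' Note that for noisy scanned surfaces DNE grows with mesh resolution, so
#' comparative samples should be simplified to a common face count.
#'
#' @param mesh a [tri_mesh()].
#' @param options a [dne_options()] list.
#' @return object of class `dne_result`: list with `total_dne` and `faces`,
#'   a data.frame with per-face `energy_density`, `area`,
#'   `condition_number` and `exclusion` (factor: none, degenerate,
#'   boundary, condition, outlier).
#' @export
compute_dne <- function(mesh, options = dne_options()) {
  stopifnot_mesh(mesh)
  if (!inherits(options, "dne_options")) stop("`options` must come from dne_options()")
  if (options$smooth_first)
    mesh <- implicit_fair_smooth(mesh, options$smooth_iterations,
                                 options$smooth_lambda)
  fn <- face_normals(mesh)
  vn <- vertex_normals(mesh, fn)
  ed <- energy_density_faces(mesh$vertices, mesh$faces, vn$normals)
  m <- n_faces(mesh)

  reason <- rep("none", m)
  # 0) degenerate faces, faces with a cancelled vertex normal, singular G
  flagged_vertex <- vn$flagged[mesh$faces[, 1L]] | vn$flagged[mesh$faces[, 2L]] |
    vn$flagged[mesh$faces[, 3L]]
  degen <- fn$degenerate | flagged_vertex | is.na(ed$energy_density)
  reason[degen] <- "degenerate"
  # 1) boundary-of-hole faces
  if (options$boundary_discard) {
    bf <- boundary_faces(mesh)
    reason[reason == "none" & seq_len(m) %in% bf] <- "boundary"
  }
  # 2) ill-conditioned G
  if (options$condition_check) {
    bad <- ed$condition_number > options$condition_threshold
    reason[reason == "none" & bad] <- "condition"
  }
  # 3) outliers, percentile over faces surviving the earlier filters
  if (options$outlier_discard) {
    inc <- reason == "none"
    basis <- if (options$outlier_basis == "energy")
      ed$energy_density * fn$areas else ed$energy_density
    if (any(inc)) {
      cutoff <- stats::quantile(basis[inc], options$outlier_percentile / 100,
                                names = FALSE, type = 7)
      reason[inc & basis > cutoff] <- "outlier"
    }
  }
  included <- reason == "none"
  if (!any(included))
    stop("no faces survive exclusion; cannot compute DNE")
  energy <- ed$energy_density * fn$areas
  total <- sum(energy[included])
  structure(list(
    total_dne = total,
    faces = data.frame(
      energy_density = ed$energy_density,
      area = fn$areas,
      condition_number = ed$condition_number,
      exclusion = factor(reason, levels = c("none", "degenerate", "boundary",
                                            "condition", "outlier")))),
    class = "dne_result")
}

#' @export
print.dne_result <- function(x, ...) {
  cat(sprintf("<dne_result: total DNE %.6g over %d/%d included faces>\n",
              x$total_dne, sum(x$faces$exclusion == "none"), nrow(x$faces)))
  excl <- table(x$faces$exclusion)
  excl <- excl[excl > 0 & names(excl) != "none"]
  if (length(excl))
    cat("  excluded:", paste(sprintf("%s %d", names(excl), excl), collapse = ", "),
        "\n")
  invisible(x)
}
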