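#' Aspect bins of face normals
#'
#' The aspect of a face is the compass direction of its normal projected
#' onto the XY plane, `atan2(ny, nx)` mapped to `[0, 360)` degrees. Faces
#' are sorted into eight 45-degree arcs with half-open boundaries at 0, 45,
#' ..., 315 degrees measured from +X (bin `b` covers `[45b, 45(b+1))`).
#' A Z-rotation of the mesh adds a constant to every aspect, so rotation is
#' applied as an aspect offset: the effective aspect is
#' `(aspect + rotation_deg) mod 360`. Faces whose normal is parallel to the
#' Z axis (XY norm below `1e-8`) have no aspect and are left unbinned
#' (`NA`); downward-pointing normals are binned by their XY aspect like any
#' other face, so overhangs are handled.
#'
#' @param normals m x 3 matrix of unit face normals (`NA` rows allowed for
#'   degenerate faces; they stay unbinned).
#' @param rotation_deg aspect offset in degrees, equivalent to rotating the
#'   mesh by `-rotation_deg` about Z.
#' @return integer vector of bins 0-7, `NA` for unbinned faces.
#' @export
face_aspect_bins <- function(normals, rotation_deg = 0) {
  normals <- as.matrix(normals)
  xy <- sqrt(normals[, 1L]^2 + normals[, 2L]^2)
  aspect <- (atan2(normals[, 2L], normals[, 1L]) * 180 / pi) %% 360
  eff <- (aspect + rotation_deg) %% 360
  bin <- as.integer(floor(eff / 45))
  bin[bin == 8L] <- 0L  # guard: eff == 360 - epsilon rounding up
  bin[!is.finite(xy) | xy < 1e-8] <- NA_integer_
  bin
}

#' Contiguous orientation patches
#'
#' Groups binned faces into patches: connected components of the graph
#' whose nodes are the binned faces and whose links join edge-adjacent
#' faces with equal aspect bin. Adjacency is through shared edges, not
#' shared vertices — vertex-sharing would let patches leak through single
#' points. All faces in a patch therefore face the same compass direction
#' and are mutually reachable through same-bin edge neighbors.
#'
#' @param mesh a [tri_mesh()].
#' @param adjacency optional output of [build_adjacency()].
#' @param bins output of [face_aspect_bins()].
#' @return object of class `patch_map`: list with `bins`, `patch_label`
#'   (integer per face, `NA` for unbinned faces), `patches` (data.frame
#'   with `patch`, `bin`, `size`), `faces_by_patch` (list of face-index
#'   vectors), and `rotation_deg` (attribute copied from the caller, 0 if
#'   unknown).
#' @export
find_patches <- function(mesh, adjacency = NULL, bins, rotation_deg = 0) {
  stopifnot_mesh(mesh)
  if (is.null(adjacency)) adjacency <- build_adjacency(mesh)
  m <- n_faces(mesh)
  if (length(bins) != m) stop("`bins` length must equal the face count")
  fp <- adjacency$face_pairs
  same <- !is.na(bins[fp[, 1L]]) & !is.na(bins[fp[, 2L]]) &
    bins[fp[, 1L]] == bins[fp[, 2L]]
  g <- igraph::make_empty_graph(n = m, directed = FALSE)
  if (any(same))
    g <- igraph::add_edges(g, t(fp[same, , drop = FALSE]))
  comp <- igraph::components(g)$membership
  label <- ifelse(is.na(bins), NA_integer_, comp)
  # renumber patches 1..k in order of first appearance
  uniq <- unique(label[!is.na(label)])
  label <- match(label, uniq)
  faces_by_patch <- split(seq_len(m)[!is.na(label)], label[!is.na(label)])
  sizes <- lengths(faces_by_patch)
  pbin <- vapply(faces_by_patch, function(ix) bins[ix[1L]], 0L)
  structure(list(bins = bins,
                 patch_label = label,
                 patches = data.frame(patch = seq_along(sizes),
                                      bin = as.integer(pbin),
                                      size = as.integer(sizes)),
                 faces_by_patch = faces_by_patch,
                 rotation_deg = rotation_deg),
            class = "patch_map")
}

#' Orientation patch count at one rotation
#'
#' OPC is the number of contiguous same-aspect patches whose face count
#' reaches the minimum patch size. The mesh centroid is first translated to
#' the origin (the conventional first step; translation does not alter
#' normals). A perfectly flat horizontal mesh has no binned faces and an
#' OPC of 0 (with a warning); a finely tessellated sphere has an OPC of 8,
#' one patch per compass direction.
#'
#' @param mesh a [tri_mesh()].
#' @param min_patch_size minimum faces per counted patch (>= 1). The
#'   default of 5 follows usage on meshes simplified to about 10,000 faces.
#' @param rotation_deg Z-rotation (degrees) at which to evaluate OPC.
#' @param fn,adjacency optional precomputed [face_normals()] /
#'   [build_adjacency()] results (recomputed if `NULL`).
#' @return list with `opc` (integer) and `patch_map` (a [find_patches()]
#'   result).
#' @export
compute_opc <- function(mesh, min_patch_size = 5L, rotation_deg = 0,
                        fn = NULL, adjacency = NULL) {
  stopifnot_mesh(mesh)
  min_patch_size <- as.integer(min_patch_size)
  if (min_patch_size < 1L) stop("`min_patch_size` must be >= 1")
  mesh <- center_on_origin(mesh)
  if (is.null(fn)) fn <- face_normals(mesh)
  if (is.null(adjacency)) adjacency <- build_adjacency(mesh)
  bins <- face_aspect_bins(fn$normals, rotation_deg)
  if (all(is.na(bins)))
    warning("all faces are unbinned (normals parallel to Z); OPC is 0")
  pm <- find_patches(mesh, adjacency, bins, rotation_deg = rotation_deg)
  opc <- sum(pm$patches$size >= min_patch_size)
  list(opc = as.integer(opc), patch_map = pm)
}

#' Orientation patch count rotated
#'
#' OPCR makes OPC robust to the arbitrary choice of specimen orientation
#' about the Z axis: OPC is evaluated at eight successive Z-rotations of
#' 5.625 degrees (spanning 45 degrees in total) and averaged. Because the
#' eight 45-degree bins permute cyclically under a full 45-degree rotation,
#' OPC at 45 degrees equals OPC at 0 degrees, so the eight rotations
#' `k * 5.625, k = 0..7` cover all distinct binnings. Rotation is applied
#' as an aspect offset, which is mathematically identical to rotating the
#' vertices and re-deriving normals.
#'
#' @param mesh a [tri_mesh()].
#' @param min_patch_size minimum faces per counted patch.
#' @param keep_patch_maps retain the eight per-rotation [find_patches()]
#'   results (off by default; they are large).
#' @return object of class `opcr_result`: list with `opc_per_rotation`
#'   (integer vector, rotations `0, 5.625, ..., 39.375` degrees), `opcr`
#'   (their mean), `rotations_deg`, `min_patch_size`, and optionally
#'   `patch_maps`.
#' @export
compute_opcr <- function(mesh, min_patch_size = 5L, keep_patch_maps = FALSE) {
  stopifnot_mesh(mesh)
  mesh <- center_on_origin(mesh)
  fn <- face_normals(mesh)
  adjacency <- build_adjacency(mesh)
  rot <- 5.625 * (0:7)
  maps <- if (keep_patch_maps) vector("list", 8L) else NULL
  opc <- integer(8L)
  for (k in seq_along(rot)) {
    res <- compute_opc(mesh, min_patch_size, rot[k], fn = fn,
                       adjacency = adjacency)
    opc[k] <- res$opc
    if (keep_patch_maps) maps[[k]] <- res$patch_map
  }
  structure(list(opc_per_rotation = opc,
                 opcr = mean(opc),
                 rotations_deg = rot,
                 min_patch_size = as.integer(min_patch_size),
                 patch_maps = maps),
            class = "opcr_result")
}

#' @export
print.opcr_result <- function(x, ...) {
  cat(sprintf("<opcr_result: OPCR %.3f (min patch size %d)>\n",
              x$opcr, x$min_patch_size))
  cat("  OPC per rotation:", paste(x$opc_per_rotation, collapse = " "), "\n")
  invisible(x)
}
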