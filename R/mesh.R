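#' Triangle mesh objects
#'
#' `tri_mesh()` constructs the package's basic unit of analysis: a
#' triangulated polygon surface defined by an `n x 3` matrix of vertex
#' coordinates (arbitrary length units, typically mm) and an `m x 3` integer
#' matrix of vertex indices, one row per triangular face.
#'
#' Face indices are **1-based inside R** (the natural convention for matrix
#' indexing); they are translated to the 0-based convention of the PLY and
#' OFF file formats on read and write. Users porting index lists from
#' GIS-derived tools should check which convention their source uses.
#'
#' @param vertices numeric matrix with 3 columns (x, y, z), at least 3 rows.
#' @param faces integer matrix with 3 columns of vertex indices in
#'   `[1, nrow(vertices)]`; each face must name 3 distinct vertices.
#' @param name source identifier carried through to result tables.
#' @return an object of class `tri_mesh`: a list with elements `vertices`,
#'   `faces` and `name`.
#' @examples
#' v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
#' f <- rbind(c(1L, 2L, 3L))
#' m <- tri_mesh(v, f, name = "triangle")
#' m
#' @export
tri_mesh <- function(vertices, faces, name = "mesh") {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L)
    stop("`vertices` must have exactly 3 columns (x, y, z)")
  if (ncol(faces) != 3L)
    stop("`faces` must have exactly 3 columns (triangular faces only)")
  if (nrow(vertices) < 3L)
    stop("a mesh needs at least 3 vertices")
  if (nrow(faces) < 1L)
    stop("a mesh needs at least 1 face")
  if (anyNA(vertices)) stop("`vertices` contains missing values")
  if (anyNA(faces)) stop("`faces` contains missing values")
  if (min(faces) < 1L || max(faces) > nrow(vertices))
    stop("face indices must lie in [1, vertex count]")
  dup <- faces[, 1L] == faces[, 2L] | faces[, 1L] == faces[, 3L] |
    faces[, 2L] == faces[, 3L]
  if (any(dup))
    stop("faces must reference 3 distinct vertices (first offender: face ",
         which(dup)[1L], ")")
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  structure(list(vertices = vertices, faces = faces, name = as.character(name)),
            class = "tri_mesh")
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("<tri_mesh '%s': %d vertices, %d faces>\n",
              x$name, nrow(x$vertices), nrow(x$faces)))
  rng <- apply(x$vertices, 2L, range)
  cat(sprintf("  bbox x [%g, %g]  y [%g, %g]  z [%g, %g]\n",
              rng[1, 1], rng[2, 1], rng[1, 2], rng[2, 2], rng[1, 3], rng[2, 3]))
  invisible(x)
}

n_vertices <- function(mesh) nrow(mesh$vertices)
n_faces <- function(mesh) nrow(mesh$faces)

is_tri_mesh <- function(x) inherits(x, "tri_mesh")

stopifnot_mesh <- function(mesh) {
  if (!is_tri_mesh(mesh)) stop("expected a `tri_mesh` object")
  invisible(mesh)
}
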