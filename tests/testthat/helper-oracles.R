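# Independent brute-force oracles and fixture writers used across tests.
# These deliberately avoid the package's own vectorized code paths.

# per-edge scan: a face is on the boundary iff one of its edges occurs once
brute_boundary_faces <- function(mesh) {
  f <- mesh$faces
  edge_count <- new.env(hash = TRUE)
  ekey <- function(a, b) paste(min(a, b), max(a, b))
  for (i in seq_len(nrow(f))) {
    for (e in list(c(1, 2), c(2, 3), c(3, 1))) {
      k <- ekey(f[i, e[1]], f[i, e[2]])
      edge_count[[k]] <- c(if (!is.null(edge_count[[k]])) edge_count[[k]], i)
    }
  }
  res <- integer()
  for (k in ls(edge_count))
    if (length(edge_count[[k]]) == 1L) res <- c(res, edge_count[[k]])
  sort(unique(res))
}

# transitive-closure patch labeling: repeated sweeps until no label changes
brute_patch_labels <- function(mesh, bins) {
  f <- mesh$faces
  m <- nrow(f)
  ekey <- function(a, b) paste(min(a, b), max(a, b))
  edge_faces <- new.env(hash = TRUE)
  for (i in seq_len(m)) {
    for (e in list(c(1, 2), c(2, 3), c(3, 1))) {
      k <- ekey(f[i, e[1]], f[i, e[2]])
      edge_faces[[k]] <- c(if (!is.null(edge_faces[[k]])) edge_faces[[k]], i)
    }
  }
  label <- seq_len(m)
  label[is.na(bins)] <- NA_integer_
  repeat {
    changed <- FALSE
    for (k in ls(edge_faces)) {
      fc <- edge_faces[[k]]
      if (length(fc) == 2L && !is.na(bins[fc[1]]) && !is.na(bins[fc[2]]) &&
          bins[fc[1]] == bins[fc[2]]) {
        lo <- min(label[fc]); hi <- max(label[fc])
        if (lo != hi) {
          label[label == hi] <- lo
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  label
}

# canonical form for comparing two labelings up to renaming
canonical_partition <- function(label) {
  ok <- !is.na(label)
  groups <- lapply(split(which(ok), label[ok]), as.integer)
  unname(groups[order(vapply(groups, min, 1L))])
}

# minimal binary PLY writer (float32 vertices, uchar count + int32 indices)
write_binary_ply <- function(path, vertices, faces0, endian = "little") {
  hdr <- paste0(
    "ply\nformat binary_", endian, "_endian 1.0\n",
    "element vertex ", nrow(vertices), "\n",
    "property float x\nproperty float y\nproperty float z\n",
    "element face ", nrow(faces0), "\n",
    "property list uchar int vertex_indices\nend_header\n")
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(hdr, con, eos = NULL)
  for (i in seq_len(nrow(vertices)))
    writeBin(as.numeric(vertices[i, ]), con, size = 4L, endian = endian)
  for (i in seq_len(nrow(faces0))) {
    writeBin(as.raw(3L), con)
    writeBin(as.integer(faces0[i, ]), con, size = 4L, endian = endian)
  }
  invisible(path)
}

# a 1 x n strip of triangles (2 * (n - 1) faces), handy for small patch tests
make_strip <- function(n = 11L) make_plane(n, 2L)

n_faces_of <- function(mesh) nrow(mesh$faces)

# random unit vectors
runit <- function(n) {
  m <- matrix(stats::rnorm(3 * n), n, 3)
  m / sqrt(rowSums(m^2))
}

# seeded N(0, sigma) draws that leave the global RNG untouched
with_noise <- function(n, sigma, seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  stats::rnorm(n, sd = sigma)
}

minimal_ply_text <- c(
  "ply", "format ascii 1.0",
  "element vertex 3",
  "property float x", "property float y", "property float z",
  "element face 1",
  "property list uchar int vertex_indices",
  "end_header",
  "0 0 0", "1 0 0", "0 1 0",
  "3 0 1 2")
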