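#' Regular triangulated plane
#'
#' An `nx` by `ny` vertex grid on the unit square, each cell split into two
#' triangles, optionally tilted about the X axis. Yields
#' `2 * (nx - 1) * (ny - 1)` faces. Useful as a zero-bending fixture: a
#' flat horizontal plane has Dirichlet normal energy 0, relief index 1 (up
#' to raster tolerance) and orientation patch count 0.
#'
#' @param nx,ny vertex counts along x and y (>= 2).
#' @param tilt_deg rotation about the X axis applied after triangulation.
#' @return a [tri_mesh()].
#' @export
make_plane <- function(nx = 11L, ny = 11L, tilt_deg = 0) {
  nx <- as.integer(nx); ny <- as.integer(ny)
  if (nx < 2L || ny < 2L) stop("`nx` and `ny` must be at least 2")
  xs <- seq(0, 1, length.out = nx)
  ys <- seq(0, 1, length.out = ny)
  verts <- cbind(rep(xs, times = ny), rep(ys, each = nx), 0)
  vid <- function(i, j) (j - 1L) * nx + i
  i <- rep(seq_len(nx - 1L), times = ny - 1L)
  j <- rep(seq_len(ny - 1L), each = nx - 1L)
  f1 <- cbind(vid(i, j), vid(i + 1L, j), vid(i + 1L, j + 1L))
  f2 <- cbind(vid(i, j), vid(i + 1L, j + 1L), vid(i, j + 1L))
  faces <- rbind(f1, f2)
  mesh <- tri_mesh(verts, faces, name = sprintf("plane_%dx%d", nx, ny))
  if (tilt_deg != 0) mesh <- rotate_mesh(mesh, c(tilt_deg, 0, 0))
  mesh
}

icosahedron <- function() {
  p <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  p, 0), c(1,  p, 0), c(-1, -p, 0), c(1, -p, 0),
    c(0, -1,  p), c(0, 1,  p), c(0, -1, -p), c(0, 1, -p),
    c(p, 0, -1), c(p, 0, 1), c(-p, 0, -1), c(-p, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  list(v = v, f = f)
}

#' Subdivided icosphere
#'
#' Starts from a regular icosahedron and applies `subdivisions` rounds of
#' 4-to-1 midpoint subdivision, projecting every vertex to the requested
#' radius. The result is a closed manifold with `20 * 4^s` faces and
#' `10 * 4^s + 2` vertices whose area converges to `4 * pi * r^2` from
#' below (inscribed polyhedron) and whose Dirichlet normal energy converges
#' to `8 * pi`.
#'
#' @param subdivisions integer in 0..6.
#' @param radius sphere radius.
#' @return a [tri_mesh()].
#' @export
make_icosphere <- function(subdivisions = 3L, radius = 1) {
  subdivisions <- as.integer(subdivisions)
  if (subdivisions < 0L || subdivisions > 6L)
    stop("`subdivisions` must be in 0..6")
  if (radius <= 0) stop("`radius` must be positive")
  ico <- icosahedron()
  v <- ico$v
  f <- ico$f
  for (s in seq_len(subdivisions)) {
    nv <- nrow(v)
    a <- c(f[, 1L], f[, 2L], f[, 3L])
    b <- c(f[, 2L], f[, 3L], f[, 1L])
    lo <- pmin(a, b); hi <- pmax(a, b)
    key <- (lo - 1) * nv + hi
    ukey <- unique(key)
    mid_id <- nv + match(key, ukey)
    ulo <- (ukey - 1) %/% nv + 1
    uhi <- ukey - (ulo - 1) * nv
    mids <- (v[ulo, , drop = FALSE] + v[uhi, , drop = FALSE]) / 2
    mids <- mids / sqrt(rowSums(mids^2))
    v <- rbind(v, mids)
    m <- nrow(f)
    m12 <- mid_id[seq_len(m)]
    m23 <- mid_id[m + seq_len(m)]
    m31 <- mid_id[2L * m + seq_len(m)]
    f <- rbind(cbind(f[, 1L], m12, m31),
               cbind(f[, 2L], m23, m12),
               cbind(f[, 3L], m31, m23),
               cbind(m12, m23, m31))
  }
  tri_mesh(v * radius, f, name = sprintf("icosphere_s%d_r%g", subdivisions, radius))
}

#' Open hemisphere
#'
#' The upper half of a [make_icosphere()]: faces whose three vertices all
#' satisfy `z >= -eps` are retained and unused vertices dropped, leaving a
#' dome-up open surface with a single boundary rim near the equator. This
#' is the canonical boundary-bearing fixture (its rim exercises the
#' boundary-discard rule, mirroring the inferior hole of a cropped tooth
#' crown) with analytic areas `3da ~ 2 * pi * r^2`, `2da ~ pi * r^2` and
#' relief index near 2.
#'
#' @inheritParams make_icosphere
#' @return a [tri_mesh()].
#' @export
make_hemisphere <- function(subdivisions = 4L, radius = 1) {
  sph <- make_icosphere(subdivisions, radius)
  eps <- 1e-9 * radius
  zok <- sph$vertices[, 3L] >= -eps
  keep <- zok[sph$faces[, 1L]] & zok[sph$faces[, 2L]] & zok[sph$faces[, 3L]]
  f <- sph$faces[keep, , drop = FALSE]
  used <- sort(unique(as.vector(f)))
  remap <- integer(nrow(sph$vertices))
  remap[used] <- seq_along(used)
  tri_mesh(sph$vertices[used, , drop = FALSE],
           matrix(remap[f], ncol = 3L),
           name = sprintf("hemisphere_s%d_r%g", subdivisions, radius))
}

#' Height and gradient of a sum-of-Gaussian-cusps surface
#'
#' Analytic helpers for the [make_gaussian_cusps()] fixture, exposed so
#' that tests can compare mesh-based measurements against exact values
#' (e.g. the surface-integral oracle for relief).
#'
#' @param x,y coordinates (recycled to common length).
#' @param cusps data.frame with columns `cx`, `cy`, `height`, `sigma`; one
#'   row per cusp. Zero rows give the flat plane.
#' @return `gaussian_cusp_height()`: heights; `gaussian_cusp_gradient()`:
#'   2-column matrix of `dh/dx`, `dh/dy`.
#' @export
gaussian_cusp_height <- function(x, y, cusps) {
  h <- numeric(length(x))
  for (i in seq_len(nrow(cusps))) {
    d2 <- (x - cusps$cx[i])^2 + (y - cusps$cy[i])^2
    h <- h + cusps$height[i] * exp(-d2 / (2 * cusps$sigma[i]^2))
  }
  h
}

#' @rdname gaussian_cusp_height
#' @export
gaussian_cusp_gradient <- function(x, y, cusps) {
  gx <- numeric(length(x))
  gy <- numeric(length(x))
  for (i in seq_len(nrow(cusps))) {
    dx <- x - cusps$cx[i]
    dy <- y - cusps$cy[i]
    e <- cusps$height[i] * exp(-(dx^2 + dy^2) / (2 * cusps$sigma[i]^2)) /
      cusps$sigma[i]^2
    gx <- gx - dx * e
    gy <- gy - dy * e
  }
  cbind(gx, gy)
}

#' Tooth-like Gaussian-cusp surface
#'
#' A heightfield `h(x, y) = sum_i height_i * exp(-d_i^2 / (2 sigma_i^2))`
#' on a triangulated grid over the unit square: isolated radially symmetric
#' cusps on a flat base, the simplest caricature of an occlusal surface.
#' With zero cusps and zero noise it degenerates to the flat plane.
#' Optional seeded Gaussian noise is applied along vertex normals to mimic
#' scanner noise (relevant to the outlier-discard and smoothing options);
#' the same spec and seed always reproduce the identical mesh, and the
#' caller's random number state is left untouched.
#'
#' @param nx,ny grid vertex counts (>= 50 for faithful cusp geometry).
#' @param cusps data.frame with columns `cx`, `cy` (centers inside the unit
#'   square), `height`, `sigma`.
#' @param noise_sigma standard deviation of vertex noise along normals, in
#'   mesh units (0 for none).
#' @param seed integer seed for the noise.
#' @return a [tri_mesh()].
#' @export
make_gaussian_cusps <- function(nx = 51L, ny = 51L,
                                cusps = data.frame(cx = 0.5, cy = 0.5,
                                                   height = 0.3, sigma = 0.15),
                                noise_sigma = 0, seed = 1L) {
  base <- make_plane(nx, ny)
  x <- base$vertices[, 1L]
  y <- base$vertices[, 2L]
  if (nrow(cusps) > 0 &&
      (any(cusps$cx < 0 | cusps$cx > 1) || any(cusps$cy < 0 | cusps$cy > 1)))
    stop("cusp centers must lie inside the unit square")
  z <- gaussian_cusp_height(x, y, cusps)
  mesh <- tri_mesh(cbind(x, y, z), base$faces,
                   name = sprintf("cusps_%d", nrow(cusps)))
  if (noise_sigma > 0) {
    vn <- vertex_normals(mesh)$normals
    vn[!is.finite(vn)] <- 0
    noise <- with_preserved_rng(seed, stats::rnorm(length(x), sd = noise_sigma))
    mesh <- tri_mesh(mesh$vertices + vn * noise, mesh$faces, name = mesh$name)
  }
  mesh
}

# run `expr` under `seed` without disturbing the caller's RNG state
with_preserved_rng <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}
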