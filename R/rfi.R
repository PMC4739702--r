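#' Three-dimensional surface area
#'
#' Sum of the triangle areas (half cross-product magnitudes) of a mesh, in
#' squared length units.
#'
#' @param mesh a [tri_mesh()].
#' @param fn optional output of [face_normals()].
#' @return positive scalar.
#' @export
surface_area_3d <- function(mesh, fn = NULL) {
  stopifnot_mesh(mesh)
  if (is.null(fn)) fn <- face_normals(mesh)
  sum(fn$areas[!fn$degenerate])
}

#' Projected (occlusal) 2D area by rasterization
#'
#' Measures the area of the mesh silhouette projected onto the XY plane —
#' the plane parallel to the occlusal plane, which the caller is
#' responsible for aligning (see [rotate_mesh()]). The projection is
#' rasterized: a pixel grid spans the XY bounding box with `resolution`
#' pixels along its longest side, a pixel is filled when its center falls
#' inside the XY projection of any face (stacked surface regions such as
#' undercuts fill a pixel once), and the area is the filled-pixel count
#' times the pixel area. This mirrors the classic workflow of exporting an
#' occlusal-view bitmap and counting pixels against a scale bar, and is
#' robust to self-overlapping projections. Discretization error shrinks
#' with resolution (it is of order silhouette perimeter times pixel size);
#' pixel centers exactly on a projected edge are counted as inside.
#'
#' @param mesh a [tri_mesh()].
#' @param resolution pixels along the longest XY extent (>= 100).
#' @return positive scalar, same squared units as the vertex coordinates.
#' @export
projected_area_2d <- function(mesh, resolution = 1000L) {
  stopifnot_mesh(mesh)
  resolution <- as.integer(resolution)
  if (resolution < 100L) stop("`resolution` must be at least 100 pixels")
  v <- mesh$vertices
  xr <- range(v[, 1L])
  yr <- range(v[, 2L])
  ext <- c(diff(xr), diff(yr))
  if (max(ext) <= 0)
    stop("mesh has zero XY extent; projection is degenerate")
  px <- max(ext) / resolution
  nx <- max(1L, as.integer(ceiling(ext[1L] / px)))
  ny <- max(1L, as.integer(ceiling(ext[2L] / px)))
  filled <- matrix(FALSE, nx, ny)
  f <- mesh$faces
  x0 <- xr[1L]; y0 <- yr[1L]
  eps <- 1e-12 * max(ext)^2
  for (i in seq_len(nrow(f))) {
    ax <- v[f[i, 1L], 1L]; ay <- v[f[i, 1L], 2L]
    bx <- v[f[i, 2L], 1L]; by <- v[f[i, 2L], 2L]
    cx <- v[f[i, 3L], 1L]; cy <- v[f[i, 3L], 2L]
    # candidate pixel centers within the triangle's bbox
    ilo <- max(1L, as.integer(floor((min(ax, bx, cx) - x0) / px - 0.5)) + 1L)
    ihi <- min(nx, as.integer(ceiling((max(ax, bx, cx) - x0) / px + 0.5)))
    jlo <- max(1L, as.integer(floor((min(ay, by, cy) - y0) / px - 0.5)) + 1L)
    jhi <- min(ny, as.integer(ceiling((max(ay, by, cy) - y0) / px + 0.5)))
    if (ilo > ihi || jlo > jhi) next
    xs <- x0 + (ilo:ihi - 0.5) * px
    ys <- y0 + (jlo:jhi - 0.5) * px
    gx <- rep(xs, times = length(ys))
    gy <- rep(ys, each = length(xs))
    # signed edge functions; sign of the triangle's orientation normalizes them
    d1 <- (bx - ax) * (gy - ay) - (by - ay) * (gx - ax)
    d2 <- (cx - bx) * (gy - by) - (cy - by) * (gx - bx)
    d3 <- (ax - cx) * (gy - cy) - (ay - cy) * (gx - cx)
    orient <- (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
    if (abs(orient) <= eps) next  # degenerate XY projection of this face
    s <- sign(orient)
    inside <- (s * d1 >= -eps) & (s * d2 >= -eps) & (s * d3 >= -eps)
    if (any(inside)) {
      sub <- filled[ilo:ihi, jlo:jhi]
      sub[matrix(inside, ihi - ilo + 1L, jhi - jlo + 1L)] <- TRUE
      filled[ilo:ihi, jlo:jhi] <- sub
    }
  }
  sum(filled) * px^2
}

#' Relief index
#'
#' The relief index (RFI) of a surface is the ratio of its 3D area (`3da`)
#' to the area of its projection onto the occlusal (XY) plane (`2da`).
#' High-crowned, high-relief surfaces have large RFI; a flat horizontal
#' sheet has RFI 1, a hemispherical dome RFI 2. Because published work
#' reports the metric variously as the plain ratio, as `3da/2da * 100`,
#' and as `ln(3da/2da)`, all three forms are returned along with the two
#' areas themselves. Stacked surface regions (undercuts) count fully toward
#' `3da` but only once toward `2da`.
#'
#' The mesh must already be oriented with the occlusal plane parallel to XY.
#'
#' @param mesh a [tri_mesh()].
#' @param resolution raster resolution passed to [projected_area_2d()].
#' @return object of class `rfi_result`: list with `area_3d`, `area_2d`,
#'   `rfi_ratio`, `rfi_x100`, `rfi_ln`, `resolution`.
#' @export
compute_rfi <- function(mesh, resolution = 1000L) {
  stopifnot_mesh(mesh)
  a3 <- surface_area_3d(mesh)
  a2 <- projected_area_2d(mesh, resolution)
  ratio <- a3 / a2
  structure(list(area_3d = a3, area_2d = a2,
                 rfi_ratio = ratio, rfi_x100 = 100 * ratio,
                 rfi_ln = log(ratio), resolution = as.integer(resolution)),
            class = "rfi_result")
}

#' @export
print.rfi_result <- function(x, ...) {
  cat(sprintf("<rfi_result: 3da %.6g, 2da %.6g, RFI %.4f (x100 %.2f, ln %.4f)>\n",
              x$area_3d, x$area_2d, x$rfi_ratio, x$rfi_x100, x$rfi_ln))
  invisible(x)
}
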