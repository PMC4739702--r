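#' Read an ASCII Stanford PLY mesh
#'
#' Parses an ASCII-encoded Stanford Triangle / Polygon File Format (PLY)
#' file into a [tri_mesh()]. The first three numeric vertex properties are
#' taken as x, y, z; any further vertex properties (stored normals, colors)
#' are skipped because downstream metrics recompute normals from geometry
#' and stored values are untrusted. Faces must be triangles: faces declared
#' with more (or fewer) than 3 vertices are rejected rather than silently
#' re-triangulated, since re-triangulation would change every metric value.
#'
#' @param source path to a PLY file, or a connection.
#' @param name specimen identifier; defaults to the file base name.
#' @return a [tri_mesh()].
#' @seealso [convert_binary_to_ascii()] for binary-encoded PLY files.
#' @export
read_ply <- function(source, name = NULL) {
  if (is.character(source)) {
    if (is.null(name)) name <- sub("\\.[Pp][Ll][Yy]$", "", basename(source))
    lines <- readLines(source, warn = FALSE)
  } else {
    if (is.null(name)) name <- "mesh"
    lines <- readLines(source, warn = FALSE)
  }
  if (length(lines) == 0L || trimws(lines[1L]) != "ply")
    stop("not a PLY file: missing 'ply' magic on line 1")
  hdr_end <- which(trimws(lines) == "end_header")
  if (length(hdr_end) == 0L)
    stop("malformed PLY header: no 'end_header' line")
  hdr_end <- hdr_end[1L]
  hdr <- parse_ply_header(lines[seq_len(hdr_end)])
  if (hdr$format %in% c("binary_little_endian", "binary_big_endian"))
    stop("PLY file uses binary encoding ('", hdr$format, "'); ",
         "convert it with convert_binary_to_ascii() first")
  if (hdr$format != "ascii")
    stop("unsupported PLY format '", hdr$format, "'")

  el_names <- vapply(hdr$elements, `[[`, "", "name")
  iv <- match("vertex", el_names)
  ifc <- match("face", el_names)
  if (is.na(iv) || is.na(ifc))
    stop("PLY header must declare both 'element vertex' and 'element face'")

  body <- lines[-seq_len(hdr_end)]
  body <- body[nzchar(trimws(body))]
  # body rows appear in element declaration order
  offset <- 0L
  vertices <- faces <- NULL
  for (el in hdr$elements) {
    rows <- body[offset + seq_len(el$count)]
    if (el$count > 0L && (length(rows) < el$count || anyNA(rows)))
      stop("PLY body ended early: element '", el$name, "' declares ",
           el$count, " rows but the file has ",
           length(body) - offset, " (after body line ", offset, ")")
    if (el$name == "vertex") {
      nprop <- length(el$properties)
      if (any(vapply(el$properties, `[[`, TRUE, "is_list")))
        stop("list-typed vertex properties are not supported")
      if (nprop < 3L)
        stop("element vertex must carry at least 3 numeric properties (x, y, z)")
      toks <- scan(text = rows, what = numeric(), quiet = TRUE)
      if (length(toks) != el$count * nprop)
        stop("vertex rows malformed near body line ", offset + 1L,
             ": expected ", el$count * nprop, " numbers, found ", length(toks))
      vertices <- matrix(toks, ncol = nprop, byrow = TRUE)[, 1:3, drop = FALSE]
    } else if (el$name == "face") {
      toklist <- strsplit(trimws(rows), "[[:space:]]+")
      cnt <- vapply(toklist, function(t) suppressWarnings(as.integer(t[1L])), 1L)
      if (anyNA(cnt))
        stop("face rows malformed near body line ", offset + 1L)
      bad <- which(cnt != 3L)
      if (length(bad))
        stop("non-triangular face (", cnt[bad[1L]], " vertices) at face row ",
             bad[1L], "; only triangle meshes are supported")
      idx <- t(vapply(toklist, function(t) as.integer(t[2:4]), integer(3L)))
      faces <- idx + 1L  # PLY is 0-based
    }
    offset <- offset + el$count
  }
  tri_mesh(vertices, faces, name = name)
}

parse_ply_header <- function(hdr_lines) {
  format <- NULL
  elements <- list()
  cur <- NULL
  for (i in seq_along(hdr_lines)) {
    tok <- strsplit(trimws(hdr_lines[i]), "[[:space:]]+")[[1L]]
    if (length(tok) == 0L || tok[1L] %in% c("ply", "comment", "obj_info", "end_header"))
      next
    if (tok[1L] == "format") {
      format <- tok[2L]
    } else if (tok[1L] == "element") {
      if (!is.null(cur)) elements[[length(elements) + 1L]] <- cur
      cnt <- suppressWarnings(as.integer(tok[3L]))
      if (is.na(cnt)) stop("malformed element count on header line ", i)
      cur <- list(name = tok[2L], count = cnt, properties = list())
    } else if (tok[1L] == "property") {
      if (is.null(cur)) stop("property before any element on header line ", i)
      if (tok[2L] == "list") {
        p <- list(name = tok[5L], is_list = TRUE,
                  count_type = tok[3L], index_type = tok[4L])
      } else {
        p <- list(name = tok[3L], is_list = FALSE, type = tok[2L])
      }
      cur$properties[[length(cur$properties) + 1L]] <- p
    } else {
      stop("unrecognized PLY header keyword '", tok[1L], "' on line ", i)
    }
  }
  if (!is.null(cur)) elements[[length(elements) + 1L]] <- cur
  if (is.null(format)) stop("malformed PLY header: no 'format' line")
  list(format = format, elements = elements)
}

#' Write a mesh as ASCII PLY
#'
#' Emits a minimal ASCII Stanford PLY file: x, y, z vertex properties and
#' triangular vertex index lists (0-based on disk). Coordinates are written
#' with `digits` significant digits; the default of 6 exceeds typical
#' surface-scanner precision while keeping files diff-able.
#'
#' @param mesh a [tri_mesh()].
#' @param dest output file path.
#' @param digits significant digits for coordinates.
#' @return `dest`, invisibly.
#' @export
write_ply <- function(mesh, dest, digits = 6L) {
  stopifnot_mesh(mesh)
  hdr <- c("ply", "format ascii 1.0",
           paste("element vertex", n_vertices(mesh)),
           "property float x", "property float y", "property float z",
           paste("element face", n_faces(mesh)),
           "property list uchar int vertex_indices",
           "end_header")
  fmt <- sprintf("%%.%dg", as.integer(digits))
  vrows <- sprintf(paste(fmt, fmt, fmt),
                   mesh$vertices[, 1L], mesh$vertices[, 2L], mesh$vertices[, 3L])
  frows <- sprintf("3 %d %d %d",
                   mesh$faces[, 1L] - 1L, mesh$faces[, 2L] - 1L, mesh$faces[, 3L] - 1L)
  writeLines(c(hdr, vrows, frows), dest)
  invisible(dest)
}

#' Write a mesh in OFF format
#'
#' Standard Object File Format: an `OFF` magic line, a `V F E` counts line
#' (the edge count is conventionally written as 0), vertex rows, then face
#' rows `3 i j k` with 0-based indices.
#'
#' @inheritParams write_ply
#' @return `dest`, invisibly.
#' @export
write_off <- function(mesh, dest, digits = 6L) {
  stopifnot_mesh(mesh)
  fmt <- sprintf("%%.%dg", as.integer(digits))
  vrows <- sprintf(paste(fmt, fmt, fmt),
                   mesh$vertices[, 1L], mesh$vertices[, 2L], mesh$vertices[, 3L])
  frows <- sprintf("3 %d %d %d",
                   mesh$faces[, 1L] - 1L, mesh$faces[, 2L] - 1L, mesh$faces[, 3L] - 1L)
  writeLines(c("OFF",
               paste(n_vertices(mesh), n_faces(mesh), 0L),
               vrows, frows), dest)
  invisible(dest)
}

#' Results table columns
#'
#' Fixed column set of the batch results spreadsheet, in output order.
#' @keywords internal
RESULT_COLUMNS <- c("Specimen", "DNE", "RFI", "3DArea", "2DArea", "OPCR",
                    paste0("OPC_r", 0:7))

#' Write topographic results as a tab-separated table
#'
#' One row per specimen, columns `Specimen, DNE, RFI, 3DArea, 2DArea, OPCR,
#' OPC_r0 ... OPC_r7` (per-rotation orientation patch counts). Metrics that
#' were not computed are written as `NA`.
#'
#' @param records data.frame of results as produced by [run_batch()] /
#'   [analyze_mesh()]; must contain a `Specimen` column and at least one row.
#' @param dest output file path.
#' @return `dest`, invisibly.
#' @export
write_results_tsv <- function(records, dest) {
  records <- as.data.frame(records)
  if (nrow(records) == 0L) stop("no result records to write")
  if (!"Specimen" %in% names(records)) stop("records must have a Specimen column")
  for (cn in RESULT_COLUMNS)
    if (!cn %in% names(records)) records[[cn]] <- NA_real_
  records <- records[, RESULT_COLUMNS, drop = FALSE]
  utils::write.table(records, dest, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(dest)
}
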