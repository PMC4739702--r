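ply_type_size <- c(char = 1L, int8 = 1L, uchar = 1L, uint8 = 1L,
                   short = 2L, int16 = 2L, ushort = 2L, uint16 = 2L,
                   int = 4L, int32 = 4L, uint = 4L, uint32 = 4L,
                   float = 4L, float32 = 4L, double = 8L, float64 = 8L)

read_ply_scalar <- function(raw, offset, type, endian) {
  sz <- ply_type_size[[type]]
  bytes <- raw[(offset + 1L):(offset + sz)]
  val <- switch(type,
    char = , int8 = readBin(bytes, "integer", 1L, size = 1L, signed = TRUE),
    uchar = , uint8 = readBin(bytes, "integer", 1L, size = 1L, signed = FALSE),
    short = , int16 = readBin(bytes, "integer", 1L, size = 2L, signed = TRUE,
                              endian = endian),
    ushort = , uint16 = readBin(bytes, "integer", 1L, size = 2L, signed = FALSE,
                                endian = endian),
    int = , int32 = , uint = , uint32 =
      readBin(bytes, "integer", 1L, size = 4L, endian = endian),
    float = , float32 = readBin(bytes, "double", 1L, size = 4L, endian = endian),
    double = , float64 = readBin(bytes, "double", 1L, size = 8L, endian = endian),
    stop("unsupported PLY property type '", type, "'"))
  if (type %in% c("uint", "uint32") && val < 0)
    stop("uint32 value exceeds R's integer range")
  val
}

#' Convert a binary PLY file to ASCII encoding
#'
#' Decodes a little- or big-endian binary Stanford PLY file (scalar numeric
#' vertex properties, list-typed triangular face indices) and re-emits it as
#' ASCII PLY. Vertex coordinates are written with 9 significant digits so
#' that float32 payloads round-trip exactly through the decimal
#' representation; face indices are preserved verbatim. Some mesh-editing
#' applications only save binary PLY, while the analysis functions here read
#' the ASCII encoding.
#'
#' @param source path to a binary PLY file.
#' @param dest output path for the ASCII PLY file.
#' @return `dest`, invisibly.
#' @export
convert_binary_to_ascii <- function(source, dest) {
  raw <- readBin(source, "raw", n = file.info(source)$size)
  # header is ASCII text terminated by an "end_header" line; the payload
  # after it is binary, so locate the terminator on the raw bytes
  hit <- grepRaw("end_header\n", raw, fixed = TRUE)
  pat_len <- 11L
  if (length(hit) == 0L) {
    hit <- grepRaw("end_header\r\n", raw, fixed = TRUE)
    pat_len <- 12L
  }
  if (length(hit) == 0L)
    stop("malformed PLY header: no 'end_header' line found")
  hdr_nbytes <- hit[1L] + pat_len - 1L
  hdr_lines <- strsplit(rawToChar(raw[seq_len(hdr_nbytes)]), "\r?\n")[[1L]]
  if (length(hdr_lines) == 0L || trimws(hdr_lines[1L]) != "ply")
    stop("not a PLY file: missing 'ply' magic")
  hdr <- parse_ply_header(hdr_lines)
  if (hdr$format == "ascii")
    stop("file is already ASCII encoded; no conversion needed")
  endian <- switch(hdr$format,
                   binary_little_endian = "little",
                   binary_big_endian = "big",
                   stop("unsupported PLY format '", hdr$format, "'"))

  offset <- hdr_nbytes
  total <- length(raw)
  need <- function(nbytes) {
    if (offset + nbytes > total)
      stop("binary PLY payload truncated at byte ", offset,
           " (need ", nbytes, " more, have ", total - offset, ")")
  }
  vertices <- NULL
  faces <- NULL
  for (el in hdr$elements) {
    if (el$name == "vertex") {
      for (p in el$properties)
        if (p$is_list) stop("unsupported list-typed vertex property '", p$name, "'")
      types <- vapply(el$properties, `[[`, "", "type")
      bad <- setdiff(types, names(ply_type_size))
      if (length(bad)) stop("unsupported PLY property type '", bad[1L], "'")
      sizes <- ply_type_size[types]
      stride <- sum(sizes)
      need(el$count * stride)
      if (all(types == types[1L])) {
        # uniform type: bulk decode
        n <- el$count * length(types)
        what <- if (types[1L] %in% c("float", "float32", "double", "float64"))
          "double" else "integer"
        vals <- readBin(raw[(offset + 1L):(offset + el$count * stride)],
                        what, n = n, size = sizes[1L], endian = endian)
        mat <- matrix(vals, ncol = length(types), byrow = TRUE)
      } else {
        mat <- matrix(0, el$count, length(types))
        for (i in seq_len(el$count)) {
          for (j in seq_along(types)) {
            mat[i, j] <- read_ply_scalar(raw, offset, types[j], endian)
            offset <- offset + sizes[j]
          }
        }
        offset <- offset - el$count * stride  # advanced below uniformly
      }
      offset <- offset + el$count * stride
      vertices <- mat[, 1:3, drop = FALSE]
    } else if (el$name == "face") {
      lp <- Filter(function(p) p$is_list, el$properties)
      if (length(lp) != 1L || length(el$properties) != 1L)
        stop("element face must carry exactly one list property of vertex indices")
      lp <- lp[[1L]]
      csz <- ply_type_size[[lp$count_type]]
      isz <- ply_type_size[[lp$index_type]]
      if (is.null(csz) || is.null(isz))
        stop("unsupported PLY property type in face list")
      faces <- matrix(0L, el$count, 3L)
      for (i in seq_len(el$count)) {
        need(csz)
        k <- read_ply_scalar(raw, offset, lp$count_type, endian)
        offset <- offset + csz
        if (k != 3L)
          stop("non-triangular face (", k, " vertices) at face ", i)
        need(3L * isz)
        for (j in 1:3) {
          faces[i, j] <- read_ply_scalar(raw, offset, lp$index_type, endian)
          offset <- offset + isz
        }
      }
    } else {
      stop("unsupported element '", el$name, "' in binary PLY")
    }
  }
  if (is.null(vertices) || is.null(faces))
    stop("binary PLY must declare vertex and face elements")
  mesh <- tri_mesh(vertices, faces + 1L,
                   name = sub("\\.[Pp][Ll][Yy]$", "", basename(source)))
  write_ply(mesh, dest, digits = 9L)
  invisible(dest)
}
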