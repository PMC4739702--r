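test_that("minimal ASCII PLY parses to the declared mesh", {
  f <- withr::local_tempfile(fileext = ".ply")
  writeLines(minimal_ply_text, f)
  m <- read_ply(f)
  expect_s3_class(m, "tri_mesh")
  expect_equal(nrow(m$vertices), 3L)
  expect_equal(nrow(m$faces), 1L)
  expect_equal(m$vertices, rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)))
  expect_equal(m$faces, matrix(c(1L, 2L, 3L), 1L))
})

test_that("extra vertex properties are tolerated and skipped", {
  f <- withr::local_tempfile(fileext = ".ply")
  writeLines(c(
    "ply", "format ascii 1.0",
    "comment normals and colors present",
    "element vertex 3",
    "property float x", "property float y", "property float z",
    "property float nx", "property float ny", "property float nz",
    "element face 1",
    "property list uchar int vertex_indices",
    "end_header",
    "0 0 0 0 0 1", "1 0 0 0 0 1", "0 1 0 0 0 1",
    "3 0 1 2"), f)
  m <- read_ply(f)
  expect_equal(ncol(m$vertices), 3L)
  expect_equal(m$vertices[2, ], c(1, 0, 0))
})

test_that("PLY write/read round-trip is an identity", {
  mesh <- make_icosphere(1)
  f1 <- withr::local_tempfile(fileext = ".ply")
  f2 <- withr::local_tempfile(fileext = ".ply")
  write_ply(mesh, f1)
  m1 <- read_ply(f1)
  write_ply(m1, f2)
  m2 <- read_ply(f2)
  expect_identical(m1$faces, mesh$faces)
  expect_identical(m2$vertices, m1$vertices)
  expect_identical(m2$faces, m1$faces)
  # written coordinates preserved to the emitted precision
  expect_equal(m1$vertices, mesh$vertices, tolerance = 1e-5)
})

test_that("quad faces and malformed files are rejected with clear errors", {
  f <- withr::local_tempfile(fileext = ".ply")
  writeLines(c(
    "ply", "format ascii 1.0",
    "element vertex 4",
    "property float x", "property float y", "property float z",
    "element face 1",
    "property list uchar int vertex_indices",
    "end_header",
    "0 0 0", "1 0 0", "1 1 0", "0 1 0",
    "4 0 1 2 3"), f)
  expect_error(read_ply(f), "non-triangular face")

  writeLines(c(minimal_ply_text[1:9], "1 0 0", "3 0 1 2"), f)  # vertex missing
  expect_error(read_ply(f), "malformed|ended early|expected")

  writeLines(c("solid not_a_ply"), f)
  expect_error(read_ply(f), "magic")
})

test_that("binary-encoded PLY is refused by read_ply with a pointer to conversion", {
  f <- withr::local_tempfile(fileext = ".ply")
  write_binary_ply(f, rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                   matrix(c(0L, 1L, 2L), 1L))
  expect_error(read_ply(f), "binary.*convert_binary_to_ascii")
})

test_that("binary to ASCII conversion reproduces the payload in both endiannesses", {
  # coordinates exactly representable in float32
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0.5, 0.25, -1.75))
  f0 <- rbind(c(0L, 1L, 2L), c(1L, 3L, 2L))
  for (endian in c("little", "big")) {
    bin <- withr::local_tempfile(fileext = ".ply")
    asc <- withr::local_tempfile(fileext = ".ply")
    write_binary_ply(bin, v, f0, endian = endian)
    convert_binary_to_ascii(bin, asc)
    m <- read_ply(asc)
    expect_equal(m$vertices, v, ignore_attr = TRUE)
    expect_identical(m$faces, f0 + 1L, ignore_attr = TRUE)
  }
})

test_that("conversion rejects ASCII input and truncated payloads", {
  asc <- withr::local_tempfile(fileext = ".ply")
  writeLines(minimal_ply_text, asc)
  expect_error(convert_binary_to_ascii(asc, tempfile()), "already ASCII")

  bin <- withr::local_tempfile(fileext = ".ply")
  write_binary_ply(bin, rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                   matrix(c(0L, 1L, 2L), 1L))
  raw <- readBin(bin, "raw", file.info(bin)$size)
  trunc <- withr::local_tempfile(fileext = ".ply")
  writeBin(raw[1:(length(raw) - 7L)], trunc)
  expect_error(convert_binary_to_ascii(trunc, tempfile()), "truncated")
})

test_that("OFF export follows the format definition", {
  mesh <- tri_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                   matrix(c(1L, 2L, 3L), 1L))
  f <- withr::local_tempfile(fileext = ".off")
  write_off(mesh, f)
  lines <- readLines(f)
  expect_identical(lines[1], "OFF")
  expect_identical(lines[2], "3 1 0")
  expect_identical(lines[6], "3 0 1 2")
  # coordinates preserved to at least 6 significant digits
  mesh2 <- tri_mesh(rbind(c(0.123456789, 0, 0), c(1, 2.71828183, 0),
                          c(0, 1, 3.14159265)),
                    matrix(c(1L, 2L, 3L), 1L))
  write_off(mesh2, f)
  vals <- scan(f, skip = 2, nlines = 3, quiet = TRUE)
  expect_equal(matrix(vals, 3, 3, byrow = TRUE), mesh2$vertices,
               tolerance = 1e-5)
})

test_that("degenerate meshes are rejected at construction", {
  expect_error(tri_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                        matrix(integer(), 0L, 3L)), "at least 1 face")
  expect_error(tri_mesh(rbind(c(0, 0, 0), c(1, 0, 0)),
                        matrix(c(1L, 2L, 2L), 1L)), "at least 3 vertices")
  expect_error(tri_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                        matrix(c(1L, 2L, 2L), 1L)), "distinct")
  expect_error(tri_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                        matrix(c(1L, 2L, 4L), 1L)), "face indices")
})

test_that("results TSV has the documented layout and NA handling", {
  rec1 <- analyze_mesh(make_plane(5, 5, tilt_deg = 30), metrics = "OPCR")
  rec2 <- analyze_mesh(make_plane(5, 5, tilt_deg = 30), metrics = c("DNE", "RFI"),
                       rfi_resolution = 100)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_results_tsv(rbind(rec1, rec2), f)
  lines <- readLines(f)
  expect_length(lines, 3L)
  expect_identical(strsplit(lines[1], "\t")[[1]],
                   c("Specimen", "DNE", "RFI", "3DArea", "2DArea", "OPCR",
                     paste0("OPC_r", 0:7)))
  tab <- utils::read.delim(f, check.names = FALSE)
  expect_true(is.na(tab$DNE[1]) && is.na(tab$RFI[1]))
  expect_true(is.na(tab$OPCR[2]) && !is.na(tab$RFI[2]))
  # reparse reproduces numeric values
  expect_equal(tab$OPCR[1], rec1$OPCR, tolerance = 1e-6)
  expect_equal(tab$RFI[2], rec2$RFI, tolerance = 1e-6)
  expect_error(write_results_tsv(rec1[0, ], f), "no result records")
})
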