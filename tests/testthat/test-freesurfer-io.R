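# Bit-exact reading and writing of the three FreeSurfer binary families.

test_that("surface round-trip preserves a tetrahedron exactly", {
  v <- matrix(c(0, 0, 0, 1, 0, 0, 0, 1, 0, 0, 0, 1), 4, 3, byrow = TRUE)
  f <- matrix(c(1, 2, 3, 1, 2, 4, 1, 3, 4, 2, 3, 4), 4, 3, byrow = TRUE)
  surf <- fs_surface(v, f)
  path <- withr::local_tempfile(fileext = ".pial")
  write_surface(surf, path)
  back <- read_surface(path)
  expect_identical(back$faces, surf$faces)
  expect_equal(back$vertices, surf$vertices)  # float32 exact for these values
})

test_that("a handcrafted byte-level surface file parses to exact coordinates", {
  # written independently of write_surface: raw big-endian bytes
  path <- withr::local_tempfile(fileext = ".surf")
  con <- file(path, "wb")
  writeBin(as.integer(c(255, 255, 254)), con, size = 1L)         # magic
  writeBin(charToRaw("x\n\n"), con)                              # comment
  writeBin(c(3L, 1L), con, size = 4L, endian = "big")            # nv, nf
  writeBin(c(0, 0, 0, 1, 0, 0, 0, 1, 0), con, size = 4L, endian = "big")
  writeBin(c(0L, 1L, 2L), con, size = 4L, endian = "big")        # 0-based
  close(con)
  surf <- read_surface(path)
  expect_equal(surf$vertices,
               matrix(c(0, 0, 0, 1, 0, 0, 0, 1, 0), 3, 3, byrow = TRUE))
  expect_identical(surf$faces, matrix(c(1L, 2L, 3L), 1, 3))
})

test_that("quad magic and corrupted magic raise format errors, never misparse", {
  path <- withr::local_tempfile()
  con <- file(path, "wb")
  writeBin(as.integer(c(255, 255, 255)), con, size = 1L)  # quad magic
  writeBin(raw(64), con)
  close(con)
  expect_error(read_surface(path), "quad")

  good <- withr::local_tempfile()
  write_surface(fs_surface(diag(3), matrix(1:3, 1)), good)
  bytes <- readBin(good, "raw", file.size(good))
  bytes[2] <- as.raw(0L)
  writeBin(bytes, good)
  expect_error(read_surface(good), "format error")
})

test_that("annotation round-trip preserves labels and the name table", {
  tab <- annot_table(c("Unknown", "S_central", "S_postcentral"))
  labels <- c(tab$code[2], tab$code[2], 0L, tab$code[3], rep(0L, 4))
  ann <- fs_annotation(labels, tab)
  path <- withr::local_tempfile(fileext = ".annot")
  write_annotation(ann, path)
  back <- read_annotation(path)
  expect_identical(back$table$name, tab$name)
  expect_identical(back$table$code, tab$code)
  # vertices labelled "Unknown" by code come back as the no-label id 0
  expect_identical(back$labels[3], 0L)
  expect_identical(back$labels[c(1, 2, 4)], labels[c(1, 2, 4)])
})

test_that("annotation lookup by the printed Destrieux names succeeds", {
  tab <- annot_table(c("Unknown", "S_central", "S_postcentral", "S_front_sup"))
  ann <- fs_annotation(rep(tab$code[2], 5), tab)
  path <- withr::local_tempfile(fileext = ".annot")
  write_annotation(ann, path)
  back <- read_annotation(path)
  for (nm in c("S_central", "S_postcentral", "S_front_sup")) {
    expect_true(nm %in% back$table$name)
  }
})

test_that("annotation without a colour table is rejected", {
  path <- withr::local_tempfile(fileext = ".annot")
  con <- file(path, "wb")
  writeBin(1L, con, size = 4L, endian = "big")
  writeBin(c(0L, 0L), con, size = 4L, endian = "big")
  writeBin(0L, con, size = 4L, endian = "big")  # tag: no ctab
  close(con)
  expect_error(read_annotation(path), "colour table")
})

test_that("overlay round-trip preserves values; count mismatch errors", {
  path <- withr::local_tempfile(fileext = ".sulc")
  write_overlay(c(0.5, -1.25, 3.0), path)
  expect_identical(read_overlay(path), c(0.5, -1.25, 3.0))
  expect_error(read_overlay(path, expected_n = 4L), "expected")
})

test_that("randomised round-trips preserve values to stored precision", {
  set.seed(101)
  vals <- rnorm(10000) * 100
  path <- withr::local_tempfile(fileext = ".sulc")
  write_overlay(vals, path)
  # float32 storage: relative precision ~2^-24
  expect_equal(read_overlay(path), vals, tolerance = 1e-6)

  for (rep in 1:5) {
    nv <- sample(4:40, 1)
    v <- matrix(rnorm(3 * nv), nv, 3)
    nf <- sample(1:30, 1)
    f <- t(replicate(nf, sample.int(nv, 3)))
    surf <- fs_surface(v, f)
    sp <- withr::local_tempfile()
    write_surface(surf, sp)
    back <- read_surface(sp)
    expect_identical(back$faces, surf$faces)
    expect_equal(back$vertices, surf$vertices, tolerance = 1e-6)

    tab <- annot_table(c("Unknown", "A", "B", "C"))
    labels <- sample(c(0L, tab$code[-1]), nv, replace = TRUE)
    ap <- withr::local_tempfile()
    write_annotation(fs_annotation(labels, tab), ap)
    expect_identical(read_annotation(ap)$labels, labels)
  }
})

test_that("writers validate invariants before writing", {
  expect_error(fs_surface(matrix(0, 0, 3), matrix(1:3, 1)), "n >= 3")
  expect_error(fs_surface(diag(3), matrix(c(1, 1, 2), 1)), "distinct")
  expect_error(fs_surface(diag(3), matrix(c(1, 2, 4), 1)), "out of range")
  expect_error(write_overlay(c(1, NaN), withr::local_tempfile()), "finite")
  expect_error(write_overlay(numeric(0), withr::local_tempfile()), "non-empty")
})

test_that("files interoperate with an independent reader/writer (nibabel)", {
  py <- Sys.which("python")
  expect_true(nzchar(py))
  d <- withr::local_tempdir()
  set.seed(7)
  surf <- fs_surface(matrix(rnorm(30), 10, 3),
                     matrix(c(1, 2, 3, 2, 3, 4, 5, 6, 7, 8, 9, 10),
                            4, 3, byrow = TRUE))
  write_surface(surf, file.path(d, "t.surf"))
  write_overlay(c(1.5, -2.25, 3), file.path(d, "t.sulc"))
  tab <- annot_table(c("Unknown", "S_central"))
  write_annotation(fs_annotation(c(tab$code[2], rep(0L, 9)), tab),
                   file.path(d, "t.annot"))
  script <- sprintf("
import numpy as np, nibabel.freesurfer.io as fsio
d = %s
v, f = fsio.read_geometry(d + '/t.surf')
assert v.shape == (10, 3) and f.shape == (4, 3) and f.min() == 0
m = fsio.read_morph_data(d + '/t.sulc')
assert np.allclose(m, [1.5, -2.25, 3])
labels, ctab, names = fsio.read_annot(d + '/t.annot')
assert names[1] == b'S_central' and labels[0] == 1
fsio.write_geometry(d + '/n.surf', v, f)
fsio.write_morph_data(d + '/n.sulc', m)
print('OK')", deparse(d))
  out <- system2(py, "-", input = script, stdout = TRUE, stderr = TRUE)
  expect_true(any(grepl("^OK$", out)), info = paste(out, collapse = "\n"))
  nib <- read_surface(file.path(d, "n.surf"))
  expect_identical(nib$faces, surf$faces)
  expect_equal(nib$vertices, surf$vertices, tolerance = 1e-6)
  expect_equal(read_overlay(file.path(d, "n.sulc")), c(1.5, -2.25, 3))
})
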