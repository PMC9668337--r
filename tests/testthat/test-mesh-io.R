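# Mesh readers/writers and topology validation.

test_that("OFF read/write round-trips exactly and enforces triangles", {
  tet <- tetrahedron()
  p <- withr::local_tempfile(fileext = ".off")
  writeSurface(tet, p, format = "off")
  lines <- readLines(p)
  expect_identical(lines[1], "OFF")
  expect_identical(lines[2], "4 4 0")
  back <- readSurface(p, format = "off")
  expect_identical(meshVertices(back), meshVertices(tet))
  expect_identical(meshFaces(back), meshFaces(tet))
  # auto-detection
  expect_identical(meshFaces(readSurface(p)), meshFaces(tet))
  # quad face is a format error
  quad <- c("OFF", "4 1 0",
            "0 0 0", "1 0 0", "1 1 0", "0 1 0", "4 0 1 2 3")
  pq <- withr::local_tempfile(fileext = ".off")
  writeLines(quad, pq)
  expect_error(readSurface(pq), "non-triangular")
})

test_that("PLY ascii and binary round-trip through a float32 quantum", {
  ico <- icosphere(0)
  for (fmt in c("ply", "ply_binary")) {
    p <- withr::local_tempfile(fileext = ".ply")
    writeSurface(ico, p, format = fmt)
    back <- readSurface(p, format = "ply")
    expect_equal(nVertices(back), 12L)
    expect_equal(nFaces(back), 20L)
    expect_identical(meshFaces(back), meshFaces(ico))
    expect_equal(meshVertices(back), meshVertices(ico),
                 tolerance = 1e-6)
    # writing the already-quantized mesh again is lossless
    p2 <- withr::local_tempfile(fileext = ".ply")
    writeSurface(back, p2, format = fmt)
    again <- readSurface(p2)
    expect_identical(meshVertices(again), meshVertices(back))
  }
  # ascii PLY has 12 vertex records and 20 face records
  p <- withr::local_tempfile(fileext = ".ply")
  writeSurface(ico, p, format = "ply")
  body <- readLines(p)
  hdrEnd <- which(body == "end_header")
  expect_length(body, hdrEnd + 32L)
})

test_that("FreeSurfer binary surfaces round-trip and match an independent writer", {
  ico <- icosphere(1)
  p <- withr::local_tempfile()
  writeSurface(ico, p, format = "freesurfer")
  back <- readSurface(p)                 # magic-number detection
  expect_identical(meshFaces(back), meshFaces(ico))
  expect_equal(meshVertices(back), meshVertices(ico), tolerance = 1e-6)
  # independent byte-level writer of the same format
  p2 <- withr::local_tempfile()
  con <- file(p2, "wb")
  writeBin(as.raw(c(0xff, 0xff, 0xfe)), con)
  writeBin(charToRaw("elsewhere\n\n"), con)
  vq <- meshVertices(back)               # already float32-exact
  writeBin(c(nVertices(back), nFaces(back)), con, size = 4,
           endian = "big")
  writeBin(as.numeric(t(vq)), con, size = 4, endian = "big")
  writeBin(as.integer(t(meshFaces(back) - 1L)), con, size = 4,
           endian = "big")
  close(con)
  indep <- readSurface(p2)
  expect_identical(meshVertices(indep), meshVertices(back))
  expect_identical(meshFaces(indep), meshFaces(back))
})

test_that("empty meshes are refused and unreadable files raise I/O errors", {
  expect_error(writeSurface(TriangleMesh(matrix(0, 0, 3),
                                         matrix(0L, 0, 3)),
                            tempfile(), format = "off"), "empty")
  expect_error(readSurface(file.path(tempdir(), "no_such_mesh.off")),
               "not found")
})

test_that("validateMesh reports closedness, boundaries and genus", {
  rep0 <- validateMesh(icosphere(2))
  expect_true(rep0$closed)
  expect_true(rep0$manifold)
  expect_true(rep0$oriented)
  expect_identical(rep0$genus, 0L)

  holey <- icosphere(1)
  holey@faces <- holey@faces[-1, , drop = FALSE]
  rep1 <- validateMesh(holey)
  expect_false(rep1$closed)
  expect_identical(nrow(rep1$boundary_edges), 3L)

  expect_identical(validateMesh(torusMesh())$genus, 1L)
})

test_that("validateMesh passes for icospheres at all tested levels", {
  for (s in 0:4) {
    r <- validateMesh(icosphere(s))
    expect_true(r$closed && r$manifold && r$oriented && r$genus == 0L,
                info = paste("subdivision", s))
  }
})

test_that("orientation repair restores consistent outward winding", {
  ico <- icosphere(1)
  scrambled <- ico
  flip <- c(3, 10, 40)
  scrambled@faces[flip, ] <- scrambled@faces[flip, c(1, 3, 2)]
  expect_false(validateMesh(scrambled)$oriented)
  expect_warning(fixed <- repairOrientation(scrambled), "flipped")
  expect_true(validateMesh(fixed)$oriented)
  expect_gt(shapeAsym:::.signedVolume(fixed), 0)
})

test_that("spectra tables round-trip with keys, tag and full precision", {
  set.seed(42)
  info <- data.frame(subject = c("s1", "s1", "s2"),
                     session = c("t1", "t1", "t1"),
                     hemi = c("L", "R", "L"))
  tab <- SpectraTable(info, matrix(rexp(30), 3, 10),
                      normalization = "area")
  p <- withr::local_tempfile(fileext = ".csv")
  writeTable(tab, p)
  back <- readTable(p, schema = "spectra")
  expect_equal(dim(spectraValues(back)), c(3L, 10L))
  expect_identical(back@normalization, "area")
  expect_identical(spectraInfo(back)$hemi, info$hemi)
  expect_equal(spectraValues(back), spectraValues(tab),
               tolerance = 1e-15)
  # tab-separated variant auto-detects
  pt <- withr::local_tempfile(fileext = ".tsv")
  writeTable(tab, pt)
  expect_equal(spectraValues(readTable(pt, schema = "spectra")),
               spectraValues(tab), tolerance = 1e-15)
})

test_that("table schemas enforce their key columns", {
  p <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(subject = "a", family = "f"), p,
            row.names = FALSE)
  expect_error(readTable(p, schema = "pedigree"), "zygosity")
  expect_error(readTable(p, schema = "spectra"), "session")
  ph <- readTable(p, schema = "phenotypes")
  expect_identical(ph$subject, "a")
})
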