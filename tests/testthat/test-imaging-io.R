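test_that("NIfTI write/read round-trips data and geometry", {
  td <- withr::local_tempdir()
  vol <- image_volume(array(seq_len(24 * 20 * 10), dim = c(24, 20, 10)),
                      spacing = c(0.419, 0.419, 1), origin = c(-5, 3, 7))
  f <- file.path(td, "v.nii.gz")
  write_volume(vol, f)
  v2 <- read_volume(f)
  expect_equal(v2$spacing, c(0.419, 0.419, 1))
  expect_equal(v2$origin, c(-5, 3, 7))
  expect_identical(dim(v2$data), dim(vol$data))
  expect_equal(as.numeric(v2$data), as.numeric(vol$data))
  expect_equal(sum(v2$data), sum(vol$data))   # intensity sum preserved
})

test_that("volume constructor enforces its invariants", {
  expect_error(image_volume(array(1, c(4, 4)), c(1, 1, 1)), "3D")
  expect_error(image_volume(array(1, c(4, 4, 1)), c(1, 1, 1)), "at least 2")
  expect_error(image_volume(array(1, c(4, 4, 4)), c(1, -1, 1)), "positive")
  expect_error(image_volume(array(c(NA, rep(1, 63)), c(4, 4, 4)), c(1, 1, 1)),
               "finite")
  expect_error(read_volume(file.path(tempdir(), "nope.nii")), "no such path")
})

test_that("DICOM series reading recovers dimensions, spacing and voxels", {
  td <- withr::local_tempdir()
  set.seed(7)
  arr <- write_dicom_series(file.path(td, "s"), nx = 16, ny = 12, nz = 5,
                            spacing = c(0.7, 0.5, 2), origin = c(1, 2, 3))
  v <- read_volume(file.path(td, "s"))
  expect_identical(dim(v$data), c(16L, 12L, 5L))
  expect_equal(v$spacing, c(0.7, 0.5, 2))
  expect_equal(v$origin, c(1, 2, 3))
  expect_equal(as.integer(v$data), as.integer(arr))
})

test_that("DICOM geometry errors are caught", {
  td <- withr::local_tempdir()
  d <- file.path(td, "bad"); dir.create(d)
  write_dicom_slice(file.path(d, "a.dcm"), matrix(0L, 4, 4), ipp = c(0, 0, 0))
  write_dicom_slice(file.path(d, "b.dcm"), matrix(0L, 4, 4), ipp = c(0, 0, 1))
  write_dicom_slice(file.path(d, "c.dcm"), matrix(0L, 4, 4), ipp = c(0, 0, 3))
  expect_error(read_volume(d), "inconsistent slice spacing")
  d2 <- file.path(td, "rot"); dir.create(d2)
  ang <- cos(pi / 7); s <- sin(pi / 7)
  write_dicom_slice(file.path(d2, "a.dcm"), matrix(0L, 4, 4), ipp = c(0, 0, 0),
                    iop = c(ang, s, 0, -s, ang, 0))
  expect_error(read_volume(d2), "non-axis-aligned|orientation")
  f <- file.path(td, "x.dcm")
  writeBin(as.raw(1:64), f)
  expect_error(laa3d:::parse_dicom_file(f), "not a DICOM")
})

test_that("STL round trip merges vertices and is a byte-identical fixed point", {
  td <- withr::local_tempdir()
  cube <- mesh_cube(10)
  f1 <- file.path(td, "c.stl")
  write_stl(cube, f1)
  m <- read_stl(f1)
  expect_identical(nrow(m$vertices), 8L)     # duplicated facet corners merged
  expect_identical(nrow(m$triangles), 12L)
  expect_equal(mesh_volume(m), 1)

  for (bin in c(TRUE, FALSE)) {
    ico <- mesh_icosphere(10, 3)
    fa <- file.path(td, paste0("a", bin, ".stl"))
    fb <- file.path(td, paste0("b", bin, ".stl"))
    write_stl(ico, fa, binary = bin)
    m2 <- read_stl(fa)
    write_stl(m2, fb, binary = bin)
    expect_identical(readBin(fa, raw(), file.size(fa)),
                     readBin(fb, raw(), file.size(fb)))
    expect_identical(nrow(m2$vertices), nrow(ico$vertices))
  }
})

test_that("STL refuses empty meshes and non-STL content", {
  td <- withr::local_tempdir()
  mesh <- mesh_cube(5)
  mesh$triangles <- mesh$triangles[0, , drop = FALSE]
  expect_error(write_stl(mesh, file.path(td, "e.stl")), "empty")
  f <- file.path(td, "junk.stl")
  writeLines("this is not a mesh at all", f)
  expect_error(read_stl(f), "not a valid STL")
  expect_error(read_stl(file.path(td, "missing.stl")), "no such file")
})

test_that("landmark files round-trip and roles are validated", {
  td <- withr::local_tempdir()
  lm <- landmark_set(name = c("c1", "c2", "c3", "s"),
                     role = c("ostium_cut", "ostium_cut", "ostium_cut", "laa_seed"),
                     x = c(0, 1, 0, 5), y = c(0, 0, 1, 5), z = c(1, 2, 3, 4))
  f <- file.path(td, "lm.csv")
  write_landmarks(lm, f)
  lm2 <- read_landmarks(f)
  expect_equal(nrow(lm2), 4L)
  expect_equal(as.data.frame(lm2), as.data.frame(lm))
  writeLines(c("name,role,x,y,z", "p,apex,0,0,0"), f)
  expect_error(read_landmarks(f), "allowed roles")
  expect_error(landmark_set("a", "apex", 0, 0, 0), "ostium_cut")
})
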