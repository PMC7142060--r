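test_that("orthogonal sections copy the stored grid plane exactly", {
  set.seed(5)
  v <- random_volume(dims = c(8, 8, 8))
  k <- 3L
  expect_identical(orthogonal_section(v, "axial", k), v$data[, , k + 1])

  # oracle: explicit double loop for the sagittal plane
  i <- 5L
  sag <- orthogonal_section(v, "sagittal", i)
  oracle <- matrix(0, 8, 8)
  for (y in 1:8) for (z in 1:8) oracle[y, z] <- v$data[i + 1, y, z]
  expect_identical(sag, oracle)

  const <- cad_volume(array(7, c(4, 5, 6)))
  expect_true(all(orthogonal_section(const, "coronal", 2) == 7))
  expect_error(orthogonal_section(v, "axial", 8), "valid: 0\\.\\.7")
  expect_error(orthogonal_section(v, "axial", -1), "out of range")
})

test_that("grid-aligned oblique planes equal orthogonal sections bit-exactly", {
  set.seed(6)
  v <- random_volume(dims = c(7, 6, 5), spacing = c(0.9, 1.4, 2.2),
                     origin = c(3, -1, 10))
  for (k in c(0L, 2L, 4L)) {
    # nearest-neighbour on a grid plane is bit-exact
    near <- section_spec(voxel_to_mm(v, c(0, 0, k)),
                         u_axis = v$row_dir * v$spacing[1],
                         v_axis = v$col_dir * v$spacing[2],
                         out_size = c(7, 6), interpolation = "nearest")
    expect_identical(oblique_section(v, near),
                     orthogonal_section(v, "axial", k) + 0)
    # trilinear agrees to floating-point tolerance
    tri <- section_spec(near$origin, near$u_axis, near$v_axis,
                        c(7, 6), "trilinear")
    expect_lt(max(abs(oblique_section(v, tri) -
                        orthogonal_section(v, "axial", k))), 1e-9)
  }
})

test_that("trilinear oblique sections match the brute-force per-pixel oracle", {
  set.seed(11)
  for (trial in 1:20) {
    v <- random_volume(dims = sample(3:16, 3, replace = TRUE))
    spec <- random_section_spec(v, interpolation =
                                  sample(c("trilinear", "nearest"), 1))
    got <- oblique_section(v, spec)
    want <- brute_force_section(v, spec)
    expect_lt(max(abs(got - want)), 1e-9)
  }
})

test_that("trilinear samples stay within the convex hull of their neighbours", {
  set.seed(12)
  v <- random_volume(dims = c(6, 6, 6))
  spec <- section_spec(voxel_to_mm(v, c(1.2, 0.7, 0.3)),
                       u_axis = c(0.6, 0.2, 0.1), v_axis = c(-0.1, 0.5, 0.4),
                       out_size = c(5, 5), interpolation = "trilinear",
                       fill_value = NA)
  sec <- oblique_section(v, spec)
  inside <- !is.na(sec)
  expect_true(all(sec[inside] >= min(v$data) - 1e-9))
  expect_true(all(sec[inside] <= max(v$data) + 1e-9))

  const <- cad_volume(array(3.5, c(6, 6, 6)))
  spec2 <- section_spec(c(1, 1, 1), c(0.5, 0.3, 0), c(0, 0.4, 0.5),
                        c(4, 4), "trilinear")
  expect_true(all(abs(oblique_section(const, spec2) - 3.5) < 1e-12))
})

test_that("out-of-volume samples take the fill value, edges do not bleed", {
  v <- cad_volume(array(10, c(4, 4, 4)))
  spec <- section_spec(c(-5, 0, 0), c(1, 0, 0), c(0, 1, 0), c(3, 3),
                       "trilinear", fill_value = -77)
  expect_true(all(oblique_section(v, spec) == -77))
  # sampling exactly on the far face uses the face voxels, not fill
  face <- section_spec(c(0, 0, 3), c(1, 0, 0), c(0, 1, 0), c(4, 4),
                       "trilinear", fill_value = -77)
  expect_true(all(oblique_section(v, face) == 10))
})

test_that("window/level maps stored values onto 0..255 as specified", {
  w <- window_spec(40, 400)
  expect_identical(apply_window(matrix(40 - 200), w), matrix(0L))
  expect_identical(apply_window(matrix(40 + 200), w), matrix(255L))
  expect_identical(apply_window(matrix(40), w), matrix(128L))  # half-up

  # oracle: direct per-pixel evaluation of the formula
  set.seed(3)
  img <- matrix(runif(256, -500, 500), 16, 16)
  got <- apply_window(img, w)
  want <- matrix(0L, 16, 16)
  for (i in 1:16) for (j in 1:16) {
    t <- min(max((img[i, j] - (40 - 200)) / 400, 0), 1)
    want[i, j] <- as.integer(floor(t * 255 + 0.5))
  }
  expect_identical(got, want)

  # monotone non-decreasing
  vals <- sort(runif(100, -400, 500))
  out <- apply_window(matrix(vals), w)
  expect_true(all(diff(out) >= 0))
  expect_error(window_spec(40, 0), "width")
})

test_that("voxel/mm coordinate maps are mutually inverse", {
  v <- cad_volume(array(0, c(4, 4, 4)), spacing = c(0.5, 0.5, 2),
                  origin = c(10, 20, 30))
  expect_equal(voxel_to_mm(v, c(0, 0, 0)), c(10, 20, 30))
  # oracle: hand computation origin + index * spacing
  expect_equal(voxel_to_mm(v, c(2, 4, 1)), c(11, 22, 32))

  set.seed(9)
  vr <- random_volume(dims = c(5, 5, 5))
  pts <- matrix(runif(300, -10, 10), ncol = 3)
  back <- mm_to_voxel(vr, voxel_to_mm(vr, pts))
  expect_lt(max(abs(back - pts)), 1e-9)
})

test_that("windowed sections export as valid grayscale PNG", {
  set.seed(4)
  v <- random_volume(dims = c(8, 6, 4))
  img8 <- apply_window(orthogonal_section(v, "axial", 1),
                       window_spec(0, 2000))
  path <- tempfile(fileext = ".png")
  write_section_png(img8, path)
  back <- png::readPNG(path)
  expect_identical(dim(back), c(6L, 8L))     # rows = section-y
  expect_equal(round(back * 255), t(img8), tolerance = 1e-9)
})
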