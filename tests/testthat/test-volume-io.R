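test_that("synthetic series load back with the requested geometry", {
  spec <- synthetic_spec(c(20, 14, 6), spacing = c(0.7, 1.1, 2.5),
                         background_level = 80, noise_sd = 3, seed = 2)
  s <- generate_synthetic_series(spec)
  loaded <- load_dicom_series(s$payloads)
  expect_equal(dim(loaded$volume$data), c(20, 14, 6))
  expect_equal(loaded$volume$spacing, c(0.7, 1.1, 2.5), tolerance = 1e-9)
  expect_identical(loaded$metadata$series_uid, s$series_uid)
  # noise-free generator arrays survive the DICOM round trip exactly
  spec0 <- synthetic_spec(c(9, 7, 5), noise_sd = 0, background_level = 42,
                          seed = 3)
  s0 <- generate_synthetic_series(spec0)
  l0 <- load_dicom_series(s0$payloads)
  expect_identical(l0$volume$data + 0, s0$array + 0)
  expect_true(all(l0$volume$data == 42))
})

test_that("single-slice series defaults slice spacing from SliceThickness or 1 mm", {
  spec <- synthetic_spec(c(6, 5, 1), spacing = c(1, 1, 4))
  s <- generate_synthetic_series(spec)
  loaded <- load_dicom_series(s$payloads)
  expect_equal(dim(loaded$volume$data), c(6, 5, 1))
  expect_equal(loaded$volume$spacing[3], 4)   # SliceThickness present

  # strip SliceThickness: sz falls back to 1.0 mm
  dec <- dicom_decode(s$payloads[[1]])
  tags <- dec$elements
  tags$SliceThickness <- NULL
  tags$Rows <- NULL; tags$Columns <- NULL
  pix <- matrix(radcad:::raw_to_pixels(dec$pixel_raw, "int16"), nrow = 6)
  bare <- dicom_encode_slice(pix, tags)
  l2 <- load_dicom_series(list(bare))
  expect_equal(l2$volume$spacing[3], 1.0)
})

test_that("slice order is recovered from stored positions under any file order", {
  # oracle: independently sort the written slice positions
  set.seed(7)
  spec <- synthetic_spec(c(8, 8, 16), spacing = c(1, 1, 2.5), noise_sd = 10,
                         seed = 7)
  s <- generate_synthetic_series(spec)
  zpos <- vapply(s$payloads, function(p) {
    radcad:::ds_values(dicom_decode(p)$elements$ImagePositionPatient)[3]
  }, 0)
  expect_equal(order(zpos), seq_len(16))  # generator emits in z order

  shuffled <- sample(s$payloads)
  loaded <- load_dicom_series(shuffled)
  ref <- load_dicom_series(s$payloads)
  expect_identical(loaded$volume$data, ref$volume$data)
  expect_equal(loaded$volume$origin, c(0, 0, 0))
})

test_that("mixed series, mixed sizes and irregular spacing are rejected", {
  a <- generate_synthetic_series(synthetic_spec(c(6, 6, 3), seed = 1))
  b <- generate_synthetic_series(synthetic_spec(c(6, 6, 3), seed = 2))
  expect_error(load_dicom_series(c(a$payloads, b$payloads)), "mixed series")

  c1 <- generate_synthetic_series(synthetic_spec(c(6, 6, 2), seed = 4))
  c2 <- generate_synthetic_series(synthetic_spec(c(8, 6, 2), seed = 4))
  # same seed => same series uid, but different in-plane size
  expect_error(load_dicom_series(list(c1$payloads[[1]], c2$payloads[[2]])),
               "in-plane|pixel spacing|mixed")

  # displace one slice: the error names the offending gap
  s <- generate_synthetic_series(synthetic_spec(c(6, 6, 5),
                                                spacing = c(1, 1, 2)))
  dec <- dicom_decode(s$payloads[[4]])
  tags <- dec$elements
  tags$ImagePositionPatient <- c(0, 0, 7.3)   # was 6.0
  tags$Rows <- NULL; tags$Columns <- NULL
  pix <- matrix(radcad:::raw_to_pixels(dec$pixel_raw, "int16"), nrow = 6)
  moved <- dicom_encode_slice(pix, tags)
  expect_error(load_dicom_series(c(s$payloads[1:4], list(moved))),
               "non-uniform slice spacing.*gap")
  expect_error(load_dicom_series(list()), "at least one")
})

test_that("generation is byte-identical for a fixed seed", {
  spec <- synthetic_spec(c(10, 10, 4), noise_sd = 8,
                         lesions = list(list(center = c(5, 5, 2),
                                             radius_mm = 2, intensity = 300)),
                         seed = 99)
  s1 <- generate_synthetic_series(spec)
  s2 <- generate_synthetic_series(spec)
  expect_identical(s1$payloads, s2$payloads)
  s3 <- generate_synthetic_series(synthetic_spec(c(10, 10, 4), noise_sd = 8,
                                                 seed = 100))
  expect_false(identical(s1$payloads[[1]], s3$payloads[[1]]))
})

test_that("planted sphere voxel count matches exhaustive enumeration", {
  # oracle: count voxels whose centre distance to the lesion centre is <= r
  spec <- synthetic_spec(c(16, 16, 16), spacing = c(1, 1, 1),
                         background_level = 0, noise_sd = 0,
                         lesions = list(list(center = c(8, 8, 8),
                                             radius_mm = 4.5,
                                             intensity = 100)),
                         seed = 1)
  s <- generate_synthetic_series(spec)
  n_expected <- 0L
  for (x in 0:15) for (y in 0:15) for (z in 0:15) {
    if ((x - 8)^2 + (y - 8)^2 + (z - 8)^2 <= 4.5^2) {
      n_expected <- n_expected + 1L
    }
  }
  expect_identical(sum(s$array == 100), n_expected)
  # within one voxel shell of the analytic volume 4/3*pi*r^3
  expect_lt(abs(n_expected - 4 / 3 * pi * 4.5^3), 4 * pi * 4.5^2)
})

test_that("lesions outside the grid are rejected", {
  expect_error(synthetic_spec(c(8, 8, 8),
                              lesions = list(list(center = c(8, 4, 4),
                                                  radius_mm = 1,
                                                  intensity = 10))),
               "outside grid")
  expect_error(synthetic_spec(c(8, 8, 8),
                              lesions = list(list(center = c(4, 4, 4),
                                                  radius_mm = 0,
                                                  intensity = 10))),
               "radius")
})

test_that("pydicom agrees with the hand-rolled codec on geometry and pixels", {
  spec <- synthetic_spec(c(12, 9, 4), spacing = c(0.8, 1.2, 3),
                         background_level = 60, noise_sd = 15, seed = 21)
  dir <- tempfile("dcm")
  s <- generate_synthetic_series(spec, dir = dir)
  out <- run_python(sprintf('
import pydicom, glob
import numpy as np
fs = sorted(glob.glob("%s/*.dcm"))
tot = 0
for f in fs:
    ds = pydicom.dcmread(f)
    tot += int(ds.pixel_array.astype("int64").sum())
ds = pydicom.dcmread(fs[2])
print(ds.Rows, ds.Columns, float(ds.PixelSpacing[0]), float(ds.PixelSpacing[1]),
      float(ds.ImagePositionPatient[2]), ds.SeriesInstanceUID, tot)
', dir))
  parts <- strsplit(out[length(out)], " ")[[1]]
  expect_equal(as.integer(parts[1:2]), c(9, 12))          # Rows=ny, Cols=nx
  expect_equal(as.numeric(parts[3:4]), c(1.2, 0.8))       # (dy, dx)
  expect_equal(as.numeric(parts[5]), 2 * 3)               # slice 2 at z=6
  expect_identical(parts[6], s$series_uid)
  expect_equal(as.numeric(parts[7]), sum(s$array))
})
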