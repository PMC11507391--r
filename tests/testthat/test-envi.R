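# float32-representable random cube for exact roundtrips
f32_cube <- function(nr = 6, nc = 5, nb = 7, seed = 1) {
  set.seed(seed)
  vals <- round(runif(nr * nc * nb), 3) * 1024 / 1024
  # snap to float32 grid by a write/read through a raw connection
  con <- rawConnection(raw(0), "wb")
  writeBin(as.numeric(vals), con, size = 4L)
  snapped <- readBin(rawConnectionValue(con), "numeric", n = length(vals),
                     size = 4L)
  close(con)
  hypercube(array(snapped, c(nr, nc, nb)), seq(900, 900 + 10 * (nb - 1), by = 10))
}

test_that("ENVI write/read roundtrips exactly across interleaves and dtypes", {
  cube <- f32_cube()
  for (il in c("bsq", "bil", "bip")) {
    stem <- file.path(withr::local_tempdir(), paste0("cube_", il))
    write_envi(cube, stem, interleave = il)
    back <- read_envi(paste0(stem, ".hdr"))
    expect_identical(back$data, cube$data)
    expect_equal(back$wavelengths, cube$wavelengths)
  }
  # uint16 counts roundtrip
  counts <- hypercube(array(sample(0:65535, 60, replace = TRUE), c(4, 3, 5)),
                      seq_len(5))
  stem <- file.path(withr::local_tempdir(), "counts")
  write_envi(counts, stem, dtype = "uint16")
  expect_equal(read_envi(paste0(stem, ".hdr"))$data, counts$data)
})

test_that("malformed ENVI headers are rejected with informative errors", {
  cube <- f32_cube()
  stem <- file.path(withr::local_tempdir(), "cube")
  write_envi(cube, stem)
  hdr <- readLines(paste0(stem, ".hdr"))

  h2 <- sub("bands = 7", "bands = 5", hdr)
  writeLines(h2, paste0(stem, ".hdr"))
  expect_error(read_envi(paste0(stem, ".hdr")), "wavelengths")

  writeLines(hdr[!grepl("^wavelength =", hdr)], paste0(stem, ".hdr"))
  expect_error(read_envi(paste0(stem, ".hdr")), "wavelength")

  writeLines(sub("interleave = bsq", "interleave = foo", hdr),
             paste0(stem, ".hdr"))
  expect_error(read_envi(paste0(stem, ".hdr")), "interleave")

  # truncated raster
  writeLines(hdr, paste0(stem, ".hdr"))
  raw <- readBin(paste0(stem, ".raw"), "raw", n = 100)
  writeBin(raw, paste0(stem, ".raw"))
  expect_error(read_envi(paste0(stem, ".hdr")), "size")
})

test_that("reflectance calibration matches its defining ratio and is gain-invariant", {
  set.seed(4)
  dark <- hypercube(array(runif(60, 0, 0.1), c(4, 3, 5)), 1:5)
  white <- hypercube(dark$data + array(runif(60, 0.5, 1), c(4, 3, 5)), 1:5)

  expect_equal(calibrate_reflectance(white, white, dark)$data,
               array(1, c(4, 3, 5)))
  expect_equal(calibrate_reflectance(dark, white, dark)$data,
               array(0, c(4, 3, 5)))
  mid <- hypercube((white$data + dark$data) / 2, 1:5)
  expect_equal(calibrate_reflectance(mid, white, dark)$data,
               array(0.5, c(4, 3, 5)))

  raw <- hypercube(dark$data + 0.3 * (white$data - dark$data), 1:5)
  r1 <- calibrate_reflectance(raw, white, dark)
  g <- 7.3   # common detector gain cancels
  r2 <- calibrate_reflectance(hypercube(g * raw$data, 1:5),
                              hypercube(g * white$data, 1:5),
                              hypercube(g * dark$data, 1:5))
  expect_equal(r1$data, r2$data)

  bad_white <- white; bad_white$data[2, 2, 3] <- dark$data[2, 2, 3]
  expect_error(calibrate_reflectance(raw, bad_white, dark), "band")
})

test_that("frame averaging and replicate averaging are elementwise means", {
  set.seed(9)
  frames <- lapply(1:10, function(i)
    hypercube(array(runif(24), c(2, 3, 4)), 1:4))
  avg <- average_frames(frames)
  expect_equal(avg$data, Reduce(`+`, lapply(frames, `[[`, "data")) / 10)

  reps <- list(c(1, 2, 3), c(3, 2, 1), c(2, 2, 2))
  expect_equal(average_replicates(reps), c(2, 2, 2))
  expect_error(average_replicates(list(1:3, 1:4)), "length")
})

test_that("ROI segmentation recovers the oil disk and respects manual thresholds", {
  spec <- spectral_scene_spec(noise_sd = 0.001)
  sc <- generate_hypercube(0.9, spec, shape = c(48, 48))
  mask <- segment_roi(sc$cube, band_window = 200:260)

  # nearly all of the true disk, and nothing far outside it
  expect_gt(sum(mask & sc$mask) / sum(sc$mask), 0.95)
  dil <- EBImage::dilate(sc$mask, EBImage::makeBrush(5, "disc")) > 0
  expect_true(all(!mask | dil))

  # flat scene cannot be segmented
  flat <- hypercube(array(0.5, c(20, 20, 3)), 1:3)
  expect_error(segment_roi(flat), "flat|empty")

  # mask area non-increasing in a manual threshold sweep
  areas <- sapply(seq(0.05, 0.6, by = 0.05), function(th)
    sum(segment_roi(sc$cube, band_window = 200:260, threshold = th)))
  expect_true(all(diff(areas) <= 0))
})

test_that("mean spectra match the brute-force pixel average", {
  set.seed(21)
  cube <- hypercube(array(runif(9 * 8 * 6), c(9, 8, 6)), 1:6)
  mask <- matrix(runif(72) > 0.5, 9, 8)

  expect_equal(mean_spectrum(cube, mask), mean_spectrum_oracle(cube, mask))

  full <- matrix(TRUE, 9, 8)
  expect_equal(mean_spectrum(cube, full), apply(cube$data, 3, mean))

  single <- matrix(FALSE, 9, 8); single[3, 4] <- TRUE
  expect_equal(mean_spectrum(cube, single), cube$data[3, 4, ])

  uni <- hypercube(array(0.42, c(4, 4, 3)), 1:3)
  expect_equal(mean_spectrum(uni, matrix(TRUE, 4, 4)), rep(0.42, 3))
  expect_error(mean_spectrum(cube, matrix(TRUE, 3, 3)), "shape")
})
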