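test_that("titration AV follows 56.1*C*V/m and averages over replicates", {
  expect_equal(titration_av(C = 0.1, V = 0, m = 2), 0)
  expect_equal(titration_av(C = 0.1, V = 0.25, m = 2), 0.70125)
  expect_equal(average_av_replicates(c(0.70, 0.72, 0.68)), 0.70)
  expect_error(titration_av(C = 0, V = 1, m = 2), "positive")
  expect_error(titration_av(C = 0.1, V = 1, m = 0), "positive")
  expect_error(titration_av(C = 0.1, V = -1, m = 2), "non-negative")

  # linear in C and V, inverse in m, over random valid triples
  set.seed(11)
  for (i in 1:25) {
    C <- runif(1, 0.01, 1); V <- runif(1, 0, 10); m <- runif(1, 0.5, 5)
    k <- runif(1, 0.1, 4)
    expect_equal(titration_av(k * C, V, m), k * titration_av(C, V, m))
    expect_equal(titration_av(C, k * V, m), k * titration_av(C, V, m))
    expect_equal(titration_av(C, V, k * m), titration_av(C, V, m) / k)
  }
})

test_that("reference AV tables are in range, skewed to the stated mean, reproducible", {
  ref <- generate_reference_avs(153, seed = 1)
  expect_equal(nrow(ref), 153)
  expect_true(all(ref$av >= 0.32 & ref$av <= 1.59))
  expect_lt(abs(mean(ref$av) - 0.70), 0.1)

  expect_identical(generate_reference_avs(153, seed = 5),
                   generate_reference_avs(153, seed = 5))
  one <- generate_reference_avs(1, seed = 2)
  expect_equal(nrow(one), 1)
  expect_true(one$av >= 0.32 && one$av <= 1.59)
  expect_error(generate_reference_avs(0), "at least 1")
  expect_error(generate_reference_avs(10, av_min = 2, av_max = 1), "below")
})

test_that("oil spectra show the four absorption minima and respond to AV", {
  spec <- spectral_scene_spec(noise_sd = 0)
  wl <- spec$wavelengths
  for (av in c(0.32, 0.7, 1.59)) {
    r <- generate_oil_spectrum(av, spec)
    expect_true(all(r > 0 & r <= 1))
    locmin <- wl[which(diff(sign(diff(r))) == 2) + 1]
    for (ctr in c(1115, 1330, 1520, 1590))
      expect_lt(min(abs(locmin - ctr)), 10)
  }
  # reflectance at the acid-sensitive bands strictly decreasing in AV
  b1330 <- which.min(abs(wl - 1330))
  b1520 <- which.min(abs(wl - 1520))
  avs <- seq(0.32, 1.59, length.out = 9)
  r1330 <- sapply(avs, function(a) generate_oil_spectrum(a, spec)[b1330])
  r1520 <- sapply(avs, function(a) generate_oil_spectrum(a, spec)[b1520])
  expect_true(all(diff(r1330) < 0))
  expect_true(all(diff(r1520) < 0))
  expect_error(generate_oil_spectrum(-0.5, spec), "positive")
})

test_that("hypercube scenes have a dark background and a consistent oil disk", {
  spec <- spectral_scene_spec(noise_sd = 0.001)
  sc <- generate_hypercube(0.8, spec, shape = c(32, 32))
  expect_s3_class(sc$cube, "hypercube")
  d <- dim(sc$cube$data)
  expect_equal(d, c(32, 32, 512))

  bg <- !sc$mask
  bgvals <- apply(sc$cube$data, 3, function(pl) mean(pl[bg]))
  expect_lt(mean(bgvals), 0.05)

  # masked mean spectrum reproduces the sample spectrum up to noise
  ms <- mean_spectrum(sc$cube, sc$mask)
  ideal <- 10^(-oleospec:::oil_absorbance(0.8, spec))
  tol <- 3 * spec$noise_sd / sqrt(sum(sc$mask)) + 1e-6
  expect_lt(max(abs(ms - ideal)), tol + 0.01 * max(ideal))

  expect_error(generate_hypercube(0.8, spec, shape = c(8, 8)), "16 x 16")
})

test_that("cohorts are reproducible, complete, and order-insensitive as sets", {
  coh1 <- generate_cohort(n = 30, seed = 77, shape = c(32, 32))
  coh2 <- generate_cohort(n = 30, seed = 77, shape = c(32, 32))
  expect_identical(coh1$spectra, coh2$spectra)
  expect_identical(coh1$reference, coh2$reference)
  expect_identical(coh1$scenes, coh2$scenes)

  coh <- default_cohort()
  expect_equal(dim(coh$spectra), c(153, 512))
  expect_equal(nrow(coh$reference), 153)
  expect_true(all(rownames(coh$spectra) == coh$reference$sample_id))

  perm <- sample(30)
  expect_setequal(unname(split(unclass(coh1$spectra),
                               row(unclass(coh1$spectra)))),
                  unname(split(unclass(coh1$spectra)[perm, ],
                               row(unclass(coh1$spectra)[perm, ]))))
  expect_error(generate_cohort(n = 5), "at least 10")
})

test_that("texture decouples from AV when texture_coupling is zero", {
  spec0 <- spectral_scene_spec(texture_coupling = 0)
  coh <- generate_cohort(n = 100, spec = spec0, seed = 31, shape = c(32, 32))
  b <- which.min(abs(spec0$wavelengths - 1330))
  f3 <- sapply(seq_len(100), function(s) {
    img <- render_band(coh, s, b)
    rast <- quantize(img, coh$scenes[[s]]$mask, levels = 64)
    glcm_features(glcm(rast, d = 1, theta = 0, levels = 64))["f3"]
  })
  expect_lt(abs(cor(f3, coh$reference$av)), 0.2)
})
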