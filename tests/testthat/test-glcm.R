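test_that("quantization bins linearly, excludes background, ignores affine maps", {
  img <- matrix(c(0.2, 0.2, 0.8, 0.8), 2, 2)
  q <- quantize(img, levels = 2)
  expect_equal(sort(unique(as.vector(q))), c(0L, 1L))

  set.seed(14)
  img2 <- matrix(runif(64), 8, 8)
  expect_identical(quantize(img2, levels = 16),
                   quantize(3.1 * img2 + 0.4, levels = 16))
  expect_lte(length(unique(as.vector(quantize(img2, levels = 5)))), 5)

  mask <- matrix(c(TRUE, FALSE), 8, 8)
  qm <- quantize(img2, mask, levels = 4)
  expect_true(all(is.na(qm[!mask])))
  expect_true(all(!is.na(qm[mask])))
  expect_warning(quantize(matrix(1, 3, 3), levels = 4), "zero intensity")
})

test_that("co-occurrence matrices match hand counts on canonical images", {
  g <- glcm(suppressWarnings(quantize(matrix(5, 4, 4), levels = 2)),
            d = 1, theta = 0, levels = 2)
  expect_equal(unclass(g)[1, 1], 1)
  expect_equal(sum(g), 1)

  cb <- outer(1:4, 1:4, function(i, j) (i + j) %% 2L)
  gcb <- glcm(cb, d = 1, theta = 0, levels = 2)
  expect_equal(unclass(gcb), matrix(c(0, 0.5, 0.5, 0), 2, 2),
               ignore_attr = TRUE)

  f <- glcm_features(gcb)
  expect_equal(unname(f), c(0.5, 0.5, log(2), -1))

  expect_error(glcm(matrix(NA_integer_, 3, 3), d = 1, theta = 0, levels = 2),
               "no valid")
  expect_error(glcm(cb, d = 1, theta = 30), "theta")
})

test_that("co-occurrence counting matches the brute-force pair counter", {
  set.seed(15)
  for (i in 1:25) {
    rast <- matrix(sample(0:3, 64, replace = TRUE), 8, 8)
    if (i %% 3 == 0) rast[matrix(runif(64) < 0.2, 8, 8)] <- NA  # masked pixels
    for (th in c(0, 45, 90, 135)) {
      expect_equal(unclass(glcm(rast, d = 1, theta = th, levels = 4)),
                   glcm_oracle(rast, 1, th, 4), ignore_attr = TRUE,
                   info = paste("theta", th))
    }
    expect_equal(unclass(glcm(rast, d = 2, theta = 45, levels = 4)),
                 glcm_oracle(rast, 2, 45, 4), ignore_attr = TRUE)
  }
})

test_that("feature values respect their closed forms and extremal orderings", {
  k <- 6
  unif <- matrix(1 / k^2, k, k)
  fu <- glcm_features(unif)
  expect_equal(unname(fu["f2"]), 1 / k^2)
  expect_equal(unname(fu["f3"]), log(k^2))

  # uniform GLCM maximises entropy and minimises energy
  set.seed(16)
  for (i in 1:20) {
    P <- matrix(rexp(k^2), k, k); P <- (P + t(P)); P <- P / sum(P)
    fr <- glcm_features(P)
    expect_lte(fr["f3"], fu["f3"] + 1e-12)
    expect_gte(fr["f2"], fu["f2"] - 1e-12)
    expect_true(fr["f1"] > 0 && fr["f1"] <= 1)
    expect_true(fr["f4"] >= -1 - 1e-12 && fr["f4"] <= 1 + 1e-12)
  }

  single <- matrix(0, 3, 3); single[2, 2] <- 1
  expect_warning(fs <- glcm_features(single), "degenerate")
  expect_equal(unname(fs), c(1, 1, 0, 0))
})

test_that("texture vectors are 64-long, deterministic, and rotate as expected", {
  set.seed(17)
  img <- matrix(runif(256), 16, 16)
  imgs <- list(`1278.78` = img, `1367.98` = img * 0.5,
               `1488.66` = sqrt(img), `1677.98` = img^2)
  mask <- matrix(TRUE, 16, 16)
  v <- texture_vector(imgs, mask)
  expect_length(v, 64)
  expect_identical(v, texture_vector(imgs, mask))
  expect_match(names(v)[1], "^w1278.78_t0_f1$")

  # rotating the scene by 90 degrees swaps the 0/90 and 45/135 blocks
  q <- quantize(img, levels = 8)
  qr <- quantize(rot90_ccw(img), levels = 8)
  for (pair in list(c(0, 90), c(45, 135))) {
    expect_equal(glcm_features(glcm(q, theta = pair[1], levels = 8)),
                 glcm_features(glcm(qr, theta = pair[2], levels = 8)))
    expect_equal(glcm_features(glcm(q, theta = pair[2], levels = 8)),
                 glcm_features(glcm(qr, theta = pair[1], levels = 8)))
  }
})
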