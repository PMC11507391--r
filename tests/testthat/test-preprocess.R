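grid <- seq(870, 1720, length.out = 512)

test_that("Savitzky-Golay derivatives are exact on low-order polynomials", {
  a <- 2; b <- 0.5; cc <- -0.001
  quad <- a + b * grid + cc * grid^2
  lin <- 1.5 - 0.02 * grid
  set <- spectrum_set(rbind(quad, lin), grid)

  d2 <- sg_filter(set, window = 11, polyorder = 2, deriv = 2)
  expect_equal(unname(unclass(d2)[1, ]), rep(2 * cc, 512), tolerance = 1e-8)
  expect_equal(unname(unclass(d2)[2, ]), rep(0, 512), tolerance = 1e-10)

  d1 <- sg_filter(set, window = 11, polyorder = 2, deriv = 1)
  expect_equal(unname(unclass(d1)[1, ]), b + 2 * cc * grid, tolerance = 1e-8)
  expect_equal(unname(unclass(d1)[2, ]), rep(-0.02, 512), tolerance = 1e-10)

  d0 <- sg_filter(set, window = 11, polyorder = 2, deriv = 0)
  expect_equal(unclass(d0), unclass(set), tolerance = 1e-9,
               ignore_attr = TRUE)

  expect_error(sg_filter(set, window = 10), "odd")
  expect_error(sg_filter(set, window = 11, polyorder = 11), "below")
  expect_error(sg_filter(set, window = 11, polyorder = 2, deriv = 3), "deriv")
  expect_error(sg_filter(spectrum_set(matrix(1:4, 1), 1:4), window = 11),
               "exceeds")
})

test_that("SNV centres and scales each spectrum and is idempotent", {
  s <- spectrum_set(matrix(c(1, 2, 3), 1, 3), c(1, 2, 3))
  expect_equal(unname(unclass(snv(s))[1, ]), c(-1, 0, 1))

  set.seed(2)
  X <- matrix(rnorm(40, mean = 3, sd = 2), 5, 8)
  out <- snv(spectrum_set(X, 1:8))
  expect_equal(unname(rowMeans(out)), rep(0, 5))
  expect_equal(unname(apply(out, 1, sd)), rep(1, 5))
  expect_equal(unclass(snv(out)), unclass(out), ignore_attr = TRUE)

  flat <- spectrum_set(rbind(X[1, ], rep(4, 8)), 1:8)
  expect_error(snv(flat), "S002")
})

test_that("min-max normalization maps rows to [0,1] and ignores affine shifts", {
  s <- spectrum_set(matrix(c(1, 2, 3), 1, 3), c(1, 2, 3))
  expect_equal(unname(unclass(minmax_normalize(s))[1, ]), c(0, 0.5, 1))

  set.seed(3)
  X <- matrix(runif(30), 3, 10)
  base <- minmax_normalize(spectrum_set(X, 1:10))
  aff <- minmax_normalize(spectrum_set(2.7 * X + 5, 1:10))
  expect_equal(unclass(base), unclass(aff), ignore_attr = TRUE)
  expect_equal(unname(apply(base, 1, min)), rep(0, 3))
  expect_equal(unname(apply(base, 1, max)), rep(1, 3))
  expect_error(minmax_normalize(spectrum_set(matrix(1, 2, 4), 1:4)), "constant")
})

test_that("baseline correction removes straight lines and is idempotent", {
  set.seed(4)
  x <- runif(512)
  s0 <- spectrum_set(rbind(x, x + 0.7), grid)
  out <- baseline_correct(s0)
  expect_equal(unname(unclass(out)[1, ]), unname(unclass(out)[2, ]))

  ramp <- spectrum_set(matrix(3 + 0.01 * grid, 1), grid)
  expect_equal(max(abs(baseline_correct(ramp))), 0, tolerance = 1e-10)

  expect_equal(unclass(baseline_correct(out)), unclass(out),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("pretreatments preserve shape, order, and stamp provenance labels", {
  set.seed(5)
  X <- matrix(runif(6 * 512, 0.1, 0.9), 6, 512)
  rownames(X) <- sprintf("oil%d", 1:6)
  s <- spectrum_set(X, grid)
  for (m in c("None", "Normalize", "1Der", "2Der", "Baseline", "SNV", "SG")) {
    out <- apply_pretreatment(s, m)
    expect_equal(dim(out), c(6, 512))
    expect_identical(rownames(out), rownames(X))
    expect_identical(provenance_label(out), m)
  }
  expect_identical(provenance_label(s), "None")
  # second derivative goes through the same code path as sg_filter
  expect_equal(unclass(apply_pretreatment(s, "2Der")),
               unclass(sg_filter(s, deriv = 2)), ignore_attr = TRUE)
})
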