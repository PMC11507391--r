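random_problem <- function(seed, n = 20, p = 10) {
  set.seed(seed)
  list(X = matrix(rnorm(n * p), n, p), y = rnorm(n),
       Xnew = matrix(rnorm(5 * p), 5, p))
}

test_that("PCR and PLSR at full rank coincide with ordinary least squares", {
  for (s in 1:5) {
    pb <- random_problem(s)
    ols <- lm.fit(cbind(1, pb$X), pb$y)$coefficients
    yhat_ols <- drop(cbind(1, pb$Xnew) %*% ols)
    expect_equal(predict(fit_pcr(pb$X, pb$y, 10), pb$Xnew), yhat_ols,
                 tolerance = 1e-8)
    expect_equal(predict(fit_plsr(pb$X, pb$y, 10), pb$Xnew), yhat_ols,
                 tolerance = 1e-8)
  }
})

test_that("NIPALS coefficients match the independent SIMPLS route", {
  for (s in 1:5) {
    pb <- random_problem(s + 10)
    for (f in c(2, 5, 10)) {
      ni <- fit_plsr(pb$X, pb$y, f)
      si <- simpls_oracle(pb$X, pb$y, f)
      expect_equal(ni$coefficients, si$coefficients, tolerance = 1e-8)
      expect_equal(predict(ni, pb$Xnew), si$predict(pb$Xnew),
                   tolerance = 1e-8)
    }
  }
})

test_that("exact low-rank structure is fitted exactly", {
  set.seed(30)
  t <- rnorm(15); p <- rnorm(8)
  X <- t %*% t(p)
  y <- 2 * t
  expect_lt(sqrt(mean((fit_pcr(X, y, 1)$fitted - y)^2)), 1e-10)
  expect_lt(sqrt(mean((fit_plsr(X, y, 1)$fitted - y)^2)), 1e-10)

  x1 <- rnorm(12)
  m <- fit_plsr(matrix(x1, 12, 1), 2 * x1, 1)
  expect_equal(unname(m$coefficients), 2)
  expect_lt(sqrt(mean((m$fitted - 2 * x1)^2)), 1e-12)
})

test_that("latent structures satisfy their orthogonality invariants", {
  pb <- random_problem(40, n = 30, p = 12)
  pls <- fit_plsr(pb$X, pb$y, 6)
  G <- crossprod(pls$scores)
  expect_lt(max(abs(G - diag(diag(G)))), 1e-10)

  pcr <- fit_pcr(pb$X, pb$y, 6)
  expect_equal(crossprod(pcr$loadings), diag(6), tolerance = 1e-10)

  # PCR reconstruction residual shrinks as components are added
  Xc <- scale(pb$X, scale = FALSE)
  res <- sapply(1:8, function(f) {
    m <- fit_pcr(pb$X, pb$y, f)
    sqrt(sum((Xc - m$scores %*% t(m$loadings))^2))
  })
  expect_true(all(diff(res) <= 1e-10))
})

test_that("fits are invariant to sample order", {
  pb <- random_problem(41, n = 25, p = 8)
  perm <- sample(25)
  a <- fit_plsr(pb$X, pb$y, 4)
  b <- fit_plsr(pb$X[perm, ], pb$y[perm], 4)
  expect_equal(a$coefficients, b$coefficients, tolerance = 1e-9)
  a2 <- fit_pcr(pb$X, pb$y, 4)
  b2 <- fit_pcr(pb$X[perm, ], pb$y[perm], 4)
  expect_equal(predict(a2, pb$Xnew), predict(b2, pb$Xnew), tolerance = 1e-9)
})

test_that("prediction honours centering and input contracts", {
  pb <- random_problem(42)
  m <- fit_plsr(pb$X, pb$y, 3)
  expect_equal(predict(m, pb$X), m$fitted)
  # shifting the response shifts predictions by the same constant
  m2 <- fit_plsr(pb$X, pb$y + 5, 3)
  expect_equal(predict(m2, pb$Xnew), predict(m, pb$Xnew) + 5)
  # the column-mean sample predicts the mean response
  xbar <- matrix(colMeans(pb$X), 1)
  expect_equal(unname(predict(m, xbar)), mean(pb$y))
  expect_equal(unname(predict(fit_pcr(pb$X, pb$y, 4), xbar)), mean(pb$y))

  expect_error(predict(m, pb$Xnew[, 1:5]), "columns")
  expect_error(fit_plsr(pb$X, rep(1, 20), 2), "variance")
  expect_error(fit_pcr(pb$X, pb$y, 11), "rank")
})

test_that("cross-validated component selection finds structure and resists noise", {
  set.seed(50)
  n <- 60
  T2 <- matrix(rnorm(n * 2), n, 2)
  P2 <- matrix(rnorm(2 * 30), 2, 30)
  X <- T2 %*% P2
  y <- T2 %*% c(1, -2)
  sel <- select_components(X, y, f_max = 8, seed = 1)
  expect_equal(sel$ncomp, 2L)

  ynoise <- rnorm(n)
  Xn <- matrix(rnorm(n * 30), n, 30)
  seln <- select_components(Xn, ynoise, f_max = 8, seed = 1)
  expect_equal(seln$ncomp, 1L)

  expect_identical(select_components(Xn, ynoise, f_max = 8, seed = 3),
                   select_components(Xn, ynoise, f_max = 8, seed = 3))
})
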