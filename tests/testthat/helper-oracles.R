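# Independent oracle implementations used to cross-check the package's
# algorithms on small problems. Deliberately naive: loops and textbook
# formulas, sharing no code with the implementations under test.

# SIMPLS (de Jong) for univariate y: an algorithmically distinct PLS route.
simpls_oracle <- function(X, y, ncomp) {
  X <- as.matrix(X)
  xm <- colMeans(X); ym <- mean(y)
  Xc <- sweep(X, 2, xm); yc <- y - ym
  p <- ncol(Xc)
  S <- crossprod(Xc, yc)
  R <- matrix(0, p, ncomp); V <- matrix(0, p, ncomp)
  q <- numeric(ncomp)
  for (a in seq_len(ncomp)) {
    r <- S                      # univariate y: dominant direction is S
    t <- drop(Xc %*% r)
    nt <- sqrt(sum(t^2))
    t <- t / nt; r <- r / nt
    pv <- crossprod(Xc, t)
    q[a] <- sum(yc * t)
    v <- pv
    if (a > 1) {
      Vp <- V[, seq_len(a - 1), drop = FALSE]
      v <- v - Vp %*% crossprod(Vp, pv)
    }
    v <- v / sqrt(sum(v^2))
    S <- S - v %*% crossprod(v, S)
    R[, a] <- r; V[, a] <- v
  }
  beta <- R %*% q
  list(coefficients = drop(beta), xmean = xm, ymean = ym,
       predict = function(Xn) drop(sweep(as.matrix(Xn), 2, xm) %*% beta) + ym)
}

# brute-force GLCM pair counter: explicit double loop over all pixels
glcm_oracle <- function(raster, d, theta, levels, symmetric = TRUE) {
  off <- switch(as.character(theta),
                `0` = c(0L, d), `45` = c(-d, d),
                `90` = c(-d, 0L), `135` = c(-d, -d))
  counts <- matrix(0, levels, levels)
  for (i in seq_len(nrow(raster))) {
    for (j in seq_len(ncol(raster))) {
      i2 <- i + off[1]; j2 <- j + off[2]
      if (i2 < 1 || i2 > nrow(raster) || j2 < 1 || j2 > ncol(raster)) next
      a <- raster[i, j]; b <- raster[i2, j2]
      if (is.na(a) || is.na(b)) next
      counts[a + 1L, b + 1L] <- counts[a + 1L, b + 1L] + 1
    }
  }
  if (symmetric) counts <- counts + t(counts)
  counts / sum(counts)
}

# brute-force Kennard-Stone for tiny n: enumerate seed pair, then greedy
ks_oracle <- function(X, n_cal) {
  X <- as.matrix(X)
  n <- nrow(X)
  D <- as.matrix(dist(X))
  best <- c(1L, 2L); bd <- -Inf
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if (D[i, j] > bd) { bd <- D[i, j]; best <- c(i, j) }
  sel <- best
  while (length(sel) < n_cal) {
    cand <- setdiff(seq_len(n), sel)
    md <- sapply(cand, function(c) min(D[c, sel]))
    sel <- c(sel, cand[which.max(md)])
  }
  sort(sel)
}

# brute-force masked mean spectrum: explicit loops
mean_spectrum_oracle <- function(cube, mask) {
  d <- dim(cube$data)
  out <- numeric(d[3])
  for (b in seq_len(d[3])) {
    s <- 0; cnt <- 0
    for (i in seq_len(d[1])) for (j in seq_len(d[2]))
      if (mask[i, j]) { s <- s + cube$data[i, j, b]; cnt <- cnt + 1 }
    out[b] <- s / cnt
  }
  out
}

# classical Gram-Schmidt residual norms for SPA chain verification
gram_schmidt_residual <- function(X, chain) {
  basis <- NULL
  norms <- numeric(0)
  R <- X
  for (idx in chain) {
    u <- X[, idx]
    if (!is.null(basis))
      for (k in seq_len(ncol(basis))) u <- u - sum(u * basis[, k]) * basis[, k]
    norms <- c(norms, sqrt(sum(u^2)))
    basis <- cbind(basis, u / sqrt(sum(u^2)))
  }
  norms
}

# 90-degree counter-clockwise rotation of a matrix image
rot90_ccw <- function(m) t(m)[ncol(m):1, , drop = FALSE]

# small planted-band feature-selection problem: 5 informative columns
# carrying independent latent factors that sum to y, the rest weak noise
planted_problem <- function(seed, n = 60, p = 80, info = c(10, 25, 40, 55, 70)) {
  set.seed(seed)
  Tm <- matrix(rnorm(n * length(info)), n, length(info))
  X <- matrix(rnorm(n * p, sd = 0.3), n, p)
  X[, info] <- Tm + matrix(rnorm(n * length(info), sd = 0.1), n, length(info))
  y <- rowSums(Tm) + rnorm(n, sd = 0.05)
  list(X = X, y = y, info = info)
}

# shared default cohort (built once per test run; ~2 s)
.cohort_cache <- new.env(parent = emptyenv())
default_cohort <- function(seed = 42, n = 153) {
  key <- paste0("c", seed, "_", n)
  if (is.null(.cohort_cache[[key]]))
    .cohort_cache[[key]] <- generate_cohort(n = n, seed = seed)
  .cohort_cache[[key]]
}
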