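# Calibration models: principal component regression and partial least
# squares regression (univariate y, NIPALS). Both centre X and y; PLSR can
# additionally autoscale columns, which fused spectral + texture matrices
# need because the blocks differ by orders of magnitude.

prep_xy <- function(X, y, scale = FALSE) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (nrow(X) != length(y)) stop("X and y sizes disagree")
  if (var(y) == 0) stop("response has zero variance")
  xm <- colMeans(X)
  xs <- if (scale) apply(X, 2, sd) else rep(1, ncol(X))
  if (scale && any(xs == 0)) xs[xs == 0] <- 1   # constant columns carry no signal
  Xc <- sweep(sweep(X, 2, xm), 2, xs, `/`)
  ym <- mean(y)
  list(Xc = Xc, yc = y - ym, xmean = xm, xscale = xs, ymean = ym)
}

#' Principal component regression
#'
#' Mean-centres the predictor matrix, decomposes it by SVD
#' (`Xc = T P' + E` with orthonormal loadings `P` and scores `T`), and
#' regresses the centred response on the first `ncomp` scores by ordinary
#' least squares. Using the leading components suppresses noise and
#' collinearity in spectral predictors.
#'
#' @param X calibration predictor matrix (samples x variables).
#' @param y calibration response (acid values, mg/g).
#' @param ncomp number of principal components, `1 <= ncomp <= rank(Xc)`.
#' @param scale autoscale columns to unit variance (used for fused
#'   spectral + texture feature matrices).
#' @return object of class `pcr_model` with loadings, scores, regression
#'   coefficients in the original variable space, and centering info.
#' @export
fit_pcr <- function(X, y, ncomp, scale = FALSE) {
  pp <- prep_xy(X, y, scale = scale)
  sv <- svd(pp$Xc)
  rank <- sum(sv$d > max(dim(pp$Xc)) * .Machine$double.eps * sv$d[1])
  if (ncomp < 1 || ncomp > rank)
    stop("ncomp must be between 1 and the rank of centred X (", rank, ")")
  Tm <- sv$u[, seq_len(ncomp), drop = FALSE] %*%
        diag(sv$d[seq_len(ncomp)], ncomp)
  P <- sv$v[, seq_len(ncomp), drop = FALSE]
  # scores are orthogonal, so OLS on them is a per-column projection
  gamma <- crossprod(Tm, pp$yc) / colSums(Tm^2)
  beta <- P %*% gamma
  structure(list(coefficients = drop(beta), gamma = drop(gamma),
                 loadings = P, scores = Tm, ncomp = ncomp,
                 xmean = pp$xmean, ymean = pp$ymean,
                 xscale = pp$xscale, rank = rank,
                 fitted = drop(Tm %*% gamma) + pp$ymean),
            class = "pcr_model")
}

#' Partial least squares regression (NIPALS)
#'
#' Univariate-response NIPALS: each component's weight vector is the
#' covariance direction `X' y` (normalised), scores are `t = X w`, X is
#' deflated by its rank-one reconstruction, and the response regresses on
#' the scores rather than on the original variables. Coefficients in the
#' original space are `B = W (P' W)^{-1} q`.
#'
#' @param X calibration predictor matrix.
#' @param y calibration response.
#' @param ncomp number of latent components.
#' @param scale autoscale columns to unit variance before fitting (used for
#'   fused spectral + texture feature matrices).
#' @return object of class `pls_model` with weights `W`, loadings `P`,
#'   scores `T`, response loadings `q`, coefficients per component count,
#'   and centering/scaling info.
#' @export
fit_plsr <- function(X, y, ncomp, scale = FALSE) {
  pp <- prep_xy(X, y, scale = scale)
  Xc <- pp$Xc; yc <- pp$yc
  n <- nrow(Xc); p <- ncol(Xc)
  ncomp <- as.integer(ncomp)
  if (ncomp < 1 || ncomp > min(n - 1, p)) stop("ncomp out of range")
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  Tm <- matrix(0, n, ncomp); q <- numeric(ncomp)
  Ex <- Xc
  for (a in seq_len(ncomp)) {
    w <- drop(crossprod(Ex, yc))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) { ncomp <- a - 1L; break }
    w <- w / nw
    t <- drop(Ex %*% w)
    tt <- sum(t^2)
    p_a <- drop(crossprod(Ex, t)) / tt
    q[a] <- sum(yc * t) / tt
    Ex <- Ex - tcrossprod(t, p_a)
    yc <- yc - q[a] * t
    W[, a] <- w; P[, a] <- p_a; Tm[, a] <- t
  }
  if (ncomp < 1) stop("no usable PLS component (X'y is zero)")
  W <- W[, seq_len(ncomp), drop = FALSE]
  P <- P[, seq_len(ncomp), drop = FALSE]
  Tm <- Tm[, seq_len(ncomp), drop = FALSE]
  q <- q[seq_len(ncomp)]
  R <- W %*% solve(crossprod(P, W))   # X-space rotation: T = Xc R
  beta <- R %*% q
  structure(list(coefficients = drop(beta), weights = W, loadings = P,
                 scores = Tm, yloadings = q, rotation = R,
                 ncomp = ncomp, scaled = scale,
                 xmean = pp$xmean, xscale = pp$xscale, ymean = pp$ymean,
                 fitted = drop(pp$Xc %*% beta) + pp$ymean),
            class = "pls_model")
}

predict_linear <- function(object, Xnew) {
  Xnew <- as.matrix(Xnew)
  if (ncol(Xnew) != length(object$xmean))
    stop("new data has ", ncol(Xnew), " columns; model was trained on ",
         length(object$xmean))
  Xc <- sweep(sweep(Xnew, 2, object$xmean), 2, object$xscale, `/`)
  drop(Xc %*% object$coefficients) + object$ymean
}

#' @export
predict.pcr_model <- function(object, newdata, ...) predict_linear(object, newdata)

#' @export
predict.pls_model <- function(object, newdata, ...) predict_linear(object, newdata)

#' @export
print.pcr_model <- function(x, ...) {
  cat("<pcr_model> ", x$ncomp, " components over ",
      length(x$coefficients), " variables\n", sep = ""); invisible(x)
}

#' @export
print.pls_model <- function(x, ...) {
  cat("<pls_model> ", x$ncomp, " components over ",
      length(x$coefficients), " variables",
      if (x$scaled) " (autoscaled)", "\n", sep = ""); invisible(x)
}

# predictions for every component count 1..ncomp from one PLS fit (nested)
pls_predict_all <- function(fit, Xnew) {
  Xc <- sweep(sweep(as.matrix(Xnew), 2, fit$xmean), 2, fit$xscale, `/`)
  Tn <- Xc %*% fit$rotation
  out <- matrix(0, nrow(Xc), fit$ncomp)
  acc <- rep(fit$ymean, nrow(Xc))
  for (a in seq_len(fit$ncomp)) {
    acc <- acc + Tn[, a] * fit$yloadings[a]
    out[, a] <- acc
  }
  out
}

#' Choose the number of latent components by cross-validation
#'
#' k-fold cross-validated RMSE over component counts `1..f_max`, with the
#' one-standard-error parsimony rule: the smallest count whose CV RMSE is
#' within one standard error of the minimum is returned.
#'
#' @param X calibration predictors.
#' @param y calibration response.
#' @param f_max largest component count to consider.
#' @param folds number of CV folds.
#' @param seed seed for the fold assignment.
#' @param method `"plsr"` or `"pcr"`.
#' @param scale autoscaling flag passed to the fitter.
#' @return list with `ncomp` (chosen), `rmsecv` (per count), `se_min`.
#' @export
select_components <- function(X, y, f_max = 10, folds = 5, seed = 1,
                              method = c("plsr", "pcr"), scale = FALSE) {
  method <- match.arg(method)
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  f_max <- min(f_max, ncol(X), n - ceiling(n / folds) - 1)
  if (f_max < 1) stop("no admissible component count")
  set.seed(seed)
  fold <- sample(rep(seq_len(folds), length.out = n))
  press <- matrix(NA_real_, n, f_max)
  for (f in seq_len(folds)) {
    tr <- fold != f; te <- !tr
    fm <- min(f_max, sum(tr) - 1)
    if (method == "plsr") {
      fit <- fit_plsr(X[tr, , drop = FALSE], y[tr], ncomp = fm, scale = scale)
      ph <- pls_predict_all(fit, X[te, , drop = FALSE])
    } else {
      ph <- matrix(0, sum(te), fm)
      for (a in seq_len(fm)) {
        fit <- fit_pcr(X[tr, , drop = FALSE], y[tr], ncomp = a, scale = scale)
        ph[, a] <- predict(fit, X[te, , drop = FALSE])
      }
    }
    nc <- ncol(ph)
    press[te, seq_len(nc)] <- (ph - y[te])^2
    if (nc < f_max)   # fold too small for the full count: reuse last column
      press[te, (nc + 1):f_max] <- press[te, nc]
  }
  rmsecv <- sqrt(colMeans(press))
  best <- which.min(rmsecv)
  # delta-method SE of the RMSE at the minimising count
  se_mse <- sd(press[, best]) / sqrt(n)
  se_rmse <- se_mse / (2 * rmsecv[best])
  ncomp <- which(rmsecv <= rmsecv[best] + se_rmse)[1]
  list(ncomp = as.integer(ncomp), rmsecv = rmsecv, se_min = se_rmse)
}

#' Fit a calibration model with automatic component selection
#'
#' @param X,y calibration data.
#' @param method `"plsr"` or `"pcr"`.
#' @param ncomp fixed component count, or `NULL` to choose by
#'   [select_components()].
#' @param scale autoscale predictor columns.
#' @param f_max,folds,seed passed to [select_components()].
#' @return fitted `pls_model` or `pcr_model`.
#' @export
fit_model <- function(X, y, method = c("plsr", "pcr"), ncomp = NULL,
                      scale = FALSE, f_max = 10, folds = 5, seed = 1) {
  method <- match.arg(method)
  if (is.null(ncomp))
    ncomp <- select_components(X, y, f_max = f_max, folds = folds,
                               seed = seed, method = method, scale = scale)$ncomp
  if (method == "plsr") fit_plsr(X, y, ncomp, scale = scale)
  else fit_pcr(X, y, ncomp, scale = scale)
}
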