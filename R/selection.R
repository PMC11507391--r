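# Characteristic-wavelength selection: the successive projections algorithm
# (SPA) and competitive adaptive reweighted sampling (CARS). Both return a
# `wavelength_subset` carrying indices into the band grid plus the
# diagnostics needed for the usual selection plots (SPA RMSE-vs-k chain;
# CARS RMSECV and variable-count traces).

wavelength_subset <- function(indices, wavelengths, method, diagnostics = list()) {
  indices <- sort(unique(as.integer(indices)))
  if (length(indices) < 1L) stop("empty wavelength subset")
  if (any(indices < 1L) || any(indices > length(wavelengths)))
    stop("subset indices out of range")
  structure(list(indices = indices,
                 wavelengths = wavelengths[indices],
                 method = method, diagnostics = diagnostics),
            class = "wavelength_subset")
}

#' @export
print.wavelength_subset <- function(x, ...) {
  cat("<wavelength_subset> ", x$method, ": ", length(x$indices),
      " bands (", paste(round(x$wavelengths, 2), collapse = ", "), ")\n",
      sep = "")
  invisible(x)
}

#' Proportion of the full wavelength grid covered by a subset
#'
#' `|subset| / n_bands * 100`, rounded to two decimals -- the conventional
#' way to report how much of the grid a selection retains (e.g. 4 of 512
#' bands is 0.78%).
#'
#' @param subset a `wavelength_subset` or an integer count.
#' @param n_bands size of the full grid (default 512).
#' @return percentage, rounded to 2 decimals.
#' @export
subset_proportion <- function(subset, n_bands = 512) {
  k <- if (inherits(subset, "wavelength_subset")) length(subset$indices)
       else as.integer(subset)
  round(k / n_bands * 100, 2)
}

# one SPA projection chain: starting from column `start`, repeatedly add the
# column with the largest norm after projection onto the orthogonal
# complement of the chain's span. Returns the chain in selection order.
spa_chain <- function(X, start, k) {
  p <- ncol(X)
  R <- X                                    # residual columns
  chain <- integer(0)
  cur <- as.integer(start)
  for (step in seq_len(k)) {
    chain <- c(chain, cur)
    u <- R[, cur]
    nu2 <- sum(u^2)
    if (nu2 < 1e-24) { chain <- chain[-length(chain)]; break }
    R <- R - u %*% (crossprod(u, R) / nu2)  # project out the chosen column
    if (step == k) break
    norms <- colSums(R^2)
    norms[chain] <- -Inf
    cur <- which.max(norms)
    if (norms[cur] < 1e-20) {
      warning("SPA chain truncated at length ", step,
              ": remaining columns are in the span of the chain")
      break
    }
  }
  chain
}

rmse_mlr <- function(Xtr, ytr, Xte, yte) {
  fit <- lm.fit(cbind(1, Xtr), ytr)
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0
  pred <- drop(cbind(1, Xte) %*% beta)
  sqrt(mean((pred - yte)^2))
}

#' Successive projections algorithm
#'
#' Builds, for every candidate start column, a chain of mutually orthogonal
#' (minimally collinear) columns by repeated orthogonal projection, then
#' scores every chain prefix of length `1..k_max` by the RMSE of a multiple
#' linear regression on an inner Kennard-Stone 70/30 validation split of
#' the calibration data. The best-scoring prefix is returned; with
#' `rule = "1se"` the smallest prefix whose validation RMSE is within one
#' standard error of the minimum is preferred (more parsimonious but less
#' stable when the validation set is small).
#'
#' @param X calibration predictor matrix (pretreated spectra).
#' @param y calibration response.
#' @param wl wavelength grid (nm) for labelling; defaults to band indices.
#' @param k_max longest chain considered.
#' @param val_frac fraction of calibration samples kept for chain scoring.
#' @param rule chain-length rule, `"min"` (default) or `"1se"`.
#' @return a `wavelength_subset` with an `rmse_by_k` diagnostic.
#' @export
spa_select <- function(X, y, wl = NULL, k_max = 10, val_frac = 0.3,
                       rule = c("min", "1se")) {
  rule <- match.arg(rule)
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (is.null(wl)) wl <- seq_len(p)
  k_max <- min(k_max, n - 2L, p)
  if (k_max < 1) stop("k_max must allow at least one variable")
  inner <- ks_split(X, ratio = 1 - val_frac)
  tr <- inner$calibration; te <- inner$prediction
  best <- list(rmse = Inf)
  rmse_tab <- matrix(NA_real_, p, k_max)
  for (s in seq_len(p)) {
    chain <- spa_chain(X[tr, , drop = FALSE], s, k_max)
    for (k in seq_along(chain)) {
      cols <- chain[seq_len(k)]
      r <- rmse_mlr(X[tr, cols, drop = FALSE], y[tr],
                    X[te, cols, drop = FALSE], y[te])
      rmse_tab[s, k] <- r
      if (r < best$rmse) best <- list(rmse = r, start = s, chain = chain)
    }
  }
  errs <- rmse_tab[best$start, ]
  kmin <- which.min(errs)
  if (rule == "1se") {
    cols_min <- best$chain[seq_len(kmin)]
    fitv <- lm.fit(cbind(1, X[tr, cols_min, drop = FALSE]), y[tr])
    beta <- fitv$coefficients; beta[is.na(beta)] <- 0
    sq <- (drop(cbind(1, X[te, cols_min, drop = FALSE]) %*% beta) - y[te])^2
    se <- sd(sq) / sqrt(length(sq)) / (2 * errs[kmin])
    k_sel <- which(errs <= errs[kmin] + se)[1]
  } else {
    k_sel <- kmin
  }
  wavelength_subset(best$chain[seq_len(k_sel)], wl, "SPA",
                    diagnostics = list(rmse_by_k = errs, k_min = kmin,
                                       k_selected = k_sel, start = best$start,
                                       rmse_selected = errs[k_sel]))
}

#' Exponentially decreasing retention schedule (EDF)
#'
#' The fraction of the original variables retained at CARS run `i` of `N`:
#' `r_i = a * exp(-k i)` with `a` and `k` solved from the boundary
#' conditions `r_1 = 1` (all `p` variables at the first run) and
#' `r_N = 2/p` (two variables at the last).
#'
#' @param i run index, `1 <= i <= N`.
#' @param N total number of runs.
#' @param p number of variables (>= 2).
#' @return retention fraction(s) in `(0, 1]`. Vectorised over `i`.
#' @export
edf_ratio <- function(i, N, p) {
  if (p < 2) stop("p must be at least 2")
  if (N < 2) stop("N must be at least 2")
  if (any(i < 1) || any(i > N)) stop("run index out of range")
  k <- log(p / 2) / (N - 1)
  exp(-k * (i - 1))
}

cv_rmse_pls <- function(X, y, ncomp_max, folds = 5) {
  n <- nrow(X)
  fold <- rep(seq_len(folds), length.out = n)  # deterministic assignment
  press <- matrix(NA_real_, n, ncomp_max)
  for (f in seq_len(folds)) {
    tr <- fold != f
    fm <- min(ncomp_max, sum(tr) - 1, ncol(X))
    fit <- fit_plsr(X[tr, , drop = FALSE], y[tr], ncomp = fm)
    ph <- pls_predict_all(fit, X[!tr, , drop = FALSE])
    nc <- ncol(ph)
    press[!tr, seq_len(nc)] <- (ph - y[!tr])^2
    if (nc < ncomp_max) press[!tr, (nc + 1):ncomp_max] <- press[!tr, nc]
  }
  min(sqrt(colMeans(press)))   # best component count per candidate set
}

#' Competitive adaptive reweighted sampling
#'
#' Monte-Carlo variable selection: at run `i`, a PLSR model is fitted on a
#' random `mc_frac` of the calibration samples over the surviving
#' variables; variables are ranked by absolute regression coefficient, the
#' top `edf_ratio(i, N, p) * p` are kept (enforced exponential decay), and
#' adaptive reweighted sampling (weighted draws with replacement,
#' probability proportional to coefficient magnitude) prunes the set
#' further. Each run's surviving set is scored by 5-fold PLS RMSECV; the
#' set with the smallest RMSECV wins.
#'
#' @param X calibration predictors.
#' @param y calibration response.
#' @param wl wavelength grid for labelling.
#' @param n_runs Monte-Carlo runs `N` (>= 2), default 50.
#' @param seed RNG seed; fixed seed gives an identical subset and traces.
#' @param mc_frac row fraction per Monte-Carlo fit.
#' @param ncomp_max PLS component cap.
#' @param folds RMSECV folds.
#' @return a `wavelength_subset` with `rmsecv_trace` and `n_vars_trace`
#'   diagnostics.
#' @export
cars_select <- function(X, y, wl = NULL, n_runs = 50, seed = 1,
                        mc_frac = 0.8, ncomp_max = 10, folds = 5) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (is.null(wl)) wl <- seq_len(p)
  if (n_runs < 2) stop("n_runs must be at least 2")
  set.seed(seed)
  surviving <- seq_len(p)
  rmsecv <- rep(NA_real_, n_runs)
  nvars <- rep(NA_real_, n_runs)
  sets <- vector("list", n_runs)
  for (i in seq_len(n_runs)) {
    rows <- sort(sample(n, max(2, round(mc_frac * n))))
    nc <- min(ncomp_max, length(rows) - 1, length(surviving))
    fit <- fit_plsr(X[rows, surviving, drop = FALSE], y[rows], ncomp = nc)
    b <- abs(fit$coefficients)
    keep_n <- min(length(surviving), max(2, round(edf_ratio(i, n_runs, p) * p)))
    top <- surviving[order(b, decreasing = TRUE)[seq_len(keep_n)]]
    wts <- b[match(top, surviving)]
    if (sum(wts) <= 0) wts <- rep(1, length(top))
    drawn <- sample(top, size = keep_n, replace = TRUE, prob = wts)
    surviving <- sort(unique(drawn))
    if (length(surviving) < 2L) {
      rmsecv <- rmsecv[seq_len(i - 1)]; nvars <- nvars[seq_len(i - 1)]
      sets <- sets[seq_len(i - 1)]
      break
    }
    sets[[i]] <- surviving
    nvars[i] <- length(surviving)
    rmsecv[i] <- cv_rmse_pls(X[, surviving, drop = FALSE], y,
                             min(ncomp_max, length(surviving)), folds)
  }
  ok <- which(!is.na(rmsecv))
  if (length(ok) == 0L) stop("CARS produced no scorable run")
  winner <- ok[which.min(rmsecv[ok])]
  wavelength_subset(sets[[winner]], wl, "CARS",
                    diagnostics = list(rmsecv_trace = rmsecv,
                                       n_vars_trace = nvars,
                                       best_run = winner))
}
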