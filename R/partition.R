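#' Kennard-Stone calibration/prediction split
#'
#' Deterministic maximin partition on Euclidean distance: the globally most
#' distant pair of samples seeds the calibration set, then the sample whose
#' minimum distance to the current calibration set is largest is added,
#' until `n_cal` samples are selected. The remainder forms the prediction
#' set. Ties are broken toward the lowest sample index, so the split is
#' reproducible.
#'
#' @param X numeric matrix (samples x features), typically the pretreated
#'   spectra used for modelling.
#' @param n_cal calibration-set size, `2 <= n_cal < nrow(X)`.
#' @return list with integer vectors `calibration` and `prediction`
#'   (sorted row indices), `order` (selection order) and `n_cal`.
#' @export
kennard_stone <- function(X, n_cal) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n_cal < 2 || n_cal >= n)
    stop("n_cal must be in [2, nrow(X) - 1]")
  D <- as.matrix(dist(X))
  # seed: most distant pair; which.max on the matrix takes the lowest
  # linear index among ties, i.e. lowest column then row
  idx <- which(D == max(D), arr.ind = TRUE)
  pair <- sort(idx[order(idx[, 1], idx[, 2]), , drop = FALSE][1, ])
  sel <- as.integer(pair)
  mind <- pmin(D[, sel[1]], D[, sel[2]])
  mind[sel] <- -Inf
  while (length(sel) < n_cal) {
    nxt <- which.max(mind)          # lowest index wins ties
    sel <- c(sel, nxt)
    mind <- pmin(mind, D[, nxt])
    mind[nxt] <- -Inf
  }
  sel <- unname(sel)
  list(calibration = sort(sel),
       prediction = setdiff(seq_len(n), sel),
       order = sel, n_cal = as.integer(n_cal))
}

#' Ratio-based Kennard-Stone split
#'
#' Convenience wrapper choosing `n_cal = ceiling(ratio * n)`; the default
#' 3:2 ratio sends 92 of 153 samples to calibration and 61 to prediction.
#'
#' @param X sample matrix.
#' @param ratio calibration fraction, default 0.6.
#' @return as [kennard_stone()].
#' @export
ks_split <- function(X, ratio = 0.6) {
  kennard_stone(X, ceiling(ratio * nrow(X)))
}

#' Outlier screening in principal-component space
#'
#' Flags abnormal samples by Mahalanobis distance in the score space of the
#' leading principal components (those explaining `var_explained` of the
#' variance, default 95%): a sample is flagged when its squared distance
#' exceeds the `1 - alpha` chi-square quantile with as many degrees of
#' freedom as retained components.
#'
#' @param X sample matrix (spectra).
#' @param y optional response vector, carried for interface symmetry with
#'   the modelling functions; the screen itself is unsupervised.
#' @param alpha flagging level, default 0.01.
#' @param var_explained cumulative variance fraction deciding how many
#'   components span the score space.
#' @param max_k cap on the number of components.
#' @return list with `retained` and `flagged` integer row indices, `k`
#'   (components used) and `d2` (squared Mahalanobis distances).
#' @export
remove_outliers <- function(X, y = NULL, alpha = 0.01, var_explained = 0.95,
                            max_k = 10) {
  X <- as.matrix(X)
  if (!is.null(y) && length(y) != nrow(X)) stop("X and y sizes disagree")
  n <- nrow(X)
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  if (sum(ev) <= 0) stop("degenerate covariance: spectra have no variance")
  k <- which(cumsum(ev) / sum(ev) >= var_explained)[1]
  k <- min(k, max_k, n - 2L, sum(ev > 1e-12 * ev[1]))
  if (k < 1L) stop("degenerate covariance: no usable components")
  # scores are uncorrelated with variances ev, so the Mahalanobis distance
  # is a weighted sum of squared standardised scores
  d2 <- rowSums(sweep(pc$x[, seq_len(k), drop = FALSE]^2, 2,
                      ev[seq_len(k)], `/`))
  cut <- qchisq(1 - alpha, df = k)
  flagged <- which(d2 > cut)
  list(retained = setdiff(seq_len(n), flagged), flagged = flagged,
       k = k, d2 = d2, cutoff = cut)
}
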