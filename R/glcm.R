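# Gray-level co-occurrence matrix (GLCM) texture features. The GLCM at
# offset (d, theta) is the joint distribution of gray-level pairs of pixels
# separated by that offset; four Haralick-style statistics summarise it:
# inverse difference moment f1, angular second moment f2, entropy f3 and
# correlation f4.

#' Quantize an intensity image to discrete gray levels
#'
#' Linear binning of the masked-pixel intensity range into `levels` equal
#' bins, producing integer levels `0 .. levels - 1`. Pixels outside the
#' mask become `NA` and never contribute co-occurrence pairs. Quantization
#' is invariant to affine intensity transforms (a + b * image, b > 0).
#'
#' @param image numeric matrix.
#' @param mask logical matrix (default: all pixels).
#' @param levels number of gray levels (>= 2), default 64.
#' @return integer matrix with `NA` outside the mask.
#' @export
quantize <- function(image, mask = NULL, levels = 64) {
  if (levels < 2) stop("levels must be at least 2")
  if (is.null(mask)) mask <- matrix(TRUE, nrow(image), ncol(image))
  if (!any(mask)) stop("mask selects no pixels")
  vals <- image[mask]
  rng <- range(vals)
  out <- matrix(NA_integer_, nrow(image), ncol(image))
  if (diff(rng) <= 0) {
    warning("zero intensity range; all pixels mapped to level 0")
    out[mask] <- 0L
    return(out)
  }
  q <- floor((vals - rng[1]) / diff(rng) * levels)
  out[mask] <- as.integer(pmin(q, levels - 1L))
  out
}

glcm_offset <- function(theta, d) {
  # (drow, dcol) in matrix coordinates; 0 deg is horizontal (same row,
  # increasing column), 90 deg vertical (decreasing row), diagonals between
  switch(as.character(theta),
         `0`   = c(0L, d),
         `45`  = c(-d, d),
         `90`  = c(-d, 0L),
         `135` = c(-d, -d),
         stop("theta must be one of 0, 45, 90, 135"))
}

#' Gray-level co-occurrence matrix
#'
#' Counts pairs of gray levels at pixel offset (`d`, `theta`), keeping only
#' pairs whose both pixels are inside the mask (non-`NA`), symmetrizes by
#' adding the transpose, and normalizes the counts to sum to one.
#'
#' @param raster integer matrix from [quantize()] (`NA` = outside mask).
#' @param d offset distance in pixels (>= 1).
#' @param theta direction in degrees: 0, 45, 90 or 135.
#' @param levels number of gray levels; defaults to `max(raster) + 1`.
#' @param symmetric add the transpose before normalizing (default TRUE).
#' @return `levels x levels` matrix of class `glcm_matrix`, entries summing
#'   to one.
#' @export
glcm <- function(raster, d = 1, theta = 0, levels = NULL, symmetric = TRUE) {
  if (d < 1) stop("d must be at least 1")
  if (is.null(levels)) levels <- max(raster, na.rm = TRUE) + 1L
  off <- glcm_offset(theta, as.integer(d))
  nr <- nrow(raster); nc <- ncol(raster)
  r1 <- max(1L, 1L - off[1]):min(nr, nr - off[1])
  c1 <- max(1L, 1L - off[2]):min(nc, nc - off[2])
  a <- raster[r1, c1, drop = FALSE]
  b <- raster[r1 + off[1], c1 + off[2], drop = FALSE]
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) stop("no valid co-occurrence pairs at this offset")
  counts <- matrix(0, levels, levels)
  tab <- tabulate(a[ok] * levels + b[ok] + 1L, nbins = levels * levels)
  counts <- matrix(tab, levels, levels, byrow = TRUE)
  if (symmetric) counts <- counts + t(counts)
  P <- counts / sum(counts)
  structure(P, class = c("glcm_matrix", "matrix", "array"),
            d = d, theta = theta, symmetric = symmetric)
}

#' GLCM texture features f1-f4
#'
#' From a normalized co-occurrence matrix `p(i, j)` (levels indexed
#' `1..k`):
#' \itemize{
#'   \item f1, inverse difference moment: `sum p(i,j) / (1 + (i - j)^2)` --
#'     local homogeneity;
#'   \item f2, angular second moment (energy): `sum p(i,j)^2` -- uniformity;
#'   \item f3, entropy: `-sum p(i,j) log p(i,j)` (natural log; zero entries
#'     contribute zero) -- textural randomness;
#'   \item f4, correlation: `(sum i*j*p(i,j) - u1*u2) / sqrt(s1^2 * s2^2)`
#'     with the usual marginal means `u1, u2` and variances `s1^2, s2^2`;
#'     defined as 0 (with a warning) when a marginal variance vanishes.
#' }
#'
#' @param P a `glcm_matrix` (or any nonnegative matrix summing to one).
#' @return named numeric vector `c(f1, f2, f3, f4)`.
#' @export
glcm_features <- function(P) {
  P <- unclass(P)
  k <- nrow(P)
  if (abs(sum(P) - 1) > 1e-8) stop("GLCM must be normalized to sum 1")
  i <- row(P); j <- col(P)
  f1 <- sum(P / (1 + (i - j)^2))
  f2 <- sum(P^2)
  pos <- P > 0
  f3 <- -sum(P[pos] * log(P[pos]))
  pi_ <- rowSums(P); pj <- colSums(P)
  u1 <- sum(seq_len(k) * pi_); u2 <- sum(seq_len(k) * pj)
  s1 <- sum((seq_len(k) - u1)^2 * pi_); s2 <- sum((seq_len(k) - u2)^2 * pj)
  if (s1 * s2 <= 0) {
    warning("degenerate GLCM marginals; correlation f4 set to 0")
    f4 <- 0
  } else {
    f4 <- (sum(i * j * P) - u1 * u2) / sqrt(s1 * s2)
  }
  c(f1 = f1, f2 = f2, f3 = f3, f4 = f4)
}

.glcm_thetas <- c(0, 45, 90, 135)

#' Texture feature vector for one scene at selected wavelengths
#'
#' For each selected band image: quantize over the mask, compute the GLCM
#' in the four directions (0, 45, 90, 135 degrees) and take f1-f4 of each,
#' yielding 16 values per band. With 4 selected wavelengths the vector has
#' 64 entries, ordered wavelength-major, then direction, then f1..f4, and
#' named like `w1278.78_t45_f3`.
#'
#' @param images named list of band images (numeric matrices), one per
#'   selected wavelength; names are used in the feature labels.
#' @param mask logical ROI matrix shared by the images.
#' @param d GLCM offset distance (default 1 pixel).
#' @param levels gray levels (default 64).
#' @return named numeric vector of length `4 * 4 * length(images)`.
#' @export
texture_vector <- function(images, mask, d = 1, levels = 64) {
  out <- numeric(0)
  for (nm in names(images)) {
    rast <- quantize(images[[nm]], mask, levels)
    for (th in .glcm_thetas) {
      f <- glcm_features(glcm(rast, d = d, theta = th, levels = levels))
      names(f) <- sprintf("w%s_t%d_f%d", nm, th, 1:4)
      out <- c(out, f)
    }
  }
  out
}

#' Texture feature table for a synthetic cohort
#'
#' Renders each sample's scene at the selected wavelengths and extracts its
#' [texture_vector()], using the scene's oil mask as ROI.
#'
#' @param cohort an `oil_cohort` from [generate_cohort()].
#' @param subset a `wavelength_subset` (e.g. from [spa_select()]).
#' @param d,levels GLCM settings.
#' @return numeric matrix, samples x (16 * n selected wavelengths), with
#'   sample ids as row names.
#' @export
cohort_texture <- function(cohort, subset, d = 1, levels = 64) {
  ids <- cohort$reference$sample_id
  wl_names <- sprintf("%.2f", subset$wavelengths)
  rows <- lapply(seq_along(ids), function(s) {
    imgs <- lapply(subset$indices, function(b) render_band(cohort, s, b))
    names(imgs) <- wl_names
    texture_vector(imgs, cohort$scenes[[s]]$mask, d = d, levels = levels)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- ids
  out
}
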