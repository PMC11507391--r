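#' Savitzky-Golay smoothing and derivatives
#'
#' Per-spectrum local polynomial filtering over a sliding window, the
#' standard NIR smoothing/derivative pretreatment. Derivatives are returned
#' per nm (the filter is scaled by the band spacing), so magnitudes do not
#' depend on the grid density. Edges are handled by fitting the window
#' polynomial to the first/last points, so the wavelength axis keeps its
#' full length (a 512-band spectrum stays 512 columns after `deriv = 2`).
#'
#' @param set a [spectrum_set()] on an evenly spaced grid.
#' @param window odd window length (points). Default 11.
#' @param polyorder polynomial order, `< window`. Default 2.
#' @param deriv derivative order, 0 (smoothing), 1 or 2; `deriv <= polyorder`.
#' @return a [spectrum_set()] with provenance tag `"SG"`, `"1Der"` or
#'   `"2Der"`.
#' @export
sg_filter <- function(set, window = 11, polyorder = 2, deriv = 0) {
  wl <- wavelengths(set)
  if (window %% 2 != 1) stop("window must be odd")
  if (polyorder >= window) stop("polyorder must be below window length")
  if (!deriv %in% 0:2 || deriv > polyorder)
    stop("deriv must be 0, 1 or 2 and not exceed polyorder")
  if (window > length(wl)) stop("window exceeds the number of bands")
  dl <- diff(wl)
  if (max(dl) - min(dl) > 1e-6 * mean(dl))
    stop("Savitzky-Golay filtering needs an evenly spaced wavelength grid")
  ts <- mean(dl)
  Y <- t(apply(unclass(set), 1, function(r)
    signal::sgolayfilt(r, p = polyorder, n = window, m = deriv, ts = ts)))
  tag <- c("SG", "1Der", "2Der")[deriv + 1]
  restamp(set, Y, tag)
}

#' Standard normal variate transform
#'
#' Centres each spectrum to mean zero and scales it to unit standard
#' deviation (n - 1 denominator) -- removes per-sample multiplicative
#' scatter and additive offset.
#'
#' @param set a [spectrum_set()].
#' @return a [spectrum_set()] with provenance tag `"SNV"`.
#' @export
snv <- function(set) {
  X <- unclass(set)
  s <- apply(X, 1, sd)
  if (any(s == 0))
    stop("constant spectrum cannot be SNV-scaled: sample ",
         rownames(X)[which(s == 0)[1]])
  restamp(set, (X - rowMeans(X)) / s, "SNV")
}

#' Per-spectrum min-max normalization
#'
#' Maps each spectrum linearly onto `[0, 1]`.
#'
#' @param set a [spectrum_set()].
#' @return a [spectrum_set()] with provenance tag `"Normalize"`.
#' @export
minmax_normalize <- function(set) {
  X <- unclass(set)
  lo <- apply(X, 1, min); hi <- apply(X, 1, max)
  if (any(hi <= lo))
    stop("constant spectrum cannot be normalized: sample ",
         rownames(X)[which(hi <= lo)[1]])
  restamp(set, (X - lo) / (hi - lo), "Normalize")
}

#' Linear baseline correction
#'
#' Subtracts the least-squares straight line in wavelength from each
#' spectrum (linear detrend), removing offset and linear drift.
#'
#' @param set a [spectrum_set()].
#' @return a [spectrum_set()] with provenance tag `"Baseline"`.
#' @export
baseline_correct <- function(set) {
  wl <- wavelengths(set)
  if (length(wl) < 3L) stop("baseline correction needs at least 3 bands")
  Z <- cbind(1, wl - mean(wl))
  # projection of each row onto the line span, removed in one matrix product
  H <- Z %*% solve(crossprod(Z), t(Z))
  X <- unclass(set)
  restamp(set, X - X %*% t(H), "Baseline")
}

.pretreatments <- c("None", "Normalize", "1Der", "2Der", "Baseline", "SNV", "SG")

#' Apply a named pretreatment
#'
#' Dispatcher over the pretreatment set compared in the study: `"None"`,
#' `"Normalize"` (min-max), `"1Der"`/`"2Der"` (Savitzky-Golay derivatives),
#' `"Baseline"` (linear detrend), `"SNV"` and `"SG"` (Savitzky-Golay
#' smoothing). All are per-spectrum maps: nothing is learned from the
#' calibration set, so the same function applies at prediction time.
#'
#' @param set a [spectrum_set()].
#' @param method one of `"None"`, `"Normalize"`, `"1Der"`, `"2Der"`,
#'   `"Baseline"`, `"SNV"`, `"SG"`.
#' @param window,polyorder Savitzky-Golay settings for `"SG"`, `"1Der"`,
#'   `"2Der"`.
#' @return a [spectrum_set()].
#' @export
apply_pretreatment <- function(set, method, window = 11, polyorder = 2) {
  method <- match.arg(method, .pretreatments)
  switch(method,
    None      = set,
    Normalize = minmax_normalize(set),
    `1Der`    = sg_filter(set, window, polyorder, deriv = 1),
    `2Der`    = sg_filter(set, window, polyorder, deriv = 2),
    Baseline  = baseline_correct(set),
    SNV       = snv(set),
    SG        = sg_filter(set, window, polyorder, deriv = 0))
}
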