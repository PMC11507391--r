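#' Spectrum set container
#'
#' A `spectrum_set` is the working unit of the chemometric stages: a numeric
#' matrix of samples (rows) by wavelengths (columns), carrying the wavelength
#' grid in nm and an append-only provenance tag recording the pretreatments
#' applied so far (used to label models, e.g. `"2Der-SPA-PLSR"`).
#'
#' @param X numeric matrix, `n_samples x n_wavelengths`. Row names are taken
#'   as sample identifiers.
#' @param wavelengths numeric vector of band centres in nm, strictly
#'   increasing, one per column of `X`.
#' @param provenance character vector of pretreatment tags already applied,
#'   in order.
#' @return an object of class `spectrum_set` (a matrix with `wavelengths` and
#'   `provenance` attributes).
#' @export
spectrum_set <- function(X, wavelengths, provenance = character()) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (ncol(X) != length(wavelengths))
    stop("column count (", ncol(X), ") does not match wavelength count (",
         length(wavelengths), ")")
  if (length(wavelengths) > 1L && any(diff(wavelengths) <= 0))
    stop("wavelengths must be strictly increasing")
  if (anyNA(X) || any(!is.finite(X)))
    stop("spectra contain non-finite values")
  if (is.null(rownames(X)))
    rownames(X) <- sprintf("S%03d", seq_len(nrow(X)))
  structure(X,
            wavelengths = as.numeric(wavelengths),
            provenance  = as.character(provenance),
            class = c("spectrum_set", "matrix", "array"))
}

#' @rdname spectrum_set
#' @param x a `spectrum_set`.
#' @export
wavelengths <- function(x) attr(x, "wavelengths")

#' @rdname spectrum_set
#' @export
provenance <- function(x) attr(x, "provenance")

#' Provenance label for model naming
#'
#' Collapses the provenance chain into the compact label convention used in
#' model names: `"None"` for untouched spectra, otherwise tags joined by
#' `"-"` (e.g. `"SG-2Der"`).
#' @param x a `spectrum_set` or character vector of tags.
#' @return single character label.
#' @export
provenance_label <- function(x) {
  tags <- if (inherits(x, "spectrum_set")) provenance(x) else as.character(x)
  if (length(tags) == 0L) "None" else paste(tags, collapse = "-")
}

# rebuild a spectrum_set after a transform, appending a provenance tag
restamp <- function(template, X, tag = NULL) {
  prov <- provenance(template)
  if (!is.null(tag)) prov <- c(prov, tag)
  rownames(X) <- rownames(template)
  spectrum_set(X, wavelengths(template), prov)
}

#' @export
print.spectrum_set <- function(x, ...) {
  wl <- wavelengths(x)
  cat("<spectrum_set> ", nrow(x), " samples x ", ncol(x), " bands (",
      round(min(wl), 1), "-", round(max(wl), 1), " nm), pretreatment: ",
      provenance_label(x), "\n", sep = "")
  invisible(x)
}

# subsetting keeps attributes (base [ drops them)
#' @export
`[.spectrum_set` <- function(x, i, j, ..., drop = FALSE) {
  wl <- wavelengths(x); prov <- provenance(x)
  y <- unclass(x)[i, j, drop = FALSE]
  if (!missing(j)) wl <- wl[j]
  spectrum_set(y, wl, prov)
}
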