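#' Hyperspectral cube container
#'
#' A `hypercube` wraps a `rows x cols x bands` numeric array together with
#' its wavelength grid (nm). Band `b` of pixel `(i, j)` is `data[i, j, b]`;
#' pixel indices are row-major and 1-based throughout the package.
#'
#' @param data numeric 3-D array, rows x cols x bands.
#' @param wavelengths numeric vector, nm, strictly increasing, length equal
#'   to the third dimension of `data`.
#' @return object of class `hypercube`.
#' @export
hypercube <- function(data, wavelengths) {
  if (length(dim(data)) != 3L) stop("data must be a 3-D array")
  if (dim(data)[3] != length(wavelengths))
    stop("bands (", dim(data)[3], ") != wavelength count (",
         length(wavelengths), ")")
  if (length(wavelengths) > 1L && any(diff(wavelengths) <= 0))
    stop("wavelengths must be strictly increasing")
  if (any(!is.finite(data))) stop("cube contains non-finite values")
  structure(list(data = data, wavelengths = as.numeric(wavelengths)),
            class = "hypercube")
}

#' @export
print.hypercube <- function(x, ...) {
  d <- dim(x$data)
  cat("<hypercube> ", d[1], " x ", d[2], " pixels, ", d[3], " bands (",
      round(min(x$wavelengths), 1), "-", round(max(x$wavelengths), 1),
      " nm)\n", sep = "")
  invisible(x)
}

.envi_dtypes <- list(`4` = list(what = "numeric", size = 4L),
                     `12` = list(what = "integer", size = 2L))

#' Write a hypercube as an ENVI header + raw binary pair
#'
#' Writes `<path>.hdr` (text header with samples/lines/bands, data type,
#' interleave and the wavelength block) and `<path>.raw` (the raster).
#' Supported data types are float32 (ENVI type 4) and uint16 (type 12);
#' supported interleaves are BSQ, BIL and BIP. Little-endian byte order.
#' Round-tripping through [read_envi()] reproduces the data exactly for
#' float32 (uint16 is integer-quantised by the caller beforehand).
#'
#' @param cube a [hypercube()].
#' @param path output path stem (no extension).
#' @param interleave one of `"bsq"`, `"bil"`, `"bip"`.
#' @param dtype `"float32"` or `"uint16"`.
#' @return invisibly, the header path.
#' @export
write_envi <- function(cube, path, interleave = c("bsq", "bil", "bip"),
                       dtype = c("float32", "uint16")) {
  interleave <- match.arg(interleave)
  dtype <- match.arg(dtype)
  d <- dim(cube$data)
  nr <- d[1]; nc <- d[2]; nb <- d[3]
  code <- if (dtype == "float32") 4L else 12L
  hdr <- c("ENVI",
           paste0("samples = ", nc),
           paste0("lines = ", nr),
           paste0("bands = ", nb),
           "header offset = 0",
           "file type = ENVI Standard",
           paste0("data type = ", code),
           paste0("interleave = ", interleave),
           "byte order = 0",
           paste0("wavelength units = nm"),
           paste0("wavelength = { ",
                  paste(format(cube$wavelengths, trim = TRUE, digits = 10),
                        collapse = ", "), " }"))
  writeLines(hdr, paste0(path, ".hdr"))
  # reorder to the on-disk layout; ENVI rasters are line-major (row by row)
  vals <- switch(interleave,
    bsq = as.vector(aperm(cube$data, c(2, 1, 3))),   # col fastest, then row, band
    bil = as.vector(aperm(cube$data, c(2, 3, 1))),   # col, band, row
    bip = as.vector(aperm(cube$data, c(3, 2, 1))))   # band, col, row
  con <- file(paste0(path, ".raw"), "wb")
  on.exit(close(con))
  if (dtype == "float32") {
    writeBin(as.numeric(vals), con, size = 4L, endian = "little")
  } else {
    v <- as.integer(round(vals))
    if (any(v < 0 | v > 65535)) stop("uint16 values out of range")
    writeBin(v, con, size = 2L, endian = "little")
  }
  invisible(paste0(path, ".hdr"))
}

parse_envi_header <- function(header_path) {
  txt <- paste(readLines(header_path, warn = FALSE), collapse = "\n")
  get_num <- function(key) {
    m <- regmatches(txt, regexec(paste0("(?mi)^\\s*", key, "\\s*=\\s*(\\S+)"),
                                 txt, perl = TRUE))[[1]]
    if (length(m) < 2) stop("ENVI header missing field: ", key)
    as.numeric(m[2])
  }
  get_str <- function(key) {
    m <- regmatches(txt, regexec(paste0("(?mi)^\\s*", key, "\\s*=\\s*(\\S+)"),
                                 txt, perl = TRUE))[[1]]
    if (length(m) < 2) stop("ENVI header missing field: ", key)
    tolower(m[2])
  }
  wl_m <- regmatches(txt, regexec("wavelength\\s*=\\s*\\{([^}]*)\\}", txt))[[1]]
  if (length(wl_m) < 2) stop("ENVI header has no wavelength block")
  wl <- as.numeric(strsplit(gsub("[\n\r]", " ", wl_m[2]), ",")[[1]])
  list(samples = as.integer(get_num("samples")),
       lines = as.integer(get_num("lines")),
       bands = as.integer(get_num("bands")),
       dtype = as.integer(get_num("data type")),
       interleave = get_str("interleave"),
       wavelengths = wl)
}

#' Read an ENVI header + raw binary pair into a hypercube
#'
#' @param header_path path to the `.hdr` file; the raster is looked up at
#'   the same stem with extension `.raw`, `.img` or `.dat`, or no extension.
#' @return a [hypercube()].
#' @export
read_envi <- function(header_path) {
  h <- parse_envi_header(header_path)
  if (length(h$wavelengths) != h$bands)
    stop("header declares ", h$bands, " bands but lists ",
         length(h$wavelengths), " wavelengths")
  if (!h$interleave %in% c("bsq", "bil", "bip"))
    stop("unknown interleave: ", h$interleave)
  dt <- .envi_dtypes[[as.character(h$dtype)]]
  if (is.null(dt)) stop("unsupported ENVI data type code: ", h$dtype)
  stem <- sub("\\.hdr$", "", header_path)
  raw_path <- NULL
  for (ext in c(".raw", ".img", ".dat", "")) {
    cand <- paste0(stem, ext)
    if (file.exists(cand) && cand != header_path) { raw_path <- cand; break }
  }
  if (is.null(raw_path)) stop("raster file not found for ", header_path)
  n <- h$samples * h$lines * h$bands
  expected <- n * dt$size
  if (file.info(raw_path)$size != expected)
    stop("raster size ", file.info(raw_path)$size,
         " bytes does not match header (expected ", expected, ")")
  con <- file(raw_path, "rb")
  on.exit(close(con))
  vals <- readBin(con, what = dt$what, n = n, size = dt$size,
                  signed = dt$size > 2L, endian = "little")
  arr <- switch(h$interleave,
    bsq = aperm(array(vals, dim = c(h$samples, h$lines, h$bands)), c(2, 1, 3)),
    bil = aperm(array(vals, dim = c(h$samples, h$bands, h$lines)), c(3, 1, 2)),
    bip = aperm(array(vals, dim = c(h$bands, h$samples, h$lines)), c(3, 2, 1)))
  hypercube(arr, h$wavelengths)
}

#' Average reference frames
#'
#' White and dark reference acquisitions are averaged over repeated frames
#' before calibration to suppress shot noise.
#'
#' @param frames list of [hypercube()]s (or 3-D arrays) with identical shape.
#' @return a [hypercube()] (or array) of elementwise means.
#' @export
average_frames <- function(frames) {
  if (length(frames) < 1L) stop("no frames to average")
  arrs <- lapply(frames, function(f) if (inherits(f, "hypercube")) f$data else f)
  d <- dim(arrs[[1]])
  if (!all(vapply(arrs, function(a) identical(dim(a), d), logical(1))))
    stop("frames differ in shape")
  out <- Reduce(`+`, arrs) / length(arrs)
  if (inherits(frames[[1]], "hypercube"))
    hypercube(out, frames[[1]]$wavelengths) else out
}

#' Reflectance calibration against white and dark references
#'
#' Converts raw counts to reflectance per pixel and band:
#' `R = (raw - dark) / (white - dark)`, clipped to `[0, 1.05]` (slight
#' super-unity values occur over specular spots). References should already
#' be frame-averaged ([average_frames()]).
#'
#' @param raw,white,dark [hypercube()]s of identical shape.
#' @return calibrated [hypercube()].
#' @export
calibrate_reflectance <- function(raw, white, dark) {
  d <- dim(raw$data)
  if (!identical(d, dim(white$data)) || !identical(d, dim(dark$data)))
    stop("raw, white and dark cubes differ in shape")
  denom <- white$data - dark$data
  if (any(denom <= 0)) {
    bad <- which(apply(denom <= 0, 3, any))
    stop("white reference does not exceed dark at band(s) ",
         paste(head(bad, 5), collapse = ", "))
  }
  R <- (raw$data - dark$data) / denom
  hypercube(pmin(pmax(R, 0), 1.05), raw$wavelengths)
}

#' Segment the oil region of interest
#'
#' Averages the cube over a band window, thresholds the mean image (Otsu by
#' default) and keeps the largest connected foreground component. The oil
#' dish is the bright region against the dark stage at NIR wavelengths.
#'
#' @param cube calibrated [hypercube()].
#' @param band_window integer band indices to average over (default: all).
#' @param threshold `"otsu"` for automatic selection, or a numeric manual
#'   threshold on the mean-reflectance image.
#' @return logical matrix mask (TRUE = oil), with attribute `count`.
#' @export
segment_roi <- function(cube, band_window = NULL, threshold = "otsu") {
  d <- dim(cube$data)
  if (is.null(band_window)) band_window <- seq_len(d[3])
  img <- apply(cube$data[, , band_window, drop = FALSE], c(1, 2), mean)
  if (identical(threshold, "otsu")) {
    rng <- range(img)
    if (diff(rng) <= 0) stop("flat image; cannot segment")
    scaled <- (img - rng[1]) / diff(rng)
    thr <- EBImage::otsu(EBImage::Image(scaled), range = c(0, 1))
    mask <- scaled > thr
  } else {
    mask <- img > as.numeric(threshold)
  }
  if (!any(mask)) stop("segmentation produced an empty mask")
  lab <- EBImage::bwlabel(mask)
  sizes <- tabulate(lab[lab > 0])
  keep <- which.max(sizes)
  out <- matrix(as.vector(lab) == keep, d[1], d[2])
  structure(out, count = sum(out))
}

#' Mean spectrum over a pixel mask
#'
#' Per-band arithmetic mean of the reflectance of all masked pixels -- the
#' per-sample spectrum used for modelling.
#'
#' @param cube a [hypercube()].
#' @param mask logical matrix matching the cube's spatial shape.
#' @return numeric vector, one value per band.
#' @export
mean_spectrum <- function(cube, mask) {
  d <- dim(cube$data)
  if (!identical(dim(mask), d[1:2])) stop("mask shape does not match cube")
  if (sum(mask) < 1L) stop("mask selects no pixels")
  m <- matrix(cube$data, nrow = d[1] * d[2], ncol = d[3])
  colMeans(m[as.vector(mask), , drop = FALSE])
}

#' Average replicate spectra
#'
#' Elementwise mean over repeated acquisitions of the same sample.
#'
#' @param replicates list of numeric vectors of equal length.
#' @return numeric vector.
#' @export
average_replicates <- function(replicates) {
  if (length(replicates) < 1L) stop("no replicates")
  len <- length(replicates[[1]])
  if (!all(vapply(replicates, length, 1L) == len))
    stop("replicate spectra differ in length")
  Reduce(`+`, replicates) / length(replicates)
}
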