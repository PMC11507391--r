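#' Acid value from a titration record
#'
#' Computes the acid value (AV, mg KOH per g oil) from a hot-ethanol
#' titration: `AV = 56.1 * C * V / m`, where 56.1 is the molar mass of KOH
#' in g/mol, `C` the exact molarity of the KOH standard (mol/L), `V` the
#' titrant volume consumed (mL) and `m` the mass of the oil test portion (g).
#'
#' @param C KOH concentration, mol/L. Must be positive.
#' @param V titrant volume, mL. Must be non-negative.
#' @param m oil mass, g. Must be positive.
#' @return acid value(s), mg KOH / g oil. Vectorised over the inputs.
#' @examples
#' titration_av(C = 0.1, V = 0.25, m = 2)  # 0.70125 mg/g
#' @export
titration_av <- function(C, V, m) {
  if (any(!is.finite(C)) || any(!is.finite(V)) || any(!is.finite(m)))
    stop("titration inputs must be finite")
  if (any(C <= 0)) stop("KOH concentration C must be positive")
  if (any(m <= 0)) stop("oil mass m must be positive")
  if (any(V < 0)) stop("titrant volume V must be non-negative")
  56.1 * C * V / m
}

#' Average replicate acid-value determinations
#'
#' Each sample's AV is titrated in several replicates and the arithmetic
#' mean is reported.
#'
#' @param av numeric vector of replicate AV determinations for one sample.
#' @return scalar mean AV.
#' @export
average_av_replicates <- function(av) {
  if (length(av) < 1L || any(!is.finite(av))) stop("need finite replicate AVs")
  mean(av)
}

#' Draw a reference table of acid values
#'
#' Generates `n` acid values from a right-skewed Beta(shape1, shape2)
#' distribution rescaled to `[av_min, av_max]`. With the default Beta(2, 5)
#' shape the cohort mean sits near 0.70 mg/g for the default range
#' 0.32--1.59 mg/g, matching the skew of a typical fresh-to-slightly-aged
#' camellia oil cohort (a few high-AV samples, most near the low end).
#'
#' @param n number of samples (>= 1).
#' @param av_min,av_max range of acid values, mg/g (`av_min < av_max`).
#' @param shape1,shape2 Beta shape parameters of the skew.
#' @param seed optional integer; when given the draw is reproducible.
#' @return data.frame with columns `sample_id` and `av` (mg KOH/g).
#' @export
generate_reference_avs <- function(n, av_min = 0.32, av_max = 1.59,
                                   shape1 = 2, shape2 = 5, seed = NULL) {
  if (n < 1L) stop("n must be at least 1")
  if (!(av_min < av_max)) stop("av_min must be below av_max")
  if (av_min <= 0) stop("acid values must be positive")
  if (!is.null(seed)) set.seed(seed)
  av <- av_min + (av_max - av_min) * rbeta(n, shape1, shape2)
  data.frame(sample_id = sprintf("S%03d", seq_len(n)), av = av,
             stringsAsFactors = FALSE)
}

#' Spectral scene specification
#'
#' Bundles the parameters of the synthetic oil scene: the instrument grid
#' (512 bands over 870--1720 nm), the absorption bands of the oil spectrum,
#' how strongly the acid-sensitive bands respond to AV, and the noise and
#' texture settings. The oil spectrum is built in absorbance as a smooth
#' baseline plus Gaussian bands at 1115, 1330, 1520 and 1590 nm (C-H
#' stretch, C-H bend, O-H bend, and a second C-H overtone region); the
#' 1330 nm and 1520 nm amplitudes grow linearly with AV because those bands
#' carry the free-fatty-acid chemistry. Reflectance is `10^(-absorbance)`
#' plus Gaussian noise, a bounded Beer-Lambert-style surrogate rather than a
#' radiative-transfer model.
#'
#' The noise and nuisance magnitudes are set so a cohort of 153 samples
#' reproduces the working regime of a bench NIR imaging study of oil AV:
#' raw-spectrum models are mediocre, second-derivative models are good, and
#' the per-sample coupling jitter (`coupling_jitter_sd`) caps what spectra
#' alone can achieve so that image texture carries complementary signal.
#'
#' @param wavelengths band centres, nm, strictly increasing.
#' @param band_centers,band_widths,band_amps Gaussian band centres (nm),
#'   standard-deviation widths (nm) and baseline amplitudes (absorbance).
#' @param av_coupling absorbance gain per (mg/g) of AV, one per band; only
#'   the acid-sensitive bands are non-zero by default.
#' @param coupling_jitter_sd sd of the per-sample multiplicative jitter on
#'   the AV-coupled amplitudes (chemistry not perfectly collinear with AV).
#' @param offset_sd,tilt_sd,gain_sd per-sample additive baseline offset,
#'   linear tilt (absorbance per 1000 nm) and multiplicative scatter sd --
#'   the nuisance structure the pretreatments exist to remove.
#' @param interferent_centers,interferent_widths,interferent_amp_sd
#'   Gaussian bands of other constituents (water, triglyceride overtones
#'   unrelated to acidity) whose per-sample amplitudes vary independently
#'   of AV with the given sd; they sit away from the acid-sensitive bands,
#'   which is what makes characteristic-wavelength selection pay off.
#' @param interferent_shift_sd sd (nm) of per-sample shifts of the
#'   interferent band centres (temperature/matrix effects). Shifted narrow
#'   bands are a high-rank, nonlinear source of variance that full-spectrum
#'   models chase and selected-wavelength models never see.
#' @param wiggle_sd,wiggle_ell sd (absorbance) and correlation length (nm)
#'   of a per-sample smooth random baseline deviation. Unlike the offset /
#'   tilt / interferent terms this component is different for every sample
#'   and effectively high-rank across a cohort, emulating the residual
#'   scatter and matrix variation that no finite set of factors captures.
#' @param refl_gain_sd,refl_offset_sd per-sample multiplicative gain and
#'   additive (stray-light) offset applied in reflectance space -- the
#'   scatter effects that SNV / normalization / derivatives exist to
#'   remove, and the main reason models on raw spectra underperform.
#' @param noise_sd reflectance-unit sd of per-band instrument noise.
#' @param texture_coupling in `[0, 1]`; 0 decouples image texture from AV,
#'   1 ties the texture correlation length strongly to AV.
#' @param texture_sd relative sd of the multiplicative pixel texture field.
#' @param texture_ell0 texture correlation length (pixels) of an
#'   hypothetical AV-zero film; the length shrinks as
#'   `ell0 / (1 + texture_av_gain * texture_coupling * av)`.
#' @param texture_av_gain strength of the correlation-length shrinkage
#'   per (mg/g) of AV.
#' @return list of class `scene_spec`.
#' @export
spectral_scene_spec <- function(wavelengths = seq(870, 1720, length.out = 512),
                                band_centers = c(1115, 1330, 1520, 1590),
                                band_widths = c(32, 26, 18, 22),
                                band_amps = c(0.50, 0.16, 0.08, 0.40),
                                av_coupling = c(0, 0.22, 0.10, 0),
                                coupling_jitter_sd = 0.045,
                                offset_sd = 0.03, tilt_sd = 0.02,
                                gain_sd = 0.04,
                                interferent_centers = c(920, 960, 1040, 1205,
                                                        1420, 1650, 1700),
                                interferent_widths = c(20, 26, 22, 22,
                                                       20, 26, 18),
                                interferent_amp_sd = 0.05,
                                interferent_shift_sd = 8,
                                wiggle_sd = 0.006, wiggle_ell = 50,
                                refl_gain_sd = 0.02, refl_offset_sd = 0.015,
                                noise_sd = 1e-4,
                                texture_coupling = 0.6,
                                texture_sd = 0.12,
                                texture_ell0 = 6, texture_av_gain = 3.5) {
  if (any(diff(wavelengths) <= 0)) stop("wavelengths must be strictly increasing")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (texture_coupling < 0 || texture_coupling > 1)
    stop("texture_coupling must lie in [0, 1]")
  nb <- length(band_centers)
  stopifnot(length(band_widths) == nb, length(band_amps) == nb,
            length(av_coupling) == nb)
  stopifnot(length(interferent_widths) == length(interferent_centers))
  structure(list(wavelengths = as.numeric(wavelengths),
                 band_centers = band_centers, band_widths = band_widths,
                 band_amps = band_amps, av_coupling = av_coupling,
                 coupling_jitter_sd = coupling_jitter_sd,
                 offset_sd = offset_sd, tilt_sd = tilt_sd, gain_sd = gain_sd,
                 interferent_centers = interferent_centers,
                 interferent_widths = interferent_widths,
                 interferent_amp_sd = interferent_amp_sd,
                 interferent_shift_sd = interferent_shift_sd,
                 wiggle_sd = wiggle_sd, wiggle_ell = wiggle_ell,
                 refl_gain_sd = refl_gain_sd, refl_offset_sd = refl_offset_sd,
                 noise_sd = noise_sd,
                 texture_coupling = texture_coupling, texture_sd = texture_sd,
                 texture_ell0 = texture_ell0,
                 texture_av_gain = texture_av_gain),
            class = "scene_spec")
}

# Noise-free absorbance of an oil sample. `jitter` multiplies the AV-coupled
# part of each band; `offset`, `tilt`, `gain` are the per-sample nuisances;
# `interferents` are per-sample amplitude deviations of the non-acid bands.
oil_absorbance <- function(av, spec, jitter = 1, offset = 0, tilt = 0,
                           gain = 1, interferents = 0,
                           interferent_shifts = 0) {
  wl <- spec$wavelengths
  # smooth instrument/matrix baseline, gently rising with wavelength
  base <- 0.12 + 0.10 * (wl - wl[1]) / (wl[length(wl)] - wl[1])
  A <- base
  for (b in seq_along(spec$band_centers)) {
    amp <- spec$band_amps[b] + jitter * spec$av_coupling[b] * av
    A <- A + amp * exp(-((wl - spec$band_centers[b])^2) /
                         (2 * spec$band_widths[b]^2))
  }
  ia <- rep_len(interferents, length(spec$interferent_centers))
  ish <- rep_len(interferent_shifts, length(spec$interferent_centers))
  for (b in seq_along(spec$interferent_centers)) {
    ctr <- spec$interferent_centers[b] + ish[b]
    A <- A + ia[b] * exp(-((wl - ctr)^2) / (2 * spec$interferent_widths[b]^2))
  }
  gain * A + offset + tilt * (wl - mean(wl)) / 1000
}

# per-sample smooth baseline deviation: white noise over the band grid,
# Gaussian-smoothed at `wiggle_ell` nm, centred, rescaled to `wiggle_sd`
smooth_wiggle <- function(spec) {
  p <- length(spec$wavelengths)
  if (spec$wiggle_sd <= 0) return(numeric(p))
  sp <- mean(diff(spec$wavelengths))
  sig <- spec$wiggle_ell / sp
  half <- ceiling(3 * sig)
  k <- dnorm(seq(-half, half), sd = sig)
  z <- rnorm(p + 2 * half)
  sm <- as.numeric(stats::filter(z, k / sum(k), sides = 2))[(half + 1):(half + p)]
  sm <- sm - mean(sm)
  spec$wiggle_sd * sm / sd(sm)
}

#' Simulate one oil reflectance spectrum
#'
#' Builds the noise-free absorbance for a sample with the given acid value
#' and converts it to reflectance `10^(-A)`, adding per-band Gaussian noise
#' and clipping to `(0, 1]`. Reflectance shows local minima at the four
#' absorption bands; the minima at 1330 and 1520 nm deepen linearly with AV.
#'
#' @param av acid value, mg/g (> 0).
#' @param spec a [spectral_scene_spec()].
#' @param jitter,offset,tilt,gain,interferents,interferent_shifts,wiggle
#'   per-sample nuisance draws in absorbance space; defaults give the
#'   idealised spectrum.
#' @param refl_gain,refl_offset per-sample scatter draws in reflectance
#'   space (multiplicative gain, additive stray-light offset).
#' @return numeric reflectance vector over `spec$wavelengths`.
#' @export
generate_oil_spectrum <- function(av, spec = spectral_scene_spec(),
                                  jitter = 1, offset = 0, tilt = 0, gain = 1,
                                  interferents = 0, interferent_shifts = 0,
                                  wiggle = 0, refl_gain = 1, refl_offset = 0) {
  if (av <= 0) stop("av must be positive")
  A <- oil_absorbance(av, spec, jitter, offset, tilt, gain, interferents,
                      interferent_shifts) + wiggle
  r <- refl_gain * 10^(-A) + refl_offset
  if (spec$noise_sd > 0)
    r <- r + rnorm(length(r), sd = spec$noise_sd)
  pmin(pmax(r, 1e-6), 1)
}

# reflect an out-of-range index back into 1..n (mirror boundary)
mirror_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  m <- (i - 1L) %% (2L * n - 2L)
  ifelse(m >= n, 2L * n - 2L - m, m) + 1L
}

# separable Gaussian smoothing with mirrored boundaries; works for kernels
# larger than the frame (small scenes, long correlation lengths)
gauss_smooth2d <- function(z, sigma) {
  sigma <- max(sigma, 0.3)
  half <- ceiling(3 * sigma)
  k <- dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  smooth_cols <- function(m) {
    idx <- mirror_index(seq(1L - half, nrow(m) + half), nrow(m))
    padded <- m[idx, , drop = FALSE]
    out <- stats::filter(padded, k, sides = 2)
    matrix(out[(half + 1):(half + nrow(m)), ], nrow(m), ncol(m))
  }
  t(smooth_cols(t(smooth_cols(z))))
}

# spatially correlated multiplicative texture field over an r x c frame:
# white noise smoothed at correlation length `ell` (pixels), rescaled to
# mean 1 and relative sd `texture_sd` over the disk mask.
texture_field <- function(nr, nc, ell, texture_sd, mask) {
  z <- gauss_smooth2d(matrix(rnorm(nr * nc), nr, nc), ell)
  mu <- mean(z[mask]); s <- sd(z[mask])
  f <- 1 + texture_sd * (z - mu) / s
  pmax(f, 0.05)
}

disk_mask <- function(nr, nc, radius_frac = 0.38) {
  r0 <- (nr + 1) / 2; c0 <- (nc + 1) / 2
  rad <- radius_frac * min(nr, nc)
  outer(seq_len(nr), seq_len(nc),
        function(i, j) (i - r0)^2 + (j - c0)^2 <= rad^2)
}

# correlation length of the texture field, shrinking with AV when coupled:
# higher-AV (more degraded) oil films show finer surface micro-texture
texture_ell <- function(av, spec) {
  spec$texture_ell0 / (1 + spec$texture_av_gain * spec$texture_coupling * av)
}

#' Simulate a hyperspectral scene for one sample
#'
#' Renders a dish-on-stage scene: a disk-shaped oil region over a dark
#' background. Every oil pixel carries the sample's reflectance spectrum
#' multiplied by a spatially correlated texture field (mean 1 over the
#' disk); the field's correlation length shrinks with AV in proportion to
#' `texture_coupling`, which is what gives GLCM features predictive value.
#' Background pixels sit near zero reflectance.
#'
#' @param av acid value, mg/g.
#' @param spec a [spectral_scene_spec()].
#' @param shape integer `c(rows, cols)`, each >= 16.
#' @param radius_frac disk radius as a fraction of the short frame side.
#' @return list with `cube` (a [hypercube()]), `mask` (true oil mask,
#'   logical matrix) and `texture` (the multiplicative field).
#' @export
generate_hypercube <- function(av, spec = spectral_scene_spec(),
                               shape = c(48, 48), radius_frac = 0.38) {
  nr <- shape[1]; nc <- shape[2]
  if (nr < 16 || nc < 16) stop("frame must be at least 16 x 16 pixels")
  if (radius_frac * min(nr, nc) < 4 || radius_frac >= 0.5)
    stop("disk does not fit in the frame")
  mask <- disk_mask(nr, nc, radius_frac)
  tex <- texture_field(nr, nc, texture_ell(av, spec), spec$texture_sd, mask)
  tex <- tex / mean(tex[mask])          # exact mean 1 over the oil region
  refl <- 10^(-oil_absorbance(av, spec))
  p <- length(spec$wavelengths)
  cube <- array(0, dim = c(nr, nc, p))
  bg <- 0.02
  for (b in seq_len(p)) {
    plane <- matrix(bg, nr, nc)
    plane[mask] <- refl[b] * tex[mask]
    if (spec$noise_sd > 0)
      plane <- plane + matrix(rnorm(nr * nc, sd = spec$noise_sd), nr, nc)
    cube[, , b] <- pmin(pmax(plane, 1e-6), 1.05)
  }
  list(cube = hypercube(cube, spec$wavelengths), mask = mask, texture = tex)
}

#' Simulate a full oil cohort
#'
#' Draws `n` acid values, a reflectance spectrum per sample (with the
#' per-sample nuisance structure: coupling jitter, baseline offset, tilt,
#' multiplicative scatter, band noise), and a compact per-sample scene
#' (texture field + pixel-noise field over a disk mask) from which the image
#' at any band can be rendered with [render_band()]. Storing scenes instead
#' of full 512-band cubes keeps a 153-sample cohort small; a full cube for
#' any one sample is available via [generate_hypercube()].
#'
#' @param n cohort size (>= 10).
#' @param spec a [spectral_scene_spec()].
#' @param seed integer seed; the whole cohort is reproducible from it.
#' @param shape scene frame `c(rows, cols)`.
#' @return list of class `oil_cohort`: `spectra` (a [spectrum_set()]),
#'   `reference` (sample_id, av), `scenes` (per-sample list with `texture`,
#'   `noise`, `mask`, `av`), and the `spec` used.
#' @export
generate_cohort <- function(n = 153, spec = spectral_scene_spec(),
                            seed = NULL, shape = c(64, 64)) {
  if (n < 10) stop("cohort needs at least 10 samples")
  if (!is.null(seed)) set.seed(seed)
  ref <- generate_reference_avs(n)
  mask <- disk_mask(shape[1], shape[2])
  X <- matrix(0, n, length(spec$wavelengths))
  scenes <- vector("list", n)
  for (i in seq_len(n)) {
    jit <- 1 + rnorm(1, sd = spec$coupling_jitter_sd)
    off <- rnorm(1, sd = spec$offset_sd)
    tlt <- rnorm(1, sd = spec$tilt_sd)
    gn  <- 1 + rnorm(1, sd = spec$gain_sd)
    ints <- rnorm(length(spec$interferent_centers),
                  sd = spec$interferent_amp_sd)
    shf <- rnorm(length(spec$interferent_centers),
                 sd = spec$interferent_shift_sd)
    wig <- smooth_wiggle(spec)
    rg <- 1 + rnorm(1, sd = spec$refl_gain_sd)
    ro <- rnorm(1, sd = spec$refl_offset_sd)
    X[i, ] <- generate_oil_spectrum(ref$av[i], spec, jit, off, tlt, gn,
                                    ints, shf, wig, rg, ro)
    tex <- texture_field(shape[1], shape[2],
                         texture_ell(ref$av[i], spec), spec$texture_sd, mask)
    scenes[[i]] <- list(texture = tex / mean(tex[mask]),
                        noise = matrix(rnorm(prod(shape)), shape[1], shape[2]),
                        mask = mask, av = ref$av[i],
                        refl_base = NULL)
  }
  rownames(X) <- ref$sample_id
  names(scenes) <- ref$sample_id
  structure(list(spectra = spectrum_set(X, spec$wavelengths),
                 reference = ref, scenes = scenes, spec = spec),
            class = "oil_cohort")
}

#' Render the image of one cohort sample at one band
#'
#' Reconstructs the scene image at a wavelength index from the stored
#' texture and pixel-noise fields: oil pixels are the sample's noise-free
#' reflectance at that band times the texture field, plus instrument noise;
#' background is dark. Deterministic for a fixed cohort.
#'
#' @param cohort an `oil_cohort`.
#' @param sample sample index or id.
#' @param band band index into the wavelength grid.
#' @return numeric matrix (reflectance image).
#' @export
render_band <- function(cohort, sample, band) {
  sc <- cohort$scenes[[sample]]
  spec <- cohort$spec
  if (band < 1 || band > length(spec$wavelengths)) stop("band out of range")
  refl <- 10^(-oil_absorbance(sc$av, spec))[band]
  img <- matrix(0.02, nrow(sc$mask), ncol(sc$mask))
  img[sc$mask] <- refl * sc$texture[sc$mask]
  img <- img + spec$noise_sd * sc$noise
  pmin(pmax(img, 1e-6), 1.05)
}

#' @export
print.oil_cohort <- function(x, ...) {
  cat("<oil_cohort> ", nrow(x$spectra), " samples, ",
      ncol(x$spectra), " bands; AV ",
      round(min(x$reference$av), 2), "-", round(max(x$reference$av), 2),
      " mg/g (mean ", round(mean(x$reference$av), 2), ")\n", sep = "")
  invisible(x)
}
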