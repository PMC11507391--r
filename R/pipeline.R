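# Evaluation layer: Rc2/RMSEC and Rp2/RMSEP metrics, spectral + texture
# feature fusion, model-improvement arithmetic, and the three-tier
# experiment (full wavelengths -> selected wavelengths -> fused features).

#' Calibration/prediction metrics
#'
#' `r2` is the squared Pearson correlation between measured and predicted
#' values (so it always lies in `[0, 1]`); `rmse` is the root mean square
#' error in the units of `y` (mg/g for acid values). A coefficient-of-
#' determination variant is available via `mode = "q2"`.
#'
#' @param y_true measured values (length >= 3, non-constant).
#' @param y_pred predicted values.
#' @param mode `"pearson"` (default) or `"q2"` (1 - SSE/SST).
#' @return list with `r2` and `rmse`.
#' @export
regression_metrics <- function(y_true, y_pred, mode = c("pearson", "q2")) {
  mode <- match.arg(mode)
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  if (length(y_true) < 3) stop("need at least 3 observations")
  if (var(y_true) == 0) stop("y_true has no spread")
  rmse <- sqrt(mean((y_true - y_pred)^2))
  if (var(y_pred) == 0) {
    warning("predictions have zero spread; r2 reported as 0")
    r2 <- 0
  } else if (mode == "pearson") {
    r2 <- cor(y_true, y_pred)^2
  } else {
    r2 <- 1 - sum((y_true - y_pred)^2) / sum((y_true - mean(y_true))^2)
  }
  list(r2 = r2, rmse = rmse)
}

#' Fuse spectral and texture feature blocks
#'
#' Column-wise concatenation, spectral block first, after checking that the
#' row counts (and row names, when present) agree. An empty texture block
#' returns the spectral block unchanged. Scaling differences between the
#' blocks are handled downstream by autoscaled model fits, not here.
#'
#' @param spectral numeric matrix of spectral features.
#' @param texture numeric matrix of texture features (may have 0 columns).
#' @return fused matrix.
#' @export
fuse_features <- function(spectral, texture) {
  spectral <- as.matrix(spectral)
  if (is.null(texture) || NCOL(texture) == 0L) return(spectral)
  texture <- as.matrix(texture)
  if (nrow(spectral) != nrow(texture))
    stop("spectral and texture blocks have different sample counts")
  if (!is.null(rownames(spectral)) && !is.null(rownames(texture)) &&
      !identical(rownames(spectral), rownames(texture)))
    stop("spectral and texture blocks are in different sample order")
  cbind(spectral, texture)
}

#' Improvement between two model accuracies
#'
#' Two conventions coexist in the chemometrics literature and both are
#' reported here: `"relative"` is the relative change
#' `(new - old) / old * 100`; `"absolute_pp"` is the absolute difference in
#' percentage points `(new - old) * 100`. Results are rounded to two
#' decimals, the usual reporting precision.
#'
#' @param old,new accuracies (e.g. Rp2 values) in `[0, 1]`.
#' @param convention `"relative"` or `"absolute_pp"`.
#' @return percentage, rounded to 2 decimals.
#' @export
improvement <- function(old, new, convention = c("relative", "absolute_pp")) {
  convention <- match.arg(convention)
  if (any(old < 0 | old > 1) || any(new < 0 | new > 1))
    stop("accuracies must lie in [0, 1]")
  if (convention == "relative") {
    if (any(old == 0)) stop("relative improvement undefined for old = 0")
    round((new - old) / old * 100, 2)
  } else {
    round((new - old) * 100, 2)
  }
}

eval_model <- function(fit, Xcal, ycal, Xpred, ypred, label, tier, mode) {
  yc_hat <- predict(fit, Xcal)
  yp_hat <- predict(fit, Xpred)
  mc <- regression_metrics(ycal, yc_hat, mode)
  mp <- regression_metrics(ypred, yp_hat, mode)
  list(row = data.frame(label = label, tier = tier,
                        method = if (inherits(fit, "pls_model")) "PLSR" else "PCR",
                        ncomp = fit$ncomp, n_features = length(fit$coefficients),
                        rc2 = mc$r2, rmsec = mc$rmse, rp2 = mp$r2,
                        rmsep = mp$rmse, stringsAsFactors = FALSE),
       predicted = list(calibration = yc_hat, prediction = yp_hat))
}

#' Run the three-tier acid-value modelling experiment
#'
#' Reproduces the full study design on a cohort: (a) PCR and PLSR on all
#' wavelengths under each pretreatment; (b) PCR and PLSR on SPA- and
#' CARS-selected characteristic wavelengths of the reference pretreatment;
#' (c) PCR and PLSR on the fusion of the selected spectral features with
#' GLCM texture features at the selected wavelengths (autoscaled fits).
#' One Kennard-Stone split, computed on the reference-pretreatment spectra,
#' is shared by every model so the tiers are comparable.
#'
#' @param cohort an `oil_cohort` from [generate_cohort()] (or a list with
#'   `spectra` and `reference`; texture tier needs scenes).
#' @param pretreatments character vector of pretreatments for the
#'   full-wavelength tier.
#' @param reference_pretreatment the pretreatment whose spectra drive the
#'   split, wavelength selection and fusion tiers (default `"2Der"`, the
#'   strongest pretreatment for oil AV).
#' @param selection_methods subset of `c("SPA", "CARS")`.
#' @param with_texture run the fusion tier (needs cohort scenes).
#' @param cal_ratio Kennard-Stone calibration fraction.
#' @param f_max component cap for model selection. The default 20 leaves
#'   room for PCR on derivative spectra, where the response-relevant
#'   direction can sit beyond the leading principal components.
#' @param seed seed for CV folds and CARS sampling.
#' @param glcm_d,glcm_levels GLCM settings for the fusion tier.
#' @param r2_mode metric mode passed to [regression_metrics()].
#' @return list of class `av_experiment`: `models` (one row per fitted
#'   model with label, tier, Rc2, RMSEC, Rp2, RMSEP), `split`, `subsets`,
#'   and `improvements` comparing the best PLSR model of successive tiers
#'   under both conventions.
#' @export
run_experiment <- function(cohort,
                           pretreatments = c("None", "Normalize", "1Der",
                                             "2Der", "Baseline", "SNV", "SG"),
                           reference_pretreatment = "2Der",
                           selection_methods = c("SPA", "CARS"),
                           with_texture = TRUE,
                           cal_ratio = 0.6, f_max = 20, seed = 1,
                           glcm_d = 1, glcm_levels = 64,
                           r2_mode = "pearson") {
  spectra <- cohort$spectra
  y <- cohort$reference$av
  ref_set <- apply_pretreatment(spectra, reference_pretreatment)
  split <- ks_split(unclass(ref_set), ratio = cal_ratio)
  cal <- split$calibration; pred <- split$prediction
  rows <- list(); subsets <- list(); predicted <- list()

  for (pt in unique(c(pretreatments, reference_pretreatment))) {
    Xp <- if (pt == reference_pretreatment) ref_set
          else apply_pretreatment(spectra, pt)
    for (m in c("pcr", "plsr")) {
      fit <- fit_model(unclass(Xp)[cal, , drop = FALSE], y[cal], method = m,
                       f_max = f_max, seed = seed)
      lab <- paste0(provenance_label(Xp), "-", toupper(m))
      ev <- eval_model(fit, unclass(Xp)[cal, , drop = FALSE], y[cal],
                       unclass(Xp)[pred, , drop = FALSE], y[pred],
                       lab, "full", r2_mode)
      rows[[lab]] <- ev$row; predicted[[lab]] <- ev$predicted
    }
  }

  Xr <- unclass(ref_set)
  wl <- wavelengths(ref_set)
  for (selm in selection_methods) {
    sub <- if (selm == "SPA")
      spa_select(Xr[cal, , drop = FALSE], y[cal], wl = wl)
    else
      cars_select(Xr[cal, , drop = FALSE], y[cal], wl = wl, seed = seed)
    subsets[[selm]] <- sub
    for (m in c("pcr", "plsr")) {
      Xs <- Xr[, sub$indices, drop = FALSE]
      fit <- fit_model(Xs[cal, , drop = FALSE], y[cal], method = m,
                       f_max = min(f_max, length(sub$indices)), seed = seed)
      lab <- paste0(provenance_label(ref_set), "-", selm, "-", toupper(m))
      ev <- eval_model(fit, Xs[cal, , drop = FALSE], y[cal],
                       Xs[pred, , drop = FALSE], y[pred],
                       lab, "selected", r2_mode)
      rows[[lab]] <- ev$row; predicted[[lab]] <- ev$predicted
    }
  }

  if (with_texture && "SPA" %in% names(subsets) &&
      !is.null(cohort$scenes)) {
    sub <- subsets[["SPA"]]
    tex <- cohort_texture(cohort, sub, d = glcm_d, levels = glcm_levels)
    fused <- fuse_features(Xr[, sub$indices, drop = FALSE], tex)
    for (m in c("pcr", "plsr")) {
      fit <- fit_model(fused[cal, , drop = FALSE], y[cal], method = m,
                       scale = TRUE, f_max = f_max, seed = seed)
      lab <- paste0(provenance_label(ref_set), "-SPA-GLCM-", toupper(m))
      ev <- eval_model(fit, fused[cal, , drop = FALSE], y[cal],
                       fused[pred, , drop = FALSE], y[pred],
                       lab, "fused", r2_mode)
      rows[[lab]] <- ev$row; predicted[[lab]] <- ev$predicted
    }
  }

  models <- do.call(rbind, rows)
  rownames(models) <- NULL
  structure(list(models = models, split = split, subsets = subsets,
                 predicted = predicted,
                 improvements = tier_improvements(models),
                 reference_pretreatment = reference_pretreatment),
            class = "av_experiment")
}

# best-PLSR-per-tier improvement table, both conventions
tier_improvements <- function(models) {
  pl <- models[models$method == "PLSR", , drop = FALSE]
  best <- lapply(split(pl, pl$tier), function(d) d[which.max(d$rp2), ])
  pairs <- list(c("full", "selected"), c("selected", "fused"),
                c("full", "fused"))
  out <- list()
  for (pr in pairs) {
    a <- best[[pr[1]]]; b <- best[[pr[2]]]
    if (is.null(a) || is.null(b)) next
    out[[paste(pr, collapse = "->")]] <- data.frame(
      from = a$label, to = b$label,
      rc2_rel = improvement(a$rc2, b$rc2, "relative"),
      rp2_rel = improvement(a$rp2, b$rp2, "relative"),
      rc2_pp = improvement(a$rc2, b$rc2, "absolute_pp"),
      rp2_pp = improvement(a$rp2, b$rp2, "absolute_pp"),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' @export
print.av_experiment <- function(x, ...) {
  cat("<av_experiment> ", nrow(x$models), " models over tiers: ",
      paste(unique(x$models$tier), collapse = ", "), "\n", sep = "")
  m <- x$models
  m$rc2 <- round(m$rc2, 4); m$rmsec <- round(m$rmsec, 4)
  m$rp2 <- round(m$rp2, 4); m$rmsep <- round(m$rmsep, 4)
  print(m[, c("label", "ncomp", "rc2", "rmsec", "rp2", "rmsep")],
        row.names = FALSE)
  invisible(x)
}
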