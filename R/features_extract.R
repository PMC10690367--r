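# Feature-extraction driver: maps x filters x feature classes -> one named
# row per sample, with provenance packed into the column names as
# map__filter__class__feature.

#' Feature extraction configuration
#'
#' @param filters character vector of filter names (see [apply_filter()]).
#' @param classes feature classes to compute, subset of
#'   c("firstorder", "glcm", "glrlm", "glszm", "gldm", "shape").
#' @param bins discretization bin count for texture/entropy features.
#' @param spacing voxel spacing for shape features.
#' @return list of class \code{feature_config}.
#' @export
feature_config <- function(filters = "original",
                           classes = c("firstorder", "glcm"),
                           bins = 32L,
                           spacing = c(1, 1, 1)) {
  ok <- c("firstorder", "glcm", "glrlm", "glszm", "gldm", "shape")
  stopifnot(all(classes %in% ok), bins >= 2)
  structure(list(filters = filters, classes = classes, bins = as.integer(bins),
                 spacing = spacing), class = "feature_config")
}

# Features of one (map, filter) combination; returns a named vector. Texture
# classes need >= 2 in-mask voxels with at least one co-occurring pair; on
# degenerate ROIs those entries come back NA with a warning-free flag.
extract_map_filter <- function(map, mask, filt, config) {
  # neighborhood filters read voxels just outside the ROI, where parametric
  # maps are undefined; pad them with the in-mask mean before filtering
  if (any(!is.finite(map[!mask]))) {
    map[!mask & !is.finite(map)] <- mean(map[mask])
  }
  fmap <- apply_filter(map, filt)
  out <- numeric(0)
  texture_classes <- intersect(config$classes,
                               c("glcm", "glrlm", "glszm", "gldm"))
  lev <- NULL
  if (length(texture_classes)) {
    lev <- discretize(fmap, mask, bins = config$bins)
  }
  add <- function(vals, cls) {
    names(vals) <- paste0(cls, "__", names(vals))
    c(out, vals)
  }
  for (cls in config$classes) {
    vals <- tryCatch(switch(cls,
      firstorder = first_order_features(fmap, mask, bins = config$bins),
      glcm = glcm_features(lev, mask),
      glrlm = glrlm_features(lev, mask),
      glszm = glszm_features(lev, mask),
      gldm = gldm_features(lev, mask),
      shape = NULL  # handled once per sample, filter-independent
    ), error = function(e) {
      proto <- feature_class_names(cls)
      setNames(rep(NA_real_, length(proto)), proto)
    })
    if (!is.null(vals)) out <- add(vals, cls)
  }
  out
}

# Canonical feature names per class (for NA-flagging degenerate ROIs and
# stable column sets).
feature_class_names <- function(cls) {
  switch(cls,
    firstorder = c("mean", "variance", "skewness", "kurtosis", "energy",
                   "entropy", "minimum", "maximum", "range", "p10", "p50",
                   "p90", "mad"),
    glcm = c("contrast", "correlation", "joint_energy", "joint_entropy",
             "homogeneity"),
    glrlm = c("short_run_emphasis", "long_run_emphasis",
              "gray_level_nonuniformity", "run_length_nonuniformity",
              "run_percentage"),
    glszm = c("small_area_emphasis", "large_area_emphasis",
              "gray_level_nonuniformity", "size_zone_nonuniformity",
              "zone_percentage"),
    gldm = c("small_dependence_emphasis", "large_dependence_emphasis",
             "gray_level_nonuniformity", "dependence_nonuniformity",
             "dependence_entropy"),
    shape = c("volume", "surface_area", "sphericity", "max_diameter_3d",
              "elongation", "flatness"),
    stop("unknown feature class: ", cls, call. = FALSE)
  )
}

#' Extract all configured radiomic features for one sample
#'
#' Iterates maps x filters x feature classes and concatenates the feature
#' vectors. Shape features (mask-only, filter-independent) are computed once
#' per sample under the name \code{shape__original__shape__*}. Invalid maps
#' (any non-finite in-mask values) yield NA-flagged features for that map.
#'
#' @param map_set named list of 3D numeric arrays (the parametric maps).
#' @param mask logical ROI array shared by all maps.
#' @param config a [feature_config()].
#' @return named numeric vector; names are
#'   \code{map__filter__class__feature}.
#' @export
extract_all <- function(map_set, mask, config = feature_config()) {
  stopifnot(length(map_set) >= 1, !is.null(names(map_set)), any(mask))
  row <- numeric(0)
  for (mname in names(map_set)) {
    map <- map_set[[mname]]
    bad <- any(!is.finite(map[mask]))
    for (filt in config$filters) {
      vals <- if (bad) {
        nm <- unlist(lapply(setdiff(config$classes, "shape"), function(cls) {
          paste0(cls, "__", feature_class_names(cls))
        }))
        setNames(rep(NA_real_, length(nm)), nm)
      } else {
        extract_map_filter(map, mask, filt, config)
      }
      if (length(vals)) {
        names(vals) <- paste0(mname, "__", filt, "__", names(vals))
        row <- c(row, vals)
      }
    }
  }
  if ("shape" %in% config$classes) {
    sh <- shape_features(mask, config$spacing)
    names(sh) <- paste0("shape__original__shape__", names(sh))
    row <- c(row, sh)
  }
  stopifnot(!anyDuplicated(names(row)))
  row
}

#' Build a feature table for a phantom cohort
#'
#' Computes the configured parametric maps per phantom and extracts one
#' feature row per phantom per map. Maps supported on the cheap (non-LM)
#' route: \code{MSI}, \code{TMAX}, \code{nrCBV}, \code{K1_unidir},
#' \code{K2_unidir}, \code{K1_bidir}, \code{K2_bidir}, \code{Kep_bidir},
#' \code{nrCBV_unidir}, \code{nrCBV_bidir}. Gamma-fit maps (rCBF, rMTT,
#' rCBV) are available via \code{fit_gamma = TRUE}.
#'
#' @param cohort list of labeled phantoms from [make_cohort()].
#' @param maps character vector of map names to compute.
#' @param config a [feature_config()].
#' @param fit_gamma run the voxelwise gamma LM fit (needed for
#'   rCBF/rMTT/rCBV).
#' @return list with \code{features} (matrix, samples x features),
#'   \code{labels} (integer vector), \code{ids}.
#' @export
cohort_feature_table <- function(cohort,
                                 maps = c("MSI", "nrCBV", "K2_unidir",
                                          "K1_bidir"),
                                 config = feature_config(
                                   filters = c("original", "wavelet-LLL",
                                               "wavelet-HHH"),
                                   classes = c("firstorder", "glcm")),
                                 fit_gamma = FALSE) {
  rows <- lapply(cohort, function(ph) {
    ms <- phantom_parametric_maps(ph, maps = maps, fit_gamma = fit_gamma)
    extract_all(ms, ph$tumor_mask, config)
  })
  nm <- names(rows[[1]])
  stopifnot(all(vapply(rows, function(r) identical(names(r), nm), logical(1))))
  X <- do.call(rbind, rows)
  rownames(X) <- vapply(cohort, `[[`, character(1), "id")
  list(features = X,
       labels = vapply(cohort, `[[`, integer(1), "label"),
       ids = rownames(X))
}

#' Parametric maps of one phantom
#'
#' Converts the phantom's 4D signal to concentration and computes the
#' requested maps inside the tumor ROI: MSI and TMAX from the measured
#' curves, nrCBV and the leakage-model maps from the exchange fits, and
#' (optionally) the gamma-fit maps rCBF/rMTT/rCBV.
#'
#' @param phantom a [build_phantom()] result.
#' @param maps map names to return.
#' @param fit_gamma run voxelwise gamma fits for rCBF/rMTT/rCBV.
#' @return named list of 3D arrays.
#' @export
phantom_parametric_maps <- function(phantom,
                                    maps = c("MSI", "nrCBV", "K2_unidir",
                                             "K1_bidir"),
                                    fit_gamma = FALSE) {
  ser <- phantom$series
  conc <- series_to_concentration(ser)
  tg <- series_time_grid(ser)
  t0 <- attr(ser, "n_baseline")
  mask <- phantom$tumor_mask
  idx <- which(mask)
  nt <- dim(conc)[4]
  flat <- matrix(conc, ncol = nt)

  out <- list()
  if (any(c("MSI", "TMAX") %in% maps)) {
    msi <- array(NA_real_, dim = dim(mask))
    tmax <- array(NA_real_, dim = dim(mask))
    for (v in idx) {
      tm <- curve_tmax(flat[v, ], tg)
      msi[v] <- mean_slope_increase(flat[v, ], t0, tm$index)$msi
      tmax[v] <- tm$tmax
    }
    out$MSI <- msi
    out$TMAX <- tmax
  }
  leak_maps <- intersect(maps, c("nrCBV", "K1_unidir", "K2_unidir",
                                 "nrCBV_unidir", "K1_bidir", "K2_bidir",
                                 "Kep_bidir", "nrCBV_bidir"))
  if (length(leak_maps)) {
    ref <- compute_reference_curve(conc, phantom$brain_mask, mask)
    models <- character(0)
    if (any(grepl("unidir", leak_maps))) models <- c(models, "unidir")
    if (any(grepl("bidir", leak_maps))) models <- c(models, "bidir")
    if (!length(models)) models <- "unidir"  # nrCBV alone still needs the pass
    lm_set <- compute_leakage_maps(conc, mask, ref, tg, t0, models = models)
    for (m in leak_maps) out[[m]] <- lm_set[[m]]
  }
  if (fit_gamma || any(c("rCBF", "rMTT", "rCBV") %in% maps)) {
    aif <- phantom$ground_truth$aif
    fits <- lapply(idx, function(v) fit_gamma_model(flat[v, ], aif, tg))
    conc_mat <- flat[idx, , drop = FALSE]
    pm <- compute_derived_maps(fits, conc_mat, tg, t0, mask)
    for (m in intersect(maps, c("rCBF", "rMTT", "rCBV"))) out[[m]] <- pm[[m]]
  }
  out[maps]
}
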