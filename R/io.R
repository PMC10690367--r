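# Containers and standard-format I/O: 4D DSC series and 3D masks as
# NIfTI-1 (via RNifti), AIF and feature tables as CSV.

#' 4D DSC series container
#'
#' A plain 4D array (x, y, z, t) carrying acquisition metadata as
#' attributes: temporal resolution \code{dt} (s), echo time \code{te} (s),
#' number of pre-bolus baseline frames \code{n_baseline}, and optionally the
#' NIfTI affine of origin.
#'
#' @param data numeric 4D array.
#' @param dt temporal resolution, seconds.
#' @param te echo time, seconds.
#' @param n_baseline number of baseline frames.
#' @param affine optional 4x4 affine matrix.
#' @return object of class \code{dsc_series}.
#' @export
dsc_series <- function(data, dt, te, n_baseline, affine = NULL) {
  stopifnot(length(dim(data)) == 4, dt > 0, te > 0,
            n_baseline >= 1, n_baseline < dim(data)[4])
  structure(data, dt = dt, te = te, n_baseline = as.integer(n_baseline),
            affine = affine, class = c("dsc_series", "array"))
}

#' Time axis of a DSC series
#' @param series a [dsc_series()].
#' @return vector of frame times in seconds, starting at 0.
#' @export
series_time_grid <- function(series) {
  (seq_len(dim(series)[4]) - 1) * attr(series, "dt")
}

#' Voxelwise signal-to-concentration conversion of a whole series
#'
#' Applies [signal_to_concentration()] to every voxel, using the series'
#' baseline length; returns a plain 4D concentration array. Voxels with a
#' nonpositive baseline yield NA curves.
#'
#' @param series a [dsc_series()].
#' @return 4D numeric array of concentrations (s^-1), with attributes
#'   \code{n_clamped} (total clamped samples) and \code{n_invalid} voxels.
#' @export
series_to_concentration <- function(series) {
  nt <- dim(series)[4]
  nb <- attr(series, "n_baseline")
  te <- attr(series, "te")
  flat <- matrix(series, ncol = nt)
  s0 <- rowMeans(flat[, seq_len(nb), drop = FALSE])
  ok <- is.finite(s0) & s0 > 0
  conc <- matrix(NA_real_, nrow = nrow(flat), ncol = nt)
  floor_vals <- 1e-3 * s0[ok]
  v <- pmax(flat[ok, , drop = FALSE], floor_vals)
  n_clamped <- sum(flat[ok, , drop = FALSE] <= 0)
  conc[ok, ] <- -log(v / s0[ok]) / te
  out <- array(conc, dim = dim(series))
  attr(out, "n_clamped") <- n_clamped
  attr(out, "n_invalid") <- sum(!ok)
  out
}

#' Read a 4D DSC series from a NIfTI-1 file
#'
#' @param path NIfTI file (.nii or .nii.gz).
#' @param dt temporal resolution in seconds (required; DSC NIfTIs rarely
#'   carry a trustworthy TR in the header).
#' @param te echo time, seconds.
#' @param n_baseline number of baseline frames.
#' @return a [dsc_series()] with the file's affine attached.
#' @export
read_dsc_series <- function(path, dt, te, n_baseline) {
  if (missing(dt) || is.null(dt)) {
    stop("dt (temporal resolution, seconds) is required", call. = FALSE)
  }
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 4) {
    stop("expected a 4D series with a time axis; got ",
         length(dim(img)), "D", call. = FALSE)
  }
  dsc_series(array(as.numeric(img), dim = dim(img)), dt = dt, te = te,
             n_baseline = n_baseline, affine = RNifti::xform(img))
}

#' Write a 4D DSC series (or any array) as NIfTI-1
#' @param data array (3D map or 4D series); NA is written as NaN.
#' @param path output path (.nii or .nii.gz).
#' @param affine optional 4x4 affine to preserve.
#' @return the path, invisibly.
#' @export
write_nifti_map <- function(data, path, affine = NULL) {
  arr <- array(as.numeric(data), dim = dim(data))
  img <- RNifti::asNifti(arr)
  if (!is.null(affine)) img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a binary mask as unsigned 8-bit NIfTI (nonzero = inside)
#' @param mask logical array.
#' @param path output path.
#' @param affine optional affine.
#' @return the path, invisibly.
#' @export
write_nifti_mask <- function(mask, path, affine = NULL) {
  arr <- array(as.integer(mask), dim = dim(mask))
  img <- RNifti::asNifti(arr, datatype = "uint8")
  if (!is.null(affine)) img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a mask NIfTI as a logical array
#' @param path NIfTI file.
#' @return logical array.
#' @export
read_nifti_mask <- function(path) {
  img <- RNifti::readNifti(path)
  array(as.numeric(img) != 0, dim = dim(img))
}

#' Read an arterial input function from a two-column CSV
#' @param path CSV with header and columns time (s), value.
#' @return list with \code{time}, \code{values}.
#' @export
read_aif_csv <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(ncol(df) >= 2)
  list(time = df[[1]], values = df[[2]])
}

#' Write an AIF curve as CSV
#' @param time,values numeric vectors.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_aif_csv <- function(time, values, path) {
  utils::write.csv(data.frame(time = time, value = values), path,
                   row.names = FALSE)
  invisible(path)
}

#' Write a cohort feature table as CSV (rows = samples, label column last)
#' @param table list from [cohort_feature_table()].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_feature_csv <- function(table, path) {
  df <- as.data.frame(table$features)
  df$label <- table$labels
  utils::write.csv(cbind(id = table$ids, df), path, row.names = FALSE)
  invisible(path)
}

#' Read a feature table CSV written by [write_feature_csv()]
#' @param path CSV path.
#' @return list with \code{features}, \code{labels}, \code{ids}.
#' @export
read_feature_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  ids <- df$id
  labels <- as.integer(df$label)
  X <- as.matrix(df[, setdiff(names(df), c("id", "label")), drop = FALSE])
  rownames(X) <- ids
  list(features = X, labels = labels, ids = ids)
}
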