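# Image filters producing derived maps for radiomics: separable one-level
# wavelet decomposition, Laplacian of Gaussian, gradient magnitude,
# logarithmic/exponential intensity transforms, and slice-wise LBP.

# 1-D neighbor-pair filters along one axis of a 3D array with replicate
# padding: low = (x[i] + x[i+1]) / 2, high = (x[i] - x[i+1]) / 2.
axis_pair_filter <- function(arr, axis, kind) {
  d <- dim(arr)
  idx_next <- pmin(seq_len(d[axis]) + 1L, d[axis])
  slicer <- function(ix) {
    args <- rep(list(quote(expr = )), 3)
    args[[axis]] <- ix
    do.call(`[`, c(list(arr), args, list(drop = FALSE)))
  }
  nxt <- slicer(idx_next)
  if (kind == "low") (arr + nxt) / 2 else (arr - nxt) / 2
}

#' One-level separable wavelet decomposition of a 3D map
#'
#' Applies a two-tap averaging (L) or differencing (H) filter along each
#' axis in turn (undecimated, replicate edge handling), yielding the 8
#' sub-bands LLL..HHH. The LLL band of a constant image is the image itself;
#' every band containing an H is identically zero on a constant image.
#'
#' @param map numeric 3D array.
#' @param bands character vector of sub-band names ("LLL", "HHL", ...);
#'   default all 8.
#' @return named list of arrays, one per requested band.
#' @export
wavelet_bands <- function(map, bands = NULL) {
  stopifnot(length(dim(map)) == 3)
  if (is.null(bands)) {
    bands <- apply(expand.grid(c("L", "H"), c("L", "H"), c("L", "H")), 1,
                   paste0, collapse = "")
  }
  out <- lapply(bands, function(b) {
    ks <- strsplit(b, "")[[1]]
    stopifnot(length(ks) == 3, all(ks %in% c("L", "H")))
    a <- map
    for (axis in 1:3) {
      a <- axis_pair_filter(a, axis, if (ks[axis] == "L") "low" else "high")
    }
    a
  })
  names(out) <- bands
  out
}

# Separable Gaussian smoothing with a discrete sampled kernel (sigma in
# voxels), replicate padding.
gaussian_smooth <- function(map, sigma) {
  if (sigma <= 0) return(map)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  d <- dim(map)
  out <- map
  for (axis in 1:3) {
    acc <- array(0, dim = d)
    for (j in seq_along(k)) {
      off <- j - r - 1L
      idx <- pmin(pmax(seq_len(d[axis]) + off, 1L), d[axis])
      args <- rep(list(quote(expr = )), 3)
      args[[axis]] <- idx
      acc <- acc + k[j] * do.call(`[`, c(list(out), args, list(drop = FALSE)))
    }
    out <- acc
  }
  out
}

# Discrete 6-neighbor Laplacian with replicate padding (zero on constants).
laplacian3d <- function(map) {
  d <- dim(map)
  shift <- function(axis, off) {
    idx <- pmin(pmax(seq_len(d[axis]) + off, 1L), d[axis])
    args <- rep(list(quote(expr = )), 3)
    args[[axis]] <- idx
    do.call(`[`, c(list(map), args, list(drop = FALSE)))
  }
  shift(1, 1) + shift(1, -1) + shift(2, 1) + shift(2, -1) +
    shift(3, 1) + shift(3, -1) - 6 * map
}

#' Apply a named image filter to a 3D map
#'
#' Supported filters: \code{"wavelet-<band>"} (e.g. "wavelet-LLL"),
#' \code{"log-sigma-<s>"} (Laplacian of Gaussian at sigma s voxels),
#' \code{"gradient"} (central-difference gradient magnitude),
#' \code{"logarithm"} (\code{log(x - min + 1)} shift-log transform),
#' \code{"exponential"} (\code{exp(x)}; its exact inverse is
#' \code{log}, used by \code{"logarithm-raw"}), \code{"lbp-2d"}
#' (slice-wise 8-neighbor local binary pattern codes), and
#' \code{"original"} (identity).
#'
#' @param map numeric 3D array.
#' @param filter_spec filter name string.
#' @return filtered array, same shape.
#' @export
apply_filter <- function(map, filter_spec) {
  stopifnot(length(dim(map)) == 3)
  if (filter_spec == "original") return(map)
  if (startsWith(filter_spec, "wavelet-")) {
    band <- sub("^wavelet-", "", filter_spec)
    return(wavelet_bands(map, bands = band)[[1]])
  }
  if (startsWith(filter_spec, "log-sigma-")) {
    sigma <- as.numeric(sub("^log-sigma-", "", filter_spec))
    stopifnot(is.finite(sigma), sigma > 0)
    return(laplacian3d(gaussian_smooth(map, sigma)))
  }
  switch(filter_spec,
    gradient = gradient_magnitude(map),
    logarithm = log(map - min(map) + 1),
    `logarithm-raw` = log(pmax(map, .Machine$double.xmin)),
    exponential = exp(map),
    `lbp-2d` = lbp_2d(map),
    stop("unknown filter: ", filter_spec, call. = FALSE)
  )
}

# Central-difference gradient magnitude with replicate padding.
gradient_magnitude <- function(map) {
  d <- dim(map)
  shift <- function(axis, off) {
    idx <- pmin(pmax(seq_len(d[axis]) + off, 1L), d[axis])
    args <- rep(list(quote(expr = )), 3)
    args[[axis]] <- idx
    do.call(`[`, c(list(map), args, list(drop = FALSE)))
  }
  gx <- (shift(1, 1) - shift(1, -1)) / 2
  gy <- (shift(2, 1) - shift(2, -1)) / 2
  gz <- (shift(3, 1) - shift(3, -1)) / 2
  sqrt(gx^2 + gy^2 + gz^2)
}

# Slice-wise local binary pattern with 8 neighbors (axial slices, replicate
# padding): code = sum over neighbors of 2^k * (neighbor >= center).
lbp_2d <- function(map) {
  d <- dim(map)
  out <- array(0, dim = d)
  neigh <- list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, 1),
                c(1, 1), c(1, 0), c(1, -1), c(0, -1))
  for (z in seq_len(d[3])) {
    sl <- map[, , z]
    code <- matrix(0, d[1], d[2])
    for (k in seq_along(neigh)) {
      o <- neigh[[k]]
      xs <- pmin(pmax(seq_len(d[1]) + o[1], 1L), d[1])
      ys <- pmin(pmax(seq_len(d[2]) + o[2], 1L), d[2])
      code <- code + 2^(k - 1) * (sl[xs, ys] >= sl)
    }
    out[, , z] <- code
  }
  out
}

#' Shape descriptors of a binary ROI
#'
#' Mesh-free descriptors: voxel-count volume, face-counting surface area
#' (exposed voxel faces times face area), sphericity
#' \eqn{\pi^{1/3}(6V)^{2/3}/A}, maximum 3D diameter (largest pairwise
#' voxel-center distance), and elongation/flatness from the principal-axis
#' second moments (sqrt of eigenvalue ratios).
#'
#' @param mask logical 3D array, nonempty.
#' @param spacing voxel spacing (mm or any length unit), length 3.
#' @return named numeric vector.
#' @export
shape_features <- function(mask, spacing = c(1, 1, 1)) {
  stopifnot(any(mask), length(spacing) == 3)
  d <- dim(mask)
  coords <- which(mask, arr.ind = TRUE)
  n <- nrow(coords)
  vox_vol <- prod(spacing)
  volume <- n * vox_vol

  # exposed faces: neighbor out of bounds or outside the mask
  faces <- 0
  face_area <- c(spacing[2] * spacing[3], spacing[1] * spacing[3],
                 spacing[1] * spacing[2])
  for (axis in 1:3) {
    for (off in c(-1L, 1L)) {
      q <- coords
      q[, axis] <- q[, axis] + off
      outside <- q[, axis] < 1 | q[, axis] > d[axis]
      inb <- !outside
      exposed <- sum(outside)
      if (any(inb)) {
        lin <- (q[inb, 3] - 1L) * d[1] * d[2] + (q[inb, 2] - 1L) * d[1] + q[inb, 1]
        exposed <- exposed + sum(!mask[lin])
      }
      faces <- faces + exposed * face_area[axis]
    }
  }
  sphericity <- (pi^(1 / 3) * (6 * volume)^(2 / 3)) / faces

  pts <- sweep(coords, 2, spacing, `*`)
  max_diam <- if (n > 1) max(dist(pts)) else 0

  if (n > 2) {
    ev <- sort(eigen(stats::cov(pts), symmetric = TRUE,
                     only.values = TRUE)$values, decreasing = TRUE)
    ev <- pmax(ev, 0)
    elong <- if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 1
    flat <- if (ev[1] > 0) sqrt(ev[3] / ev[1]) else 1
  } else {
    elong <- 1; flat <- 1
  }
  c(volume = volume,
    surface_area = faces,
    sphericity = sphericity,
    max_diameter_3d = max_diam,
    elongation = elong,
    flatness = flat)
}
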