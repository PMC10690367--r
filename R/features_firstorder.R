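# Intensity discretization and first-order radiomic features.

#' Gray-level discretization of a map inside an ROI
#'
#' Maps in-mask intensities to integer levels 1..L, either with a fixed
#' number of equal-width bins over the in-mask range (default, 32 bins) or
#' with a fixed bin width anchored at the in-mask minimum. Out-of-mask
#' voxels are left as NA.
#'
#' @param map numeric array.
#' @param mask logical array, same shape, nonempty.
#' @param mode "fixed-bin-count" or "fixed-bin-width".
#' @param bins number of levels for fixed-bin-count.
#' @param bin_width level width for fixed-bin-width.
#' @return integer array of levels (NA outside the mask) with attribute
#'   \code{n_levels}.
#' @export
discretize <- function(map, mask, mode = c("fixed-bin-count",
                                           "fixed-bin-width"),
                       bins = 32L, bin_width = NULL) {
  mode <- match.arg(mode)
  stopifnot(any(mask), all(dim(map) == dim(mask)))
  vals <- map[mask]
  out <- array(NA_integer_, dim = dim(map))
  rng <- range(vals)
  if (mode == "fixed-bin-count") {
    stopifnot(bins >= 2)
    if (rng[2] == rng[1]) {
      lev <- rep(1L, length(vals))
      n_levels <- 1L
    } else {
      lev <- pmin(as.integer(floor((vals - rng[1]) / (rng[2] - rng[1]) * bins)) + 1L,
                  as.integer(bins))
      n_levels <- as.integer(bins)
    }
  } else {
    stopifnot(!is.null(bin_width), bin_width > 0)
    if (rng[2] == rng[1]) {
      message("discretize: constant image under fixed-bin-width; single level")
      lev <- rep(1L, length(vals))
      n_levels <- 1L
    } else {
      lev <- as.integer(floor((vals - rng[1]) / bin_width)) + 1L
      n_levels <- max(lev)
    }
  }
  out[mask] <- lev
  attr(out, "n_levels") <- n_levels
  out
}

#' First-order statistical features of an ROI
#'
#' Moments are population moments (divisor n). Entropy is the Shannon
#' entropy (base 2) of the discretized in-mask histogram; energy is the sum
#' of squared intensities. MAD is the mean absolute deviation from the mean.
#'
#' @param map numeric array.
#' @param mask logical array, >= 2 in-mask voxels.
#' @param bins discretization bins for the entropy histogram.
#' @return named numeric vector.
#' @export
first_order_features <- function(map, mask, bins = 32L) {
  if (!any(mask)) stop("empty mask", call. = FALSE)
  x <- map[mask]
  n <- length(x)
  if (n < 2) stop("first-order features need >= 2 in-mask voxels",
                  call. = FALSE)
  m <- mean(x)
  v <- mean((x - m)^2)
  sdev <- sqrt(v)
  skew <- if (sdev > 0) mean((x - m)^3) / sdev^3 else 0
  kurt <- if (sdev > 0) mean((x - m)^4) / sdev^4 else 0
  lev <- discretize(map, mask, bins = bins)
  p <- tabulate(lev[mask]) / n
  p <- p[p > 0]
  c(mean = m,
    variance = v,
    skewness = skew,
    kurtosis = kurt,
    energy = sum(x^2),
    entropy = -sum(p * log2(p)),
    minimum = min(x),
    maximum = max(x),
    range = diff(range(x)),
    p10 = unname(quantile(x, 0.10, type = 7)),
    p50 = unname(quantile(x, 0.50, type = 7)),
    p90 = unname(quantile(x, 0.90, type = 7)),
    mad = mean(abs(x - m)))
}
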