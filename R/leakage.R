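# Leakage-corrected blood volume estimation.
#
# With an intact blood-brain barrier, nrCBV is the integral of the voxel
# concentration curve between bolus arrival t0 and replenish t1. A leaky
# barrier lets contrast agent escape into the extravascular space, biasing
# that integral. Two exchange models express the measured voxel curve
# through the whole-brain average concentration ref(t) in non-enhancing
# voxels:
#   unidirectional:  Ct(t) = K1 ref(t) - K2 * int_0^t ref
#   bidirectional:   Ct(t) = K1 ref(t) - K2 * (ref (*) exp(-Kep t))
# K1 is a susceptibility scaling factor, K2 the intra-to-extravascular
# permeability term, Kep the return constant. Fitted K2 (and Kep) are added
# back to correct the curve before integrating. All convolutions and
# cumulative integrals here use trapezoid-consistent quadrature so the
# Kep -> 0 limit of the bidirectional model reproduces the unidirectional
# one exactly.

#' Whole-brain average reference curve over non-enhancing voxels
#'
#' Mean concentration per timepoint over brain voxels outside the tumor ROI
#' dilated by \code{dilate} voxels (Chebyshev/26-neighborhood dilation), the
#' dilation excluding the partial-volume rim around the lesion.
#'
#' @param conc_series 4D array of concentration values (x, y, z, t).
#' @param brain_mask,tumor_mask logical 3D arrays on the series grid.
#' @param dilate dilation radius in voxels for the tumor exclusion zone.
#' @return list with \code{values} (length t), \code{n_voxels_averaged}.
#' @export
compute_reference_curve <- function(conc_series, brain_mask, tumor_mask,
                                    dilate = 2L) {
  stopifnot(length(dim(conc_series)) == 4,
            all(dim(conc_series)[1:3] == dim(brain_mask)),
            all(dim(brain_mask) == dim(tumor_mask)))
  excl <- dilate_mask(tumor_mask, dilate)
  keep <- brain_mask & !excl
  if (!any(keep)) stop("empty non-enhancing reference set", call. = FALSE)
  nt <- dim(conc_series)[4]
  flat <- matrix(conc_series, ncol = nt)
  vals <- colMeans(flat[which(keep), , drop = FALSE])
  list(values = vals, n_voxels_averaged = sum(keep))
}

# Chebyshev dilation of a logical 3D mask by r voxels (26-neighborhood,
# applied r times as a box max filter).
dilate_mask <- function(mask, r) {
  if (r <= 0) return(mask)
  d <- dim(mask)
  out <- mask
  for (i in seq_len(r)) {
    nb <- out
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      xs <- pmin(pmax(seq_len(d[1]) + dx, 1L), d[1])
      ys <- pmin(pmax(seq_len(d[2]) + dy, 1L), d[2])
      zs <- pmin(pmax(seq_len(d[3]) + dz, 1L), d[3])
      nb <- nb | out[xs, ys, zs]
    }
    out <- nb
  }
  out
}

#' Blood volume by direct integration of the concentration curve
#'
#' Trapezoidal integral of C between the arrival index and the replenish
#' index (inclusive endpoints of the window).
#'
#' @param conc concentration samples.
#' @param t0_index,t1_index integration window (1-based, t0 < t1).
#' @param dt temporal resolution, seconds.
#' @return scalar nrCBV (s^-1 * s, i.e. dimensionless relative volume).
#' @export
integrate_nrcbv <- function(conc, t0_index, t1_index, dt) {
  if (t0_index < 1 || t1_index > length(conc) || t0_index >= t1_index) {
    stop("invalid integration window", call. = FALSE)
  }
  trapz_dt(conc[t0_index:t1_index], dt)
}

#' Replenish index: first local minimum of the reference curve after its peak
#'
#' The integration window end for nrCBV is not uniquely defined by the
#' model; the package takes the first local minimum of the whole-brain
#' reference curve after its global maximum (the end of the first passage),
#' falling back to the last frame when the curve never turns back up.
#'
#' @param ref_values reference concentration curve.
#' @return 1-based index.
#' @export
find_replenish_index <- function(ref_values) {
  peak <- which.max(ref_values)
  n <- length(ref_values)
  if (peak >= n - 1L) return(n)
  for (i in (peak + 1L):(n - 1L)) {
    if (ref_values[i] <= ref_values[i - 1L] && ref_values[i] <= ref_values[i + 1L] &&
        ref_values[i + 1L] > ref_values[i]) {
      return(i)
    }
  }
  n
}

#' Fit the unidirectional exchange model (linear least squares)
#'
#' Solves \eqn{C_t(t) = K_1 ref(t) - K_2 \int_0^t ref} for (K1, K2) by
#' ordinary least squares (the model is linear in both parameters; no sign
#' constraints, matching an unconstrained fit over the reals).
#'
#' @param conc measured voxel concentration curve.
#' @param ref reference curve values (same grid).
#' @param dt temporal resolution, seconds.
#' @return list with \code{K1}, \code{K2}, \code{residual_norm},
#'   \code{fitted}.
#' @export
fit_unidirectional <- function(conc, ref, dt) {
  stopifnot(length(conc) == length(ref))
  cum_ref <- cumtrapz_dt(ref, dt)
  X <- cbind(ref, -cum_ref)
  qrX <- qr(X)
  if (qrX$rank < 2) stop("rank-deficient design in unidirectional fit",
                         call. = FALSE)
  beta <- qr.coef(qrX, conc)
  fitted <- drop(X %*% beta)
  list(K1 = unname(beta[1]), K2 = unname(beta[2]),
       residual_norm = sqrt(sum((conc - fitted)^2)), fitted = fitted)
}

#' Unidirectional leakage correction of a voxel curve
#'
#' Adds the fitted leakage term back:
#' \eqn{C_{t,unidir}(t) = C_t(t) + K_2 \int_0^t ref}.
#'
#' @inheritParams fit_unidirectional
#' @param K2 fitted permeability term.
#' @return corrected concentration curve.
#' @export
correct_unidirectional <- function(conc, ref, K2, dt) {
  conc + K2 * cumtrapz_dt(ref, dt)
}

# Bidirectional leakage regressor: (ref (*) exp(-Kep t)) with trapezoid
# quadrature.
bidir_leak_term <- function(ref, Kep, time_grid) {
  dt <- time_grid[2] - time_grid[1]
  conv_trapz(ref, exp(-Kep * (time_grid - time_grid[1])), dt)
}

#' Fit the bidirectional exchange model
#'
#' Estimates (K1, K2, Kep) in \eqn{C_t(t) = K_1 ref - K_2 (ref \ast
#' e^{-K_{ep} t})}. For fixed Kep the problem is linear in (K1, K2), so the
#' fit profiles: an inner exact linear solve nested in a 1-D golden-section
#' search over Kep, which is deterministic and needs no starting point
#' beyond the search bracket. Kep is reported but flagged unidentifiable
#' when the fitted K2 is (numerically) zero, since the Kep term then drops
#' out of the model.
#'
#' @param conc measured voxel concentration curve.
#' @param ref reference curve values.
#' @param time_grid uniform sample times, seconds.
#' @param kep_bracket search interval for Kep (s^-1).
#' @return list with \code{K1}, \code{K2}, \code{Kep}, \code{residual_norm},
#'   \code{converged}, \code{kep_identifiable}.
#' @export
fit_bidirectional <- function(conc, ref, time_grid, kep_bracket = c(0, 2)) {
  stopifnot(length(conc) == length(ref), length(conc) == length(time_grid))
  sse_at <- function(kep) {
    lt <- bidir_leak_term(ref, kep, time_grid)
    X <- cbind(ref, -lt)
    qrX <- qr(X)
    if (qrX$rank < 2) return(list(sse = sum(conc^2) + 1, beta = c(NA, NA)))
    beta <- qr.coef(qrX, conc)
    r <- conc - drop(X %*% beta)
    list(sse = sum(r^2), beta = beta)
  }
  opt <- optimize(function(k) sse_at(k)$sse,
                  interval = kep_bracket, tol = 1e-10)
  # optimize() never evaluates the bracket endpoints; check Kep = 0 (the
  # unidirectional limit) explicitly so nesting is exact.
  cand <- list(opt$minimum, kep_bracket[1])
  sses <- vapply(cand, function(k) sse_at(k)$sse, numeric(1))
  kep <- cand[[which.min(sses)]]
  sol <- sse_at(kep)
  if (any(!is.finite(sol$beta))) {
    return(list(K1 = NaN, K2 = NaN, Kep = NaN, residual_norm = NaN,
                converged = FALSE, kep_identifiable = FALSE))
  }
  list(K1 = unname(sol$beta[1]), K2 = unname(sol$beta[2]), Kep = kep,
       residual_norm = sqrt(sol$sse), converged = TRUE,
       kep_identifiable = abs(sol$beta[2]) > 1e-8)
}

#' Bidirectional leakage correction of a voxel curve
#'
#' Mirrors the unidirectional add-back with the exchange kernel:
#' \eqn{C_{t,bidir}(t) = C_t(t) + K_2 (ref \ast e^{-K_{ep} t})}. At
#' \eqn{K_{ep}=0} this reduces exactly to [correct_unidirectional()].
#'
#' @inheritParams fit_bidirectional
#' @param K2,Kep fitted exchange parameters.
#' @return corrected concentration curve.
#' @export
correct_bidirectional <- function(conc, ref, K2, Kep, time_grid) {
  conc + K2 * bidir_leak_term(ref, Kep, time_grid)
}

#' Leakage parameter and nrCBV maps over an ROI
#'
#' Runs the unidirectional and bidirectional fits voxelwise inside
#' \code{mask}, corrects each curve, and integrates uncorrected and
#' corrected nrCBV over [arrival, replenish].
#'
#' @param conc_series 4D concentration array.
#' @param mask logical 3D ROI (typically the tumor).
#' @param ref reference curve list from [compute_reference_curve()].
#' @param time_grid sample times, seconds.
#' @param t0_index arrival index (last baseline frame).
#' @param t1_index replenish index; default from [find_replenish_index()].
#' @param models character subset of c("unidir", "bidir").
#' @return object of class \code{nrcbv_maps}: 3D arrays \code{nrCBV} and,
#'   per model, \code{K1_*, K2_*, (Kep_bidir), nrCBV_*}, plus \code{valid}.
#' @export
compute_leakage_maps <- function(conc_series, mask, ref, time_grid, t0_index,
                                 t1_index = NULL,
                                 models = c("unidir", "bidir")) {
  shape <- dim(conc_series)[1:3]
  nt <- dim(conc_series)[4]
  stopifnot(all(dim(mask) == shape), length(ref$values) == nt)
  if (is.null(t1_index)) t1_index <- find_replenish_index(ref$values)
  dt <- time_grid[2] - time_grid[1]
  idx <- which(mask)
  flat <- matrix(conc_series, ncol = nt)
  blank <- array(NA_real_, dim = shape)
  out <- list(nrCBV = blank)
  if ("unidir" %in% models) {
    out$K1_unidir <- blank; out$K2_unidir <- blank; out$nrCBV_unidir <- blank
  }
  if ("bidir" %in% models) {
    out$K1_bidir <- blank; out$K2_bidir <- blank; out$Kep_bidir <- blank
    out$nrCBV_bidir <- blank
  }
  valid <- array(FALSE, dim = shape)
  for (v in idx) {
    conc <- flat[v, ]
    out$nrCBV[v] <- integrate_nrcbv(conc, t0_index, t1_index, dt)
    ok <- TRUE
    if ("unidir" %in% models) {
      fu <- fit_unidirectional(conc, ref$values, dt)
      cu <- correct_unidirectional(conc, ref$values, fu$K2, dt)
      out$K1_unidir[v] <- fu$K1
      out$K2_unidir[v] <- fu$K2
      out$nrCBV_unidir[v] <- integrate_nrcbv(cu, t0_index, t1_index, dt)
    }
    if ("bidir" %in% models) {
      fb <- fit_bidirectional(conc, ref$values, time_grid)
      ok <- ok && fb$converged
      out$K1_bidir[v] <- fb$K1
      out$K2_bidir[v] <- fb$K2
      out$Kep_bidir[v] <- fb$Kep
      if (fb$converged) {
        cb <- correct_bidirectional(conc, ref$values, fb$K2, fb$Kep, time_grid)
        out$nrCBV_bidir[v] <- integrate_nrcbv(cb, t0_index, t1_index, dt)
      }
    }
    valid[v] <- ok
  }
  out$valid <- valid
  class(out) <- "nrcbv_maps"
  out
}
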