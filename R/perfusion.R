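# Gamma-variate tracer-kinetic quantification of DSC concentration curves.
#
# The tissue model is C_t(t) = Ft * (AIF (*) R)(t) with R(t) = 1 - int_0^t h,
# h a gamma-variate transit-time density. Fitting the four parameters
# [Ft, t1, sigma1, a1] voxelwise yields rCBF = Ft, rMTT = t1 + sigma1(1+a1)
# and, by the central volume principle, rCBV = rCBF * rMTT. TMAX and the mean
# slope of increase (MSI) are computed on the measured concentration curve.

#' Gamma-variate transport function (transit-time density)
#'
#' \deqn{h(t) = \frac{1}{A_1}(t-t_1)^{a_1} e^{-(t-t_1)/\sigma_1}, \quad t \ge t_1}
#' and 0 before arrival, with \eqn{A_1 = \sigma_1^{1+a_1}\Gamma(1+a_1)} so
#' that h integrates to 1. Its mean transit time is
#' \eqn{t_1 + \sigma_1 (1 + a_1)}.
#'
#' @param t sample times, seconds.
#' @param t1 arrival delay, seconds.
#' @param sigma1 dispersion scale, seconds, > 0.
#' @param a1 shape exponent, > -1.
#' @return density values at \code{t}.
#' @export
transport_function <- function(t, t1, sigma1, a1) {
  if (!is.finite(sigma1) || sigma1 <= 0 || !is.finite(a1) || a1 <= -1) {
    stop("transport_function requires sigma1 > 0 and a1 > -1", call. = FALSE)
  }
  s <- t - t1
  out <- numeric(length(t))
  pos <- s > 0
  # (1/A1) s^a1 e^(-s/sigma1) is the Gamma(shape = 1 + a1, scale = sigma1)
  # density; evaluate via dgamma for numerical stability at large a1.
  out[pos] <- stats::dgamma(s[pos], shape = 1 + a1, scale = sigma1)
  out
}

#' Residue function of the gamma-variate transport model
#'
#' \eqn{R(t) = 1 - \int_0^t h(\tau) d\tau}: the fraction of contrast agent
#' still inside the voxel at time t after an impulse input. Evaluated in
#' closed form through the regularized incomplete gamma function; monotone
#' nonincreasing from 1 (at or before arrival) toward 0.
#'
#' @inheritParams transport_function
#' @return values in [0, 1].
#' @export
residue_function <- function(t, t1, sigma1, a1) {
  s <- pmax(t - t1, 0)
  1 - stats::pgamma(s, shape = 1 + a1, scale = sigma1)
}

#' Convert a DSC signal curve to contrast-agent concentration
#'
#' Single-echo relaxivity relation \eqn{C(t) = -\frac{1}{TE}
#' \ln(S(t)/S(0))}, with \eqn{S(0)} the mean over the pre-bolus baseline
#' frames. Nonpositive samples are clamped to \code{clamp_frac * S(0)} (the
#' voxel is kept, the count of clamped samples is reported) rather than
#' producing non-finite concentrations; a nonpositive baseline invalidates
#' the voxel.
#'
#' @param values signal samples.
#' @param te echo time, seconds, > 0.
#' @param n_baseline number of leading frames averaged into S(0).
#' @param clamp_frac clamping floor as a fraction of S(0).
#' @return list with \code{values} (concentration, s^-1), \code{s0},
#'   \code{n_clamped}, and \code{valid}.
#' @export
signal_to_concentration <- function(values, te, n_baseline,
                                    clamp_frac = 1e-3) {
  stopifnot(te > 0, n_baseline >= 1, n_baseline <= length(values))
  s0 <- mean(values[seq_len(n_baseline)])
  if (!is.finite(s0) || s0 <= 0) {
    return(list(values = rep(NA_real_, length(values)), s0 = s0,
                n_clamped = 0L, valid = FALSE))
  }
  floor_val <- clamp_frac * s0
  n_clamped <- sum(values <= 0)
  v <- pmax(values, floor_val)
  list(values = -log(v / s0) / te, s0 = s0,
       n_clamped = as.integer(n_clamped), valid = TRUE)
}

#' Per-voxel gamma-model kinetic parameters
#' @param Ft,t1,sigma1,a1 fitted parameters.
#' @param converged logical solver flag.
#' @param residual_norm L2 norm of the fit residual.
#' @return object of class \code{gamma_kinetic_params}.
#' @export
gamma_kinetic_params <- function(Ft, t1, sigma1, a1, converged = TRUE,
                                 residual_norm = NA_real_) {
  structure(list(Ft = Ft, t1 = t1, sigma1 = sigma1, a1 = a1,
                 converged = converged, residual_norm = residual_norm),
            class = "gamma_kinetic_params")
}

# Model curve for a parameter vector theta = (Ft, t1, sigma1, a1).
gamma_model_curve <- function(theta, aif, time_grid) {
  dt <- time_grid[2] - time_grid[1]
  R <- residue_function(time_grid, theta[2], theta[3], theta[4])
  theta[1] * conv_rect(aif, R, dt)
}

#' Fit the gamma transport-function model to one concentration curve
#'
#' Levenberg-Marquardt least squares (via \pkg{minpack.lm}) for
#' \eqn{[F_t, t_1, \sigma_1, a_1]} minimizing the residual between the
#' measured curve and \eqn{F_t (AIF \ast R)}. Initial values follow a
#' data-driven heuristic: \code{t1} one frame past the AIF arrival,
#' \code{a1 = 3}, \code{sigma1 = 1.5} s, and \code{Ft} from the ratio of the
#' measured peak to the unit-flow model peak. All parameters are bounded
#' below by 0; \code{a1 <= 20} and \code{sigma1 <= 20} s.
#'
#' @param conc measured concentration curve (s^-1).
#' @param aif arterial input concentration curve on the same grid.
#' @param time_grid uniform sample times, seconds.
#' @param init optional named numeric (Ft, t1, sigma1, a1) overriding the
#'   heuristic start.
#' @param lower,upper parameter bounds in the order (Ft, t1, sigma1, a1).
#' @return a [gamma_kinetic_params()]; on solver failure \code{converged}
#'   is FALSE and the parameters are NaN.
#' @export
fit_gamma_model <- function(conc, aif, time_grid, init = NULL,
                            lower = c(0, 0, 1e-3, 0),
                            upper = c(Inf, Inf, 20, 20)) {
  stopifnot(length(conc) == length(time_grid), length(aif) == length(conc))
  if (max(abs(conc), na.rm = TRUE) < 1e-12) {
    return(gamma_kinetic_params(0, 0, 1, 1, converged = TRUE,
                                residual_norm = 0))
  }
  if (is.null(init)) {
    # t1 is the tissue delay relative to the AIF (the convolution already
    # carries the bolus timing): start one frame past the lag between the
    # concentration arrival and the AIF arrival.
    aif_arr <- which(aif > 0.05 * max(aif))[1]
    conc_arr <- which(conc > 0.05 * max(conc))[1]
    dt <- time_grid[2] - time_grid[1]
    t1_0 <- max((conc_arr - aif_arr) * dt + dt, dt)
    theta0 <- c(1, t1_0, 1.5, 3)
    unit_peak <- max(gamma_model_curve(theta0, aif, time_grid))
    theta0[1] <- if (unit_peak > 0) max(conc) / unit_peak else 1
  } else {
    theta0 <- as.numeric(init[c("Ft", "t1", "sigma1", "a1")])
  }
  theta0 <- pmin(pmax(theta0, lower + 1e-8), ifelse(is.finite(upper), upper - 1e-8, theta0))

  run_lm <- function(start) {
    tryCatch(
      minpack.lm::nls.lm(
        par = start,
        fn = function(th) gamma_model_curve(th, aif, time_grid) - conc,
        lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                             ptol = 1e-14, gtol = 0)
      ),
      error = function(e) NULL
    )
  }
  # the (t1, sigma1, a1) directions are strongly correlated; a fixed ladder
  # of shape restarts escapes the a1 = 0 boundary basin on dispersed curves
  restarts <- list(theta0,
                   replace(theta0, 3:4, c(3, 1)),
                   replace(theta0, 3:4, c(1.5, 8)),
                   replace(theta0, 2:4, c(max(theta0[2] - 3, 0.1), 3, 5)))
  scale_sse <- sum(conc^2)
  best <- NULL
  for (st in restarts) {
    fit <- run_lm(pmin(pmax(st, lower + 1e-8),
                       ifelse(is.finite(upper), upper - 1e-8, st)))
    # info 1-4: converged; 5: iteration cap with a usable iterate (kept --
    # the tight ftol means the fit is practically at its optimum)
    if (is.null(fit) || !(fit$info %in% 1:5) || any(!is.finite(fit$par))) next
    if (is.null(best) || sum(fit$fvec^2) < sum(best$fvec^2)) best <- fit
    if (sum(best$fvec^2) < 1e-16 * max(scale_sse, 1)) break
  }
  if (is.null(best)) {
    return(gamma_kinetic_params(NaN, NaN, NaN, NaN, converged = FALSE))
  }
  th <- best$par
  gamma_kinetic_params(th[1], th[2], th[3], th[4], converged = TRUE,
                       residual_norm = sqrt(sum(best$fvec^2)))
}

#' Time-to-maximum of a concentration curve
#' @param conc concentration samples.
#' @param time_grid sample times, seconds (relative to acquisition start).
#' @return list with \code{tmax} (seconds) and \code{index}.
#' @export
curve_tmax <- function(conc, time_grid) {
  i <- which.max(conc)
  list(tmax = time_grid[i], index = i)
}

#' Mean slope of increase of a concentration curve
#'
#' Average of the successive concentration differences between the end of
#' the baseline \code{t0} and the curve maximum TMAX; the sum telescopes to
#' \eqn{(C(TMAX) - C(t_0)) / N} with N the number of increments. Undefined
#' (NA, invalid) when the maximum does not lie after the baseline.
#'
#' @param conc concentration samples.
#' @param t0_index index of the last baseline frame (1-based).
#' @param tmax_index index of the curve maximum; computed if missing.
#' @return list with \code{msi}, \code{n_increments}, \code{valid}.
#' @export
mean_slope_increase <- function(conc, t0_index, tmax_index = NULL) {
  if (is.null(tmax_index)) tmax_index <- which.max(conc)
  if (tmax_index <= t0_index) {
    return(list(msi = NA_real_, n_increments = 0L, valid = FALSE))
  }
  n <- tmax_index - t0_index
  diffs <- diff(conc[t0_index:tmax_index])
  list(msi = sum(diffs) / n, n_increments = as.integer(n), valid = TRUE)
}

#' Derived perfusion maps from voxelwise gamma fits
#'
#' Assembles rCBF (= Ft), rMTT (= t1 + sigma1 (1 + a1)), rCBV (= rCBF *
#' rMTT, the central volume principle), TMAX and MSI into one map set. TMAX
#' and MSI are computed on the measured concentration curves; the kinetic
#' maps come from the fits. Non-converged or MSI-undefined voxels are marked
#' invalid.
#'
#' @param fits list of [gamma_kinetic_params()] per in-mask voxel.
#' @param conc_matrix numeric matrix, voxels x timepoints, measured
#'   concentration curves for the same voxels.
#' @param time_grid sample times, seconds.
#' @param t0_index last baseline frame index.
#' @param mask logical 3D array selecting the voxels (in array order).
#' @return object of class \code{perfusion_maps}: list of 3D arrays
#'   \code{rCBF, rMTT, rCBV, TMAX, MSI} and logical \code{valid}.
#' @export
compute_derived_maps <- function(fits, conc_matrix, time_grid, t0_index, mask) {
  idx <- which(mask)
  stopifnot(length(fits) == length(idx), nrow(conc_matrix) == length(idx))
  shape <- dim(mask)
  blank <- array(NA_real_, dim = shape)
  maps <- list(rCBF = blank, rMTT = blank, rCBV = blank,
               TMAX = blank, MSI = blank)
  valid <- array(FALSE, dim = shape)
  for (j in seq_along(idx)) {
    f <- fits[[j]]
    v <- idx[j]
    conc <- conc_matrix[j, ]
    tm <- curve_tmax(conc, time_grid)
    ms <- mean_slope_increase(conc, t0_index, tm$index)
    ok <- isTRUE(f$converged) && ms$valid
    valid[v] <- ok
    maps$rCBF[v] <- f$Ft
    maps$rMTT[v] <- f$t1 + f$sigma1 * (1 + f$a1)
    maps$rCBV[v] <- maps$rCBF[v] * maps$rMTT[v]
    maps$TMAX[v] <- tm$tmax
    maps$MSI[v] <- ms$msi
  }
  structure(c(maps, list(valid = valid)), class = "perfusion_maps")
}
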