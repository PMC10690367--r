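# Synthetic DSC phantom generator with known kinetic ground truth.
#
# Every downstream stage (perfusion fitting, leakage correction, radiomics,
# classification) is exercised against phantoms built here, because the
# clinical cohort the method targets is not publicly deposited. The generator
# emulates a single-echo gradient-echo DSC acquisition: a baseline signal
# plateau, a gamma-shaped bolus passage per tissue class, optional
# blood-brain-barrier leakage, and additive Gaussian scanner noise on the
# signal.

#' Gamma-variate bolus parameters
#'
#' The gamma-variate is used both as the arterial bolus shape and (normalized)
#' as the capillary transport function. \code{amplitude} scales the curve;
#' \code{t1} is the arrival delay in seconds; \code{sigma1} (s) and \code{a1}
#' (dimensionless) control dispersion.
#'
#' @param amplitude peak-scale factor, concentration units (s^-1).
#' @param t1 bolus arrival time, seconds (curve is 0 before it).
#' @param sigma1 dispersion scale, seconds, > 0.
#' @param a1 shape exponent, > 0.
#' @return an object of class \code{gamma_bolus_params}.
#' @export
gamma_bolus_params <- function(amplitude = 1, t1 = 0, sigma1 = 1.5, a1 = 3) {
  stopifnot(is.finite(amplitude), is.finite(t1), sigma1 > 0, a1 > 0)
  structure(list(amplitude = amplitude, t1 = t1, sigma1 = sigma1, a1 = a1),
            class = "gamma_bolus_params")
}

#' Arterial input function from a gamma-variate bolus
#'
#' Evaluates \eqn{A (t-t_1)^{a_1} e^{-(t-t_1)/\sigma_1}} for \eqn{t \ge t_1}
#' and 0 before arrival, normalized so that the amplitude parameter is the
#' curve's time integral (the density form of the gamma-variate times
#' \code{amplitude}).
#'
#' @param params a [gamma_bolus_params()] object.
#' @param time_grid strictly increasing vector of sample times, seconds.
#' @return concentration curve (s^-1) on \code{time_grid}.
#' @export
make_aif <- function(params, time_grid) {
  stopifnot(inherits(params, "gamma_bolus_params"))
  if (any(diff(time_grid) <= 0)) {
    stop("time_grid must be strictly increasing", call. = FALSE)
  }
  params$amplitude *
    transport_function(time_grid, params$t1, params$sigma1, params$a1)
}

#' Forward-simulate a tissue concentration curve
#'
#' Implements the indicator-dilution model \eqn{C_t(t) = F_t \,
#' (AIF \ast R)(t)} with the residue function \eqn{R} of a gamma-variate
#' transport function, discretized as a rectangle-rule convolution scaled by
#' \code{dt} (see [conv_rect()]).
#'
#' @param truth list or [gamma_kinetic_params()]-like with fields
#'   \code{Ft, t1, sigma1, a1}.
#' @param aif arterial input concentration curve on \code{time_grid}.
#' @param time_grid uniform sample times, seconds.
#' @param allow_negative_flow permit \code{Ft < 0} (default errors).
#' @return tissue concentration curve (s^-1).
#' @export
simulate_tissue_curve <- function(truth, aif, time_grid,
                                  allow_negative_flow = FALSE) {
  stopifnot(length(aif) == length(time_grid))
  if (truth$Ft < 0 && !allow_negative_flow) {
    stop("negative flow Ft requires allow_negative_flow = TRUE", call. = FALSE)
  }
  dt <- time_grid[2] - time_grid[1]
  R <- residue_function(time_grid, truth$t1, truth$sigma1, truth$a1)
  truth$Ft * conv_rect(aif, R, dt)
}

#' Contaminate a curve with bidirectional contrast-agent leakage
#'
#' Forward model used to create leaky phantoms: adds the exchange terms of
#' the bidirectional model to a leak-free curve,
#' \eqn{K_1 \cdot ref - K_2 (ref \ast e^{-K_{ep} t})}, with the
#' trapezoid-consistent convolution so the fitting routines can recover the
#' parameters exactly. \code{Kep = 0} degenerates to the unidirectional
#' forward form \eqn{K_1 ref - K_2 \int ref}.
#'
#' @param curve leak-free voxel concentration curve (used only via
#'   \code{reference_curve} scaling; pass the voxel curve as
#'   \code{reference_curve} for the pure forward model).
#' @param reference_curve whole-brain average concentration curve.
#' @param K1 susceptibility scaling factor.
#' @param K2 permeability-related intra-to-extravascular term (s^-1).
#' @param Kep extra-to-intravascular return constant (s^-1).
#' @param time_grid uniform sample times, seconds.
#' @return contaminated concentration curve.
#' @export
apply_leakage <- function(curve, reference_curve, K1, K2, Kep, time_grid) {
  stopifnot(length(curve) == length(time_grid),
            length(reference_curve) == length(time_grid))
  dt <- time_grid[2] - time_grid[1]
  K1 * reference_curve - K2 * conv_trapz(reference_curve,
                                         exp(-Kep * (time_grid - time_grid[1])),
                                         dt)
}

#' Convert a concentration curve to a DSC signal curve
#'
#' Inverse of the single-echo relaxivity relation: \eqn{S(t) = S_0
#' e^{-TE \cdot C(t)}}. Strictly positive for finite input.
#'
#' @param C concentration curve, s^-1.
#' @param s0 baseline signal, > 0.
#' @param te echo time, seconds, > 0.
#' @return signal curve, same length as \code{C}.
#' @export
concentration_to_signal <- function(C, s0, te) {
  stopifnot(s0 > 0, te > 0)
  s0 * exp(-te * C)
}

#' Phantom acquisition and tissue specification
#'
#' Bundles the grid geometry, acquisition metadata (matching a 60-frame,
#' dt = 1.87 s, TE = 40 ms protocol by default), the arterial bolus, the
#' per-tissue kinetic truths and the noise level.
#'
#' Tissue classes are laid out as concentric blocks: the first class fills
#' the brain block, later classes occupy nested central sub-blocks; the union
#' of all non-background classes beyond the first forms the tumor mask
#' (mirroring an enhancement/oedema/necrosis composite ROI).
#'
#' @param grid_shape integer vector of 3 positive extents (x, y, z).
#' @param n_timepoints number of frames.
#' @param dt temporal resolution, seconds.
#' @param te echo time, seconds.
#' @param n_baseline number of pre-bolus frames (>= 2).
#' @param aif_params [gamma_bolus_params()] for the arterial bolus.
#' @param tissue_classes list of tissue specs, each a list with \code{label},
#'   \code{kinetics} (list Ft, t1, sigma1, a1) and optional \code{leakage}
#'   (list K1, K2, Kep). First class = normal brain, later classes = tumor.
#' @param noise_sd additive Gaussian signal noise SD (signal units, >= 0).
#' @param s0 baseline signal level, > 0.
#' @param seed integer RNG seed for the noise.
#' @return an object of class \code{phantom_spec}.
#' @export
phantom_spec <- function(grid_shape = c(16L, 16L, 6L),
                         n_timepoints = 60L,
                         dt = 1.87,
                         te = 0.040,
                         n_baseline = 8L,
                         aif_params = gamma_bolus_params(amplitude = 12,
                                                         t1 = 8 * 1.87,
                                                         sigma1 = 2, a1 = 3),
                         tissue_classes = default_tissue_classes(),
                         noise_sd = 1,
                         s0 = 100,
                         seed = 1L) {
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 1),
            n_timepoints > 0, dt > 0, te > 0,
            n_baseline >= 2, n_baseline < n_timepoints,
            noise_sd >= 0, s0 > 0)
  for (tc in tissue_classes) {
    stopifnot(all(vapply(tc$kinetics, is.finite, logical(1))))
  }
  structure(list(grid_shape = as.integer(grid_shape),
                 n_timepoints = as.integer(n_timepoints),
                 dt = dt, te = te, n_baseline = as.integer(n_baseline),
                 aif_params = aif_params, tissue_classes = tissue_classes,
                 noise_sd = noise_sd, s0 = s0, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Default two-tissue phantom composition (normal brain + leaky tumor)
#' @param tumor_kinetics,tumor_leakage override the tumor truth.
#' @return list of tissue class specs for [phantom_spec()].
#' @export
default_tissue_classes <- function(tumor_kinetics = list(Ft = 0.8, t1 = 4,
                                                         sigma1 = 1.5, a1 = 3),
                                   tumor_leakage = list(K1 = 1, K2 = 0.02,
                                                        Kep = 0.05)) {
  list(
    list(label = "brain",
         kinetics = list(Ft = 0.4, t1 = 3, sigma1 = 1.2, a1 = 2.5),
         leakage = NULL),
    list(label = "tumor",
         kinetics = tumor_kinetics,
         leakage = tumor_leakage)
  )
}

# Concentric block layout: class 1 fills the brain block (80% of the grid,
# centred); class k >= 2 occupies a centred sub-block shrinking with k.
phantom_layout <- function(grid_shape, n_classes) {
  class_map <- array(0L, dim = grid_shape)
  centred_block <- function(frac) {
    ext <- pmax(1L, as.integer(round(grid_shape * frac)))
    lo <- pmax(1L, as.integer(floor((grid_shape - ext) / 2)) + 1L)
    hi <- pmin(grid_shape, lo + ext - 1L)
    list(lo = lo, hi = hi)
  }
  fracs <- c(0.8, 0.3, 0.2, 0.12)
  if (n_classes > length(fracs)) {
    fracs <- c(fracs, rev(seq(0.04, 0.1, length.out = n_classes - length(fracs))))
  }
  for (k in seq_len(n_classes)) {
    b <- centred_block(fracs[k])
    class_map[b$lo[1]:b$hi[1], b$lo[2]:b$hi[2], b$lo[3]:b$hi[3]] <- k
  }
  class_map
}

#' Build a 4D DSC phantom from a specification
#'
#' Simulates the per-class tissue concentration curves (gamma-variate
#' transport model, optional leakage contamination), converts them to signal
#' with a baseline plateau at \code{s0}, lays the classes out as concentric
#' blocks and adds Gaussian noise with the spec's seed. The time axis starts
#' at 0; frames before \code{n_baseline} are pure baseline because the bolus
#' arrival is placed after them.
#'
#' @param spec a [phantom_spec()].
#' @return list with \code{series} (a \code{dsc_series}), \code{brain_mask},
#'   \code{tumor_mask} (logical 3D arrays), and \code{ground_truth} (list of
#'   per-class truths, per-voxel class map, and the noiseless class curves).
#' @export
build_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (any(spec$grid_shape < 1) || spec$n_timepoints < spec$n_baseline + 2) {
    stop("degenerate phantom grid", call. = FALSE)
  }
  tg <- (seq_len(spec$n_timepoints) - 1) * spec$dt
  aif <- make_aif(spec$aif_params, tg)

  n_cls <- length(spec$tissue_classes)
  class_map <- phantom_layout(spec$grid_shape, n_cls)

  class_conc <- lapply(spec$tissue_classes, function(tc) {
    ct <- simulate_tissue_curve(tc$kinetics, aif, tg)
    if (!is.null(tc$leakage)) {
      lk <- tc$leakage
      ct <- apply_leakage(ct, ct, lk$K1, lk$K2, lk$Kep, tg)
    }
    ct
  })
  class_signal <- lapply(class_conc, concentration_to_signal,
                         s0 = spec$s0, te = spec$te)

  dims <- c(spec$grid_shape, spec$n_timepoints)
  series <- array(spec$s0, dim = dims)
  n_vox <- prod(spec$grid_shape)
  flat_class <- as.integer(class_map)
  for (k in seq_len(n_cls)) {
    idx <- which(flat_class == k)
    if (!length(idx)) next
    for (t in seq_len(spec$n_timepoints)) {
      plane <- series[, , , t]
      plane[idx] <- class_signal[[k]][t]
      series[, , , t] <- plane
    }
  }
  if (spec$noise_sd > 0) {
    series <- series + with_seed(spec$seed,
      array(rnorm(prod(dims), sd = spec$noise_sd), dim = dims))
  }

  brain_mask <- array(flat_class >= 1L, dim = spec$grid_shape)
  tumor_mask <- array(flat_class >= 2L, dim = spec$grid_shape)

  truth <- list(
    class_map = class_map,
    classes = spec$tissue_classes,
    class_concentration = class_conc,
    aif = aif
  )
  out <- list(
    series = dsc_series(series, dt = spec$dt, te = spec$te,
                        n_baseline = spec$n_baseline),
    brain_mask = brain_mask,
    tumor_mask = tumor_mask,
    ground_truth = truth
  )
  class(out) <- "dsc_phantom"
  out
}

#' Generate a labeled cohort of phantoms with class-dependent kinetics
#'
#' Emulates a two-class patient cohort (default 41 minority / 119 majority,
#' the IDH-mutant vs wildtype imbalance) whose tumor kinetic truths differ by
#' class: per-phantom tumor flow \code{Ft} and leakage \code{K2} are drawn
#' from class-specific normal distributions given by \code{effect_spec}.
#'
#' @param n_class0 minority-class count (label 0, e.g. IDH-mutant).
#' @param n_class1 majority-class count (label 1, e.g. IDH-wildtype).
#' @param effect_spec list with per-class means/SDs:
#'   \code{Ft_mean} (length 2, class 0 then 1), \code{Ft_sd}, \code{K2_mean},
#'   \code{K2_sd}. \code{cohort_effect_spec()} gives the defaults;
#'   \code{cohort_effect_spec(null = TRUE)} gives an effect-free cohort.
#' @param seed integer; drives phantom parameter draws and per-phantom noise.
#' @param spec_template base [phantom_spec()] whose geometry/acquisition are
#'   reused for every phantom.
#' @return list of phantoms; each element has the [build_phantom()] fields
#'   plus \code{label} (0/1) and \code{id}.
#' @export
make_cohort <- function(n_class0 = 41L, n_class1 = 119L,
                        effect_spec = cohort_effect_spec(),
                        seed = 1L,
                        spec_template = phantom_spec()) {
  stopifnot(n_class0 >= 1, n_class1 >= 1)
  if (isTRUE(all.equal(effect_spec$Ft_mean[1], effect_spec$Ft_mean[2])) &&
      isTRUE(all.equal(effect_spec$K2_mean[1], effect_spec$K2_mean[2]))) {
    message("make_cohort: effect_spec has no class difference (null cohort)")
  }
  labels <- c(rep(0L, n_class0), rep(1L, n_class1))
  n <- length(labels)
  draws <- with_seed(derive_seed(seed, "cohort"), {
    list(Ft = rnorm(n, effect_spec$Ft_mean[labels + 1L],
                    effect_spec$Ft_sd[labels + 1L]),
         K2 = rnorm(n, effect_spec$K2_mean[labels + 1L],
                    effect_spec$K2_sd[labels + 1L]))
  })
  draws$Ft <- pmax(draws$Ft, 0.05)

  lapply(seq_len(n), function(i) {
    spec_i <- spec_template
    spec_i$seed <- derive_seed(seed, "phantom") + i
    spec_i$tissue_classes <- default_tissue_classes(
      tumor_kinetics = list(Ft = draws$Ft[i], t1 = 4, sigma1 = 1.5, a1 = 3),
      tumor_leakage = list(K1 = 1, K2 = draws$K2[i], Kep = 0.05)
    )
    ph <- build_phantom(spec_i)
    ph$label <- labels[i]
    ph$id <- sprintf("phantom_%03d", i)
    ph$truth_params <- list(Ft = draws$Ft[i], K2 = draws$K2[i])
    ph
  })
}

#' Class effect sizes for the synthetic cohort
#'
#' Defaults place the majority (wildtype-like) class at higher tumor blood
#' flow and higher vascular permeability than the minority class, the
#' direction reported for aggressive gliomas; SDs give clearly separable but
#' overlapping distributions. \code{null = TRUE} collapses both classes onto
#' the minority distribution for calibration runs.
#'
#' @param null logical; no class difference if TRUE.
#' @return list understood by [make_cohort()].
#' @export
cohort_effect_spec <- function(null = FALSE) {
  if (null) {
    list(Ft_mean = c(0.55, 0.55), Ft_sd = c(0.10, 0.10),
         K2_mean = c(0.006, 0.006), K2_sd = c(0.003, 0.003))
  } else {
    list(Ft_mean = c(0.55, 0.90), Ft_sd = c(0.10, 0.12),
         K2_mean = c(0.006, 0.022), K2_sd = c(0.003, 0.006))
  }
}
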