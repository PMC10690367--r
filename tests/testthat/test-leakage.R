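make_ref <- function(tg = std_time_grid()) {
  simulate_tissue_curve(list(Ft = 0.4, t1 = 3, sigma1 = 1.2, a1 = 2.5),
                        std_aif(tg), tg)
}

test_that("reference curve averages non-enhancing voxels only", {
  # constructed 3-voxel case: two brain curves, one tumor curve
  conc <- array(0, dim = c(3, 1, 1, 2))
  conc[1, 1, 1, ] <- c(0, 2)
  conc[2, 1, 1, ] <- c(0, 4)
  conc[3, 1, 1, ] <- c(0, 100)
  brain <- array(TRUE, dim = c(3, 1, 1))
  tumor <- array(c(FALSE, FALSE, TRUE), dim = c(3, 1, 1))
  ref <- compute_reference_curve(conc, brain, tumor, dilate = 0L)
  expect_equal(ref$values, c(0, 3))
  expect_equal(ref$n_voxels_averaged, 2L)
  # uniform field: reference equals any single voxel curve
  conc[] <- rep(c(1, 5), each = 3)
  ref2 <- compute_reference_curve(conc, brain, tumor, dilate = 0L)
  expect_equal(ref2$values, c(1, 5))
  # dilation can empty the reference set
  expect_error(compute_reference_curve(conc, brain, tumor, dilate = 2L),
               "empty")
})

test_that("nrCBV integral is the trapezoid rule over the window", {
  expect_equal(integrate_nrcbv(c(0, 1, 1, 0), 1, 4, dt = 1), 2)
  expect_equal(integrate_nrcbv(rep(0, 10), 1, 10, dt = 1.87), 0)
  expect_equal(integrate_nrcbv(c(0, 1, 1, 0), 1, 4, dt = 2),
               2 * integrate_nrcbv(c(0, 1, 1, 0), 1, 4, dt = 1))
  expect_error(integrate_nrcbv(c(0, 1), 2, 1, 1), "window")
})

test_that("unidirectional fit equals the normal-equations solution", {
  tg <- std_time_grid(); dt <- tg[2] - tg[1]
  ref <- make_ref(tg)
  cum <- dscradiomics:::cumtrapz_dt(ref, dt)
  ct <- 1.5 * ref - 0.02 * cum
  f <- fit_unidirectional(ct, ref, dt)
  expect_equal(f$K1, 1.5, tolerance = 1e-10)
  expect_equal(f$K2, 0.02, tolerance = 1e-10)
  # pure scaling -> K2 = 0
  f2 <- fit_unidirectional(2 * ref, ref, dt)
  expect_equal(f2$K1, 2, tolerance = 1e-10)
  expect_equal(f2$K2, 0, tolerance = 1e-10)
  # adding a residual orthogonal to the design leaves the fit unchanged
  X <- cbind(ref, -cum)
  r <- rnorm(length(ref))
  r <- r - X %*% solve(crossprod(X), crossprod(X, r))
  f3 <- fit_unidirectional(ct + as.vector(r), ref, dt)
  expect_equal(f3$K1, f$K1, tolerance = 1e-8)
  expect_equal(f3$K2, f$K2, tolerance = 1e-8)
  expect_gt(f3$residual_norm, 0)
  expect_error(fit_unidirectional(ct, rep(0, 60), dt), "rank")
})

test_that("unidirectional correction restores the leak-free curve", {
  tg <- std_time_grid(); dt <- tg[2] - tg[1]
  ref <- make_ref(tg)
  expect_equal(correct_unidirectional(ref, ref, 0, dt), ref)
  # contaminate by the forward model, fit, correct, integrate
  cont <- apply_leakage(ref, ref, 1.2, 0.04, 0, tg)
  f <- fit_unidirectional(cont, ref, dt)
  corr <- correct_unidirectional(cont, ref, f$K2, dt)
  t1i <- find_replenish_index(ref)
  expect_equal(integrate_nrcbv(corr, 8, t1i, dt),
               integrate_nrcbv(1.2 * ref, 8, t1i, dt),
               tolerance = 0.01)
  # corrected - input = K2 * int(ref) pointwise
  expect_equal(corr - cont, f$K2 * dscradiomics:::cumtrapz_dt(ref, dt))
})

test_that("bidirectional fit recovers forward truths and nests at Kep = 0", {
  tg <- std_time_grid(); dt <- tg[2] - tg[1]
  ref <- make_ref(tg)
  cont <- apply_leakage(ref, ref, 1.2, 0.05, 0.1, tg)
  f <- fit_bidirectional(cont, ref, tg)
  expect_true(f$converged)
  expect_equal(f$K1, 1.2, tolerance = 0.05 * 1.2)
  expect_equal(f$K2, 0.05, tolerance = 0.05 * 0.05)
  expect_equal(f$Kep, 0.1, tolerance = 0.05 * 0.1)
  # K2 truth 0: fit degenerates, Kep unidentifiable
  f0 <- fit_bidirectional(1.4 * ref, ref, tg)
  expect_equal(f0$K2, 0, tolerance = 1e-8)
  expect_false(f0$kep_identifiable)
  # Kep -> 0 reproduces the unidirectional fit
  cont0 <- apply_leakage(ref, ref, 1.3, 0.03, 0, tg)
  fu <- fit_unidirectional(cont0, ref, dt)
  fb <- fit_bidirectional(cont0, ref, tg)
  expect_equal(fb$K1, fu$K1, tolerance = 0.01 * abs(fu$K1))
  expect_equal(fb$K2, fu$K2, tolerance = 0.01 * abs(fu$K2))
})

test_that("bidirectional correction round-trips and reduces at Kep = 0", {
  tg <- std_time_grid(); dt <- tg[2] - tg[1]
  ref <- make_ref(tg)
  cont <- apply_leakage(ref, ref, 1.2, 0.05, 0.1, tg)
  expect_equal(correct_bidirectional(cont, ref, 0, 0.3, tg), cont)
  f <- fit_bidirectional(cont, ref, tg)
  corr <- correct_bidirectional(cont, ref, f$K2, f$Kep, tg)
  t1i <- find_replenish_index(ref)
  expect_equal(integrate_nrcbv(corr, 8, t1i, dt),
               integrate_nrcbv(1.2 * ref, 8, t1i, dt), tolerance = 0.01)
  # Kep = 0 matches the unidirectional correction to machine precision
  expect_equal(correct_bidirectional(cont, ref, 0.04, 0, tg),
               correct_unidirectional(cont, ref, 0.04, dt),
               tolerance = 1e-10)
})

test_that("leakage map computation covers the ROI deterministically", {
  ph <- build_phantom(small_phantom_spec(noise_sd = 0.5, seed = 4))
  conc <- series_to_concentration(ph$series)
  tg <- series_time_grid(ph$series)
  ref <- compute_reference_curve(conc, ph$brain_mask, ph$tumor_mask)
  m1 <- compute_leakage_maps(conc, ph$tumor_mask, ref, tg, 8)
  m2 <- compute_leakage_maps(conc, ph$tumor_mask, ref, tg, 8)
  expect_identical(m1$K2_unidir, m2$K2_unidir)
  expect_identical(m1$Kep_bidir, m2$Kep_bidir)
  idx <- which(ph$tumor_mask)
  expect_true(all(is.finite(m1$nrCBV[idx])))
  expect_true(all(is.finite(m1$K1_bidir[idx])))
  expect_true(all(m1$valid[idx]))
})
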