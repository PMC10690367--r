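test_that("gamma bolus AIF has the analytic support, mode and linearity", {
  tg <- seq(0, 20, by = 0.001)
  p <- gamma_bolus_params(amplitude = 1, t1 = 0, sigma1 = 1, a1 = 2)
  a <- make_aif(p, tg)
  expect_true(all(a >= 0))
  # mode of t^a e^(-t/sigma) is at t = a * sigma
  expect_equal(tg[which.max(a)], 2, tolerance = 1e-2)
  # zero before arrival
  p2 <- gamma_bolus_params(amplitude = 3, t1 = 5, sigma1 = 1.5, a1 = 3)
  a2 <- make_aif(p2, tg)
  expect_true(all(a2[tg <= 5] == 0))
  # single interior maximum: one sign change of the derivative
  d <- diff(a2[a2 > 0])
  expect_equal(sum(diff(sign(d[d != 0])) != 0), 1)
  # linear in amplitude
  expect_equal(make_aif(gamma_bolus_params(2, 0, 1, 2), tg), 2 * a)
  expect_error(make_aif(p, c(1, 1, 2)), "increasing")
})

test_that("tissue forward model obeys convolution identities", {
  tg <- std_time_grid()
  dt <- tg[2] - tg[1]
  aif <- std_aif(tg)
  truth <- list(Ft = 0.8, t1 = 3, sigma1 = 1.5, a1 = 2.5)
  expect_equal(simulate_tissue_curve(list(Ft = 0, t1 = 3, sigma1 = 1, a1 = 2),
                                     aif, tg), rep(0, 60))
  # unit-impulse AIF (area 1) reproduces Ft * R shifted by the impulse time
  imp <- rep(0, 60); imp[5] <- 1 / dt
  ct <- simulate_tissue_curve(truth, imp, tg)
  R <- residue_function(tg, truth$t1, truth$sigma1, truth$a1)
  expect_equal(ct[5:60], truth$Ft * R[1:56], tolerance = 1e-12)
  expect_error(simulate_tissue_curve(list(Ft = -1, t1 = 1, sigma1 = 1, a1 = 2),
                                     aif, tg), "negative flow")
})

test_that("mass balance: area ratio recovers Ft * rMTT on a fine grid", {
  tgf <- seq(0, 400, by = 0.05)
  aif <- make_aif(gamma_bolus_params(12, 14, 2, 3), tgf)
  truth <- list(Ft = 0.8, t1 = 3, sigma1 = 1.5, a1 = 2.5)
  ct <- simulate_tissue_curve(truth, aif, tgf)
  rmtt <- truth$t1 + truth$sigma1 * (1 + truth$a1)
  ratio <- sum(ct) / (truth$Ft * rmtt * sum(aif))
  expect_equal(ratio, 1, tolerance = 0.01)
})

test_that("leakage forward model degenerates as expected", {
  tg <- std_time_grid()
  aif <- std_aif(tg)
  ref <- simulate_tissue_curve(list(Ft = 0.4, t1 = 3, sigma1 = 1.2, a1 = 2.5),
                               aif, tg)
  expect_equal(apply_leakage(ref, ref, 1.7, 0, 0.3, tg), 1.7 * ref)
  expect_equal(apply_leakage(ref, ref, 1, 0, 0, tg), ref)
  # Kep = 0 matches the unidirectional forward form K1 ref - K2 int(ref)
  dt <- tg[2] - tg[1]
  got <- apply_leakage(ref, ref, 1.2, 0.05, 0, tg)
  want <- 1.2 * ref - 0.05 * dscradiomics:::cumtrapz_dt(ref, dt)
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("signal conversion is exact and invertible", {
  expect_equal(concentration_to_signal(rep(0, 5), s0 = 73, te = 0.04),
               rep(73, 5))
  # closed form: 100 * exp(-0.04 * 5.5786) is about 80
  expect_equal(concentration_to_signal(5.5786, 100, 0.040), 80,
               tolerance = 1e-4)
  C <- c(0, 0.5, 3, 7.2)
  S <- concentration_to_signal(C, 100, 0.04)
  back <- signal_to_concentration(S, te = 0.04, n_baseline = 1)
  expect_equal(back$values, C, tolerance = 1e-10)
})

test_that("phantom construction is deterministic with calibrated noise", {
  sp <- small_phantom_spec(noise_sd = 0, seed = 5)
  ph <- build_phantom(sp)
  # noiseless: all tumor voxel curves identical
  idx <- which(ph$tumor_mask)
  flat <- matrix(ph$series, ncol = dim(ph$series)[4])
  expect_equal(max(apply(flat[idx, ], 2, function(v) diff(range(v)))), 0)
  # baseline frames sit at s0
  expect_equal(mean(flat[which(ph$brain_mask), seq_len(sp$n_baseline)]), 100)
  # determinism with noise
  spn <- small_phantom_spec(noise_sd = 1.5, seed = 9)
  expect_identical(unclass(build_phantom(spn)$series),
                   unclass(build_phantom(spn)$series))
  # noise calibration over >= 1000 voxels of baseline residuals
  spb <- phantom_spec(grid_shape = c(16L, 16L, 8L), noise_sd = 2, seed = 3)
  phb <- build_phantom(spb)
  base <- matrix(phb$series, ncol = 60)[, 1:8]
  resid <- base - rowMeans(base)
  expect_gt(length(resid), 1000)
  # df correction: subtracting the per-voxel mean shrinks the SD by
  # sqrt((nb-1)/nb)
  expect_equal(sd(resid) * sqrt(8 / 7), 2, tolerance = 0.05)
})

test_that("cohort generator honours counts, labels and the null spec", {
  coh <- make_cohort(n_class0 = 1, n_class1 = 1, seed = 2)
  expect_length(coh, 2)
  expect_setequal(vapply(coh, `[[`, integer(1), "label"), c(0L, 1L))
  expect_message(
    make_cohort(2, 2, effect_spec = cohort_effect_spec(null = TRUE), seed = 1),
    "no class difference")
  # class-dependent truth draws shift as configured
  coh2 <- make_cohort(20, 20, seed = 7)
  ft <- vapply(coh2, function(p) p$truth_params$Ft, numeric(1))
  lab <- vapply(coh2, `[[`, integer(1), "label")
  expect_gt(mean(ft[lab == 1]), mean(ft[lab == 0]))
})
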