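test_that("discretization maps ranges onto gray levels as specified", {
  img <- array(0:31, dim = c(8, 4, 1))
  mask <- array(TRUE, dim = c(8, 4, 1))
  lev <- discretize(img, mask, bins = 32)
  expect_equal(sort(unique(as.vector(lev))), 1:32)
  expect_equal(lev[1, 1, 1], 1L)
  expect_equal(lev[8, 4, 1], 32L)
  # constant image -> single level
  lev2 <- discretize(array(7, dim = c(2, 2, 1)), array(TRUE, dim = c(2, 2, 1)))
  expect_true(all(lev2 == 1L))
  # fixed-bin-count is invariant under a linear rescale
  lev3 <- discretize(img * 3 + 10, mask, bins = 32)
  expect_equal(as.vector(lev3), as.vector(lev))
})

test_that("first-order features match hand arithmetic and invariances", {
  m <- array(c(1, 2, 3, 4), dim = c(4, 1, 1))
  mask <- array(TRUE, dim = c(4, 1, 1))
  fo <- first_order_features(m, mask)
  expect_equal(fo[["mean"]], 2.5)
  expect_equal(fo[["variance"]], 1.25)  # population variance
  expect_equal(fo[["energy"]], 30)
  expect_equal(fo[["range"]], 3)
  # constant region: zero entropy and variance
  fc <- first_order_features(array(5, dim = c(2, 2, 1)),
                             array(TRUE, dim = c(2, 2, 1)))
  expect_equal(fc[["entropy"]], 0)
  expect_equal(fc[["variance"]], 0)
  # affine shift leaves central moments unchanged
  fo2 <- first_order_features(m + 17, mask)
  for (k in c("variance", "skewness", "kurtosis", "mad")) {
    expect_equal(fo2[[k]], fo[[k]])
  }
  # two-pass oracle for mean and variance on random data
  set.seed(2)
  x <- array(rnorm(60), dim = c(5, 4, 3))
  mk <- array(runif(60) < 0.7, dim = c(5, 4, 3))
  mk[1:2] <- TRUE
  fr <- first_order_features(x, mk)
  v <- x[mk]
  expect_equal(fr[["mean"]], sum(v) / length(v), tolerance = 1e-10)
  expect_equal(fr[["variance"]], sum((v - sum(v) / length(v))^2) / length(v),
               tolerance = 1e-10)
  expect_error(first_order_features(x, array(FALSE, dim = dim(x))), "mask")
})

test_that("GLCM reproduces the hand-worked fixture and its invariances", {
  img <- matrix(c(1L, 1L, 1L, 2L), nrow = 2, byrow = TRUE)  # [[1,1],[1,2]]
  mask <- matrix(TRUE, 2, 2)
  attr(img, "n_levels") <- 2L
  f <- glcm_features(img, mask, offsets = list(c(0L, 1L)))
  # P(1,1) = 2/4, P(1,2) = P(2,1) = 1/4 -> contrast = 0.5
  expect_equal(f[["contrast"]], 0.5)
  P <- dscradiomics:::glcm_matrix_single(img, mask, c(0L, 1L), 2L, TRUE)
  expect_equal(P / sum(P), matrix(c(0.5, 0.25, 0.25, 0), 2, 2))
  # constant image: contrast 0, joint energy 1
  cimg <- matrix(1L, 3, 3); attr(cimg, "n_levels") <- 1L
  fc <- glcm_features(cimg, matrix(TRUE, 3, 3), offsets = list(c(0L, 1L)))
  expect_equal(fc[["contrast"]], 0)
  expect_equal(fc[["joint_energy"]], 1)
  # distance-preserving relabeling g -> L+1-g leaves contrast unchanged
  set.seed(4)
  for (i in 1:10) {
    r <- matrix(sample(1:4, 16, replace = TRUE), 4, 4)
    attr(r, "n_levels") <- 4L
    rr <- 5L - r
    attr(rr, "n_levels") <- 4L
    f1 <- glcm_features(r, matrix(TRUE, 4, 4), offsets = list(c(0L, 1L)))
    f2 <- glcm_features(rr, matrix(TRUE, 4, 4), offsets = list(c(0L, 1L)))
    expect_equal(f2[["contrast"]], f1[["contrast"]])
  }
})

test_that("GLRLM run counts equal brute-force enumeration", {
  img <- matrix(c(1L, 1L, 2L, 2L), nrow = 1)
  attr(img, "n_levels") <- 2L
  M <- dscradiomics:::glrlm_matrix_single(img, matrix(TRUE, 1, 4), c(0L, 1L))
  expect_equal(sum(M), 2)            # two runs
  expect_equal(M[1, 2], 1)           # level 1 run of length 2
  expect_equal(M[2, 2], 1)
  f <- glrlm_features(img, matrix(TRUE, 1, 4), directions = list(c(0L, 1L)))
  expect_equal(f[["long_run_emphasis"]], 4)  # (1*4 + 1*4) / 2
  # checkerboard: all runs length 1
  cb <- outer(1:6, 1:6, function(i, j) ((i + j) %% 2L) + 1L)
  attr(cb, "n_levels") <- 2L
  Mcb <- dscradiomics:::glrlm_matrix_single(cb, matrix(TRUE, 6, 6), c(0L, 1L))
  expect_equal(unname(colSums(Mcb)[1]), 36)
  expect_equal(sum(Mcb[, -1]), 0)
  # property: random 6x6 images vs the brute-force oracle
  set.seed(9)
  for (i in 1:20) {
    r <- matrix(sample(1:3, 36, replace = TRUE), 6, 6)
    attr(r, "n_levels") <- 3L
    M <- dscradiomics:::glrlm_matrix_single(r, matrix(TRUE, 6, 6), c(0L, 1L))
    oracle <- brute_runs_horizontal(r)
    for (g in 1:3) for (l in seq_len(ncol(M))) {
      expect_equal(M[g, l],
                   sum(oracle[, "level"] == g & oracle[, "length"] == l))
    }
  }
})

test_that("GLSZM and GLDM match constructed zone/dependence fixtures", {
  cimg <- array(1L, dim = c(3, 3, 1))
  attr(cimg, "n_levels") <- 1L
  mask <- array(TRUE, dim = c(3, 3, 1))
  z <- glszm_features(cimg, mask)
  expect_equal(z[["large_area_emphasis"]], 81)  # one zone of size 9
  expect_equal(z[["zone_percentage"]], 1 / 9)
  # two separate zones of level 1 split by level 2
  img <- array(c(1L, 2L, 1L), dim = c(3, 1, 1))
  attr(img, "n_levels") <- 2L
  sz <- dscradiomics:::connected_zones(img, array(TRUE, dim = c(3, 1, 1)), 1L)
  expect_equal(sort(sz), c(1L, 1L))
  # GLDM on a constant 3x3: every voxel has all neighbors equal
  g <- gldm_features(cimg, mask)
  # corner voxels: 3 neighbors -> dep 4; edge: 5 -> 6; center: 8 -> 9
  expect_equal(g[["large_dependence_emphasis"]],
               (4 * 16 + 4 * 36 + 1 * 81) / 9)
  expect_true(all(is.finite(g)))
})

test_that("texture matrices are nonnegative and probability-normalized", {
  set.seed(5)
  img <- array(sample(1:4, 5 * 5 * 3, replace = TRUE), dim = c(5, 5, 3))
  attr(img, "n_levels") <- 4L
  mask <- array(TRUE, dim = c(5, 5, 3))
  for (off in dscradiomics:::offsets_3d()) {
    P <- dscradiomics:::glcm_matrix_single(img, mask, off, 4L, TRUE)
    expect_true(all(P >= 0))
    expect_equal(sum(P / sum(P)), 1, tolerance = 1e-12)
  }
})

test_that("shape features match the cube fixture and scale with spacing", {
  mask1 <- array(TRUE, dim = c(1, 1, 1))
  expect_equal(shape_features(mask1)[["volume"]], 1)
  cube <- array(FALSE, dim = c(4, 4, 4))
  cube[2:3, 2:3, 2:3] <- TRUE
  sh <- shape_features(cube)
  expect_equal(sh[["volume"]], 8)
  expect_equal(sh[["surface_area"]], 24)
  expect_equal(sh[["max_diameter_3d"]], sqrt(3))
  sh2 <- shape_features(cube, spacing = c(2, 2, 2))
  expect_equal(sh2[["volume"]], 64)  # spacing doubled -> volume x 8
  # elongation/flatness of an elongated bar are below 1
  bar <- array(FALSE, dim = c(8, 3, 3)); bar[1:8, 2, 2] <- TRUE
  shb <- shape_features(bar)
  expect_lt(shb[["elongation"]], 0.5)
})

test_that("filters behave on constants, inverses and unknown names", {
  const <- array(3, dim = c(6, 6, 4))
  wb <- wavelet_bands(const)
  expect_equal(wb$LLL, const)
  for (b in setdiff(names(wb), "LLL")) expect_equal(max(abs(wb[[b]])), 0)
  expect_equal(max(abs(apply_filter(const, "log-sigma-1")[3:4, 3:4, 2:3])), 0)
  expect_equal(max(abs(apply_filter(const, "gradient"))), 0)
  set.seed(6)
  x <- array(rnorm(60), dim = c(5, 4, 3))
  expect_equal(apply_filter(apply_filter(x, "exponential"), "logarithm-raw"),
               x, tolerance = 1e-6)
  expect_error(apply_filter(x, "swirl"), "unknown filter")
  lbp <- apply_filter(x, "lbp-2d")
  expect_true(all(lbp >= 0 & lbp <= 255))
})

test_that("extraction rows are deterministic with stable provenance names", {
  ph <- build_phantom(small_phantom_spec(noise_sd = 0.5, seed = 21))
  maps <- phantom_parametric_maps(ph, maps = c("MSI", "nrCBV"))
  cfg <- feature_config(filters = c("original", "wavelet-LLL"),
                        classes = c("firstorder", "glcm", "shape"))
  r1 <- extract_all(maps, ph$tumor_mask, cfg)
  r2 <- extract_all(maps, ph$tumor_mask, cfg)
  expect_identical(r1, r2)
  # combinatorial width: 2 maps x 2 filters x (13 fo + 5 glcm) + 6 shape
  expect_length(r1, 2 * 2 * 18 + 6)
  expect_true(all(grepl("^(MSI|nrCBV|shape)__", names(r1))))
  # map with non-finite in-mask values -> NA-flagged features
  bad <- maps
  bad$MSI[which(ph$tumor_mask)[1]] <- NA
  rb <- extract_all(bad, ph$tumor_mask, cfg)
  expect_true(all(is.na(rb[grepl("^MSI__", names(rb))])))
  expect_false(anyNA(rb[grepl("^nrCBV__", names(rb))]))
})

test_that("single-voxel ROI degrades texture gracefully", {
  ph <- build_phantom(small_phantom_spec(noise_sd = 0.5, seed = 22))
  maps <- phantom_parametric_maps(ph, maps = c("MSI"))
  mask1 <- array(FALSE, dim = dim(ph$tumor_mask))
  mask1[which(ph$tumor_mask)[1:2]] <- TRUE  # 2 voxels: first-order ok
  cfg <- feature_config(filters = "original", classes = c("firstorder", "glszm"))
  r <- extract_all(maps, mask1, cfg)
  expect_false(anyNA(r[grepl("firstorder", names(r))]))
})
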