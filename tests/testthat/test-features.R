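# Texture feature computation: GLCM, gradients, compression, spectra.

test_that("GLCM handles constant and checkerboard patches as enumerated", {
  g <- glcm_features(const_patch(100, 64))
  expect_equal(unname(g[c("glcm_asm", "glcm_entropy", "glcm_contrast")]),
               c(1, 0, 0))
  expect_equal(unname(g["glcm_correlation"]), 0)  # degenerate, by convention
  cb <- matrix(c(0L, 255L, 255L, 0L), 2)
  g2 <- glcm_features(cb, levels = 2, distances = 1, angles = 0)
  expect_equal(unname(g2["glcm_asm"]), 0.5)
  expect_equal(unname(g2["glcm_contrast"]), 1.0)
})

test_that("GLCM equals the brute-force pair-enumeration oracle on 4x4 toys", {
  offsets <- list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1))
  angles <- c(0, 45, 90, 135)
  for (seed in 1:5) {
    patch <- with_test_seed(seed, matrix(sample(0:255, 16, TRUE), 4))
    for (k in seq_along(angles)) {
      got <- glcm_features(patch, levels = 8, distances = 1,
                           angles = angles[k])
      want <- glcm_oracle(patch, levels = 8, offsets[[k]][1],
                          offsets[[k]][2])
      expect_equal(got, want, tolerance = 1e-12)
    }
  }
})

test_that("isotropic GLCM is the mean over per-offset features", {
  patch <- noise_patch(7, 32)
  iso <- glcm_features(patch, levels = 16, distances = c(1, 2),
                       angles = c(0, 90))
  single <- sapply(list(c(1, 0), c(1, 90), c(2, 0), c(2, 90)), function(da)
    glcm_features(patch, levels = 16, distances = da[1], angles = da[2]))
  expect_equal(iso, rowMeans(single), tolerance = 1e-12)
})

test_that("GLCM is invariant to a bin-aligned intensity shift", {
  # levels = 64 quantizes in steps of 4: shifting by 4 relabels all bins
  # identically while co-occurrence structure is unchanged
  patch <- with_test_seed(3, matrix(sample(seq(0, 200, by = 4), 64 * 64,
                                           TRUE), 64))
  expect_equal(glcm_features(patch), glcm_features(patch + 4L),
               tolerance = 1e-12)
})

test_that("gradient features match the Sobel expectations", {
  expect_equal(unname(gradient_features(const_patch(9, 64))), c(0, 0))
  ramp <- outer(rep(1, 512), 0:511)  # value = column index
  g <- gradient_features(ramp)
  expect_lt(g["grad_std"], 0.05 * g["grad_mean"])
  noise <- noise_patch(1)
  blurred <- blur_patch(noise, sigma = 4)
  expect_gt(gradient_features(noise)["grad_std"],
            gradient_features(blurred)["grad_std"])
})

test_that("compression density tracks incompressibility", {
  expect_lt(compression_feature(const_patch(100)), 0.05)
  noise <- noise_patch(2)
  expect_gt(compression_feature(noise), 7.9)
  expect_gt(compression_feature(noise),
            compression_feature(blur_patch(noise, sigma = 4)))
  # deterministic
  expect_identical(compression_feature(noise), compression_feature(noise))
})

test_that("radial spectrum is invariant to 90-degree rotation", {
  patch <- noise_patch(11, 128)
  rot90 <- t(patch)[ncol(patch):1, ]
  expect_lt(max(abs(radial_spectrum(patch) - radial_spectrum(rot90))), 1e-6)
})

test_that("spectral model obeys PCA structure", {
  spectra <- with_test_seed(5, matrix(rnorm(100 * 64), 100, 64) +
                              outer(rnorm(100), sin(seq_len(64) / 5)))
  model <- fit_spectral_model(spectra, n_components = 25)
  expect_equal(dim(model$components), c(25L, 64L))
  # orthonormal rows, non-increasing explained variance
  expect_equal(model$components %*% t(model$components), diag(25),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_true(all(diff(model$explained_variance) <= 1e-10))
  # duplication invariance
  model2 <- fit_spectral_model(rbind(spectra, spectra), n_components = 25)
  expect_equal(abs(model2$components), abs(model$components),
               tolerance = 1e-6)
  # training scores have zero mean per component
  scores <- spectral_transform(model, spectra)
  expect_equal(unname(colMeans(scores)), rep(0, 25), tolerance = 1e-10)
  # the mean spectrum projects to zero
  expect_equal(as.numeric(spectral_transform(
    model, matrix(model$mean_spectrum, 1))), rep(0, 25), tolerance = 1e-10)
  # linearity
  a <- 0.3
  mix <- a * spectra[1, , drop = FALSE] + (1 - a) * spectra[2, , drop = FALSE]
  expect_equal(as.numeric(spectral_transform(model, mix)),
               as.numeric(a * scores[1, ] + (1 - a) * scores[2, ]),
               tolerance = 1e-10)
  expect_error(fit_spectral_model(spectra[1:10, ], n_components = 25),
               class = "leaftex_validation_error")
  expect_error(spectral_transform(list(), spectra),
               class = "leaftex_state_error")
})

test_that("feature assembly produces one row per patch with the triplet", {
  patches <- lapply(1:4, function(i) structure(list(
    patch_id = sprintf("p%d", i), pixels = noise_patch(i, 512),
    image_id = "img1", species = "sp1", tree_id = "t1", leaf_id = "l1",
    batch_id = "B1", stoma_index = 0L, offset_um = c(row = 0, col = 0),
    mode = "whole_leaf"), class = "leaftex_patch"))
  # constant patch in the mix: triplet floors
  patches[[4]]$pixels <- const_patch(80)
  base <- extract_features(patches)
  expect_equal(nrow(base), 4)
  model <- fit_spectral_model(
    with_test_seed(1, matrix(rnorm(30 * 64), 30, 64)), n_components = 5)
  full <- add_spectral_scores(base, model)
  trip <- complexity_triplet(full)
  expect_equal(trip$info_density, full$compression_bpp)
  expect_equal(trip$heterogeneity, 1 - full$glcm_asm)
  expect_equal(trip$variability, full$grad_std)
  # constant patch: all three at their floor; noise strictly greater
  expect_lt(trip$info_density[4], 0.05)
  expect_equal(trip$heterogeneity[4], 0)
  expect_equal(trip$variability[4], 0)
  expect_true(all(trip$info_density[1:3] > trip$info_density[4]))
  expect_true(all(trip$heterogeneity[1:3] > trip$heterogeneity[4]))
  expect_true(all(trip$variability[1:3] > trip$variability[4]))
})

test_that("expected triplet features rise with the complexity parameter", {
  feats <- small_features()
  trip <- complexity_triplet(feats)
  truth <- small_bench()$species
  agg <- aggregate(trip[c("info_density", "heterogeneity", "variability")],
                   list(species = trip$species), mean)
  agg <- agg[match(truth$species, agg$species), ]
  for (f in c("info_density", "heterogeneity", "variability"))
    expect_gte(spearman_rho(agg[[f]], truth$complexity_c), 0.8)
})
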