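test_that("feature expansion is deterministic with the documented term order", {
  expect_equal(unname(expandFeatures(c(1, 2, 3), order = 1)), c(1, 2, 3, 1))
  z <- expandFeatures(c(0, 0, 0), order = 2)
  expect_equal(unname(z), c(rep(0, 9), 1))
  expect_equal(unname(expandFeatures(c(1, 1, 1), order = 2)), rep(1, 10))
  expect_equal(length(expandFeatures(c(2, 3, 4), order = 3)), featureCount(3))
  expect_error(expandFeatures(c(1, 2, 3), order = 4), "order")
})

test_that("rmse matches its closed form", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(0, 0, 0), c(1, 1, 1)), 1)
  expect_equal(rmse(c(1, 2, 3), c(2, 4, 6)), sqrt(14 / 3))
  expect_error(rmse(1:3, 1:4), "mismatch")
})

test_that("correction fit reproduces pseudoinverse least squares", {
  set.seed(21)
  camXYZ <- matrix(runif(72, 5, 95), 24, 3)

  # identity case: camera XYZ equals reference XYZ
  fitI <- fitCorrection(camXYZ, camXYZ, order = 1)
  expect_lt(max(abs(applyCorrection(fitI, camXYZ) - camXYZ)), 1e-9)

  # exact order-2 polynomial distortion is recovered
  genC <- matrix(rnorm(30, sd = 0.05), 3, 10)
  genC[, 1:3] <- genC[, 1:3] + diag(3)
  refXYZ <- expandFeatures(camXYZ, 2) %*% t(genC)
  fit2 <- fitCorrection(refXYZ, camXYZ, order = 2)
  expect_lt(max(fit2@patchRMSE), 1e-8)
  expect_equal(unname(fit2@coefficients), unname(genC), tolerance = 1e-6)
  expect_lt(max(abs(applyCorrection(fit2, camXYZ) - refXYZ)), 1e-7)

  # agrees with an independent normal-equations solution
  noisyRef <- refXYZ + matrix(rnorm(72, sd = 0.5), 24, 3)
  fitN <- fitCorrection(noisyRef, camXYZ, order = 2)
  oracle <- lsqOracle(noisyRef, expandFeatures(camXYZ, 2))
  expect_equal(unname(fitN@coefficients), unname(oracle), tolerance = 1e-8)

  # degenerate single patch: minimum-norm pinv fit still reproduces it
  expect_warning(
    fit1 <- fitCorrection(camXYZ[1, , drop = FALSE], camXYZ[1, , drop = FALSE],
                          order = 2),
    "rank-deficient")
  expect_lt(max(abs(applyCorrection(fit1, camXYZ[1, ]) - camXYZ[1, ])), 1e-8)
})

test_that("spectral basis PCA is exact on low-rank data and lossless at full rank", {
  # spectra in an exact 3-dimensional affine subspace
  set.seed(5)
  base <- randomSmoothSpectra(4, seed = 5)
  coef <- matrix(runif(30, -0.2, 0.2), 10, 3)
  spectra <- sweep(coef %*% base[1:3, ], 2, base[4, ], `+`)
  b3 <- fitSpectralBasis(spectra, k = 3)
  recon <- sweep(basisScores(b3, spectra) %*% t(b3@components), 2, b3@mean, `+`)
  expect_lt(max(sqrt(rowMeans((recon - spectra)^2))), 1e-10)
  expect_lt(max(abs(crossprod(b3@components) - diag(3))), 1e-8)
  expect_lte(sum(b3@explained), 1 + 1e-9)

  # identical spectra: mean is that spectrum, all scores zero
  same <- matrix(rep(base[1, ], 5), 5, byrow = TRUE)
  bSame <- fitSpectralBasis(same)
  expect_equal(bSame@mean, base[1, ])
  expect_lt(max(abs(basisScores(bSame, same))), 1e-12)

  # full-rank PCA is lossless and matches a direct SVD oracle
  sp <- randomSmoothSpectra(8, seed = 9)
  bf <- fitSpectralBasis(sp, k = 7)
  recon <- sweep(basisScores(bf, sp) %*% t(bf@components), 2, bf@mean, `+`)
  expect_lt(max(sqrt(rowMeans((recon - sp)^2))), 1e-10)
  sv <- svd(sweep(sp, 2, colMeans(sp)))
  expect_equal(abs(diag(crossprod(bf@components, sv$v[, 1:7]))), rep(1, 7),
               tolerance = 1e-8)

  expect_error(fitSpectralBasis(sp, k = 8), "rank")
})

test_that("transformation fit recovers generating linear spectra and ignores patch order", {
  set.seed(31)
  xyz <- matrix(runif(72, 10, 90), 24, 3)
  # spectra generated as exact linear images of the expanded features;
  # built from normalized features so amplitudes stay spectra-like (any
  # polynomial of xyz/100 up to order 2 lies in the order-2 feature span)
  featsN <- expandFeatures(xyz / 100, 2)
  waves <- randomSmoothSpectra(10, seed = 13)
  genW <- t(waves) %*% matrix(rnorm(100, sd = 0.05), 10, 10)  # 401 x 10
  spectra <- 0.5 + featsN %*% t(genW)
  corr <- fitCorrection(xyz, xyz, order = 1)
  basis <- fitSpectralBasis(spectra, k = 9)
  model <- fitTransformation(basis, corr, xyz, spectra, order = 2)
  expect_lt(max(model@patchRMSE), 1e-8)

  # permuting patches leaves M unchanged
  perm <- sample(24)
  model2 <- fitTransformation(basis, corr, xyz[perm, ], spectra[perm, ], order = 2)
  expect_equal(model@M, model2@M, tolerance = 1e-8)

  # constant spectra: everything maps to the mean spectrum
  const <- matrix(0.42, 24, 401)
  bC <- fitSpectralBasis(const)
  mC <- fitTransformation(bC, corr, xyz, const, order = 2)
  rec <- reconstructSpectrum(mC, c(30, 50, 70))
  expect_equal(spectralValues(rec), rep(0.42, 401), tolerance = 1e-9)
})

test_that("noiseless calibration reconstructs every training patch spectrum", {
  fx <- noiselessModel(seed = 7)
  camXYZ <- cameraXYZOf(fx$checker)
  recon <- reconstructSpectrum(fx$model, camXYZ, clip = FALSE)
  err <- sqrt(colMeans((recon - t(fx$checker@reflectance))^2))
  expect_lt(max(err), 1e-6)
  expect_lt(max(fx$model@patchRMSE), 1e-6)

  # single-patch closed loop through the generic
  one <- reconstructSpectrum(fx$model, camXYZ[5, ])
  expect_equal(spectralValues(one), fx$checker@reflectance[5, ], tolerance = 1e-6)

  # zero-score input returns the basis mean
  basis <- spectralBasis(fx$model)
  M <- transformationMatrix(fx$model)
  # find xyz whose expanded corrected features are annihilated: use the
  # affine structure instead - reconstruction is affine, so the midpoint
  # property must hold before clipping
  r1 <- reconstructSpectrum(fx$model, camXYZ[1, ], clip = FALSE)
  r2 <- reconstructSpectrum(fx$model, camXYZ[2, ], clip = FALSE)
  expect_s4_class(r1, "SpectralCurve")
  expect_equal(ncol(basis@components), 3L)
  expect_true(all(is.finite(M)))
  expect_identical(modality(fx$model), "WLI")
})

test_that("reconstruction is affine in feature space for a linear model", {
  # with an order-1 expansion the feature map itself is affine in XYZ, so
  # midpoint reconstruction must equal the average of reconstructions
  fx <- noiselessModel(seed = 3, order = 1)
  camXYZ <- cameraXYZOf(fx$checker)
  a <- camXYZ[3, ]; b <- camXYZ[11, ]
  mid <- reconstructSpectrum(fx$model, (a + b) / 2, clip = FALSE)
  ra <- reconstructSpectrum(fx$model, a, clip = FALSE)
  rb <- reconstructSpectrum(fx$model, b, clip = FALSE)
  expect_equal(spectralValues(mid),
               (spectralValues(ra) + spectralValues(rb)) / 2,
               tolerance = 1e-9)
})

test_that("conversion model JSON serialization round-trips", {
  fx <- noiselessModel(seed = 19)
  path <- withr::local_tempfile(fileext = ".json")
  writeConversionModel(fx$model, path)
  back <- readConversionModel(path)
  expect_equal(back@M, fx$model@M)
  expect_equal(back@correction@coefficients, fx$model@correction@coefficients)
  expect_equal(back@basis@mean, fx$model@basis@mean)
  expect_equal(bandWindow(back), bandWindow(fx$model))
  xyz <- c(40, 50, 60)
  expect_equal(spectralValues(reconstructSpectrum(back, xyz)),
               spectralValues(reconstructSpectrum(fx$model, xyz)),
               tolerance = 1e-12)
})
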