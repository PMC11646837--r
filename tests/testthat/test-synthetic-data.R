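test_that("generators are deterministic under a fixed seed", {
  expect_equal(makeColorChecker(5)@cameraRGB, makeColorChecker(5)@cameraRGB)
  expect_equal(makeColorChecker(5)@reflectance, makeColorChecker(5)@reflectance)
  s1 <- makeScene(10, 10, data.frame(class = "SCC", cx = 5, cy = 5, rx = 3, ry = 2),
                  seed = 3)
  s2 <- makeScene(10, 10, data.frame(class = "SCC", cx = 5, cy = 5, rx = 3, ry = 2),
                  seed = 3)
  expect_equal(s1$image, s2$image)
  expect_false(isTRUE(all.equal(makeColorChecker(6)@cameraRGB,
                                makeColorChecker(5)@cameraRGB)))
})

test_that("checker patches are bounded reflectances with valid camera RGB", {
  ck <- makeColorChecker(11)
  expect_equal(dim(ck@reflectance), c(24L, 401L))
  expect_true(all(ck@reflectance >= 0 & ck@reflectance <= 1))
  expect_true(all(ck@cameraRGB >= 0 & ck@cameraRGB <= 1))
  # spectrometer XYZ agrees with direct tristimulus integration
  direct <- spectrumToXYZ(ck@illuminant, ck@reflectance[7, ])
  expect_equal(unname(ck@spectrometerXYZ[7, ]), unname(direct), tolerance = 1e-10)
})

test_that("illuminant shapes match their definitions", {
  expect_equal(spectralValues(makeIlluminant("flat")), rep(1, 401))
  bb <- spectralValues(makeIlluminant("broadband"))
  expect_true(all(bb > 0))
  nb <- spectralValues(makeIlluminant("dual-narrowband"))
  wl <- hsiWavelengths()
  # independent numeric integration of the two stated Gaussians
  # (centers 415/540, FWHM 30) puts 1.42% of the energy outside 390-570
  s <- 30 / (2 * sqrt(log(2)))
  oracle <- exp(-((wl - 415) / s)^2) + exp(-((wl - 540) / s)^2)
  outside <- sum(nb[wl < 390 | wl > 570]) / sum(nb)
  expect_equal(outside, sum(oracle[wl < 390 | wl > 570]) / sum(oracle),
               tolerance = 1e-12)
  expect_lt(outside, 0.02)
  # both stated band centers carry energy
  expect_gt(nb[wl == 415], 0.9)
  expect_gt(nb[wl == 540], 0.9)
})

test_that("scenes emit tight boxes and severity-resolved class maps", {
  # zero lesions: all-background frame, no boxes
  empty <- makeScene(8, 8, seed = 1)
  expect_equal(nrow(empty$truth), 0L)
  expect_true(all(empty$classMap == "normal"))

  # one SCC ellipse: a single box enclosing exactly the SCC pixels
  sc <- makeScene(20, 20, data.frame(class = "SCC", cx = 10, cy = 9, rx = 5, ry = 4),
                  seed = 2)
  expect_equal(nrow(sc$truth), 1L)
  expect_equal(sc$truth$class, "SCC")
  sccCols <- which(apply(sc$classMap == "SCC", 2, any))
  sccRows <- which(apply(sc$classMap == "SCC", 1, any))
  expect_equal(sc$truth$x_min, min(sccCols) - 1)
  expect_equal(sc$truth$x_max, max(sccCols))
  expect_equal(sc$truth$y_min, min(sccRows) - 1)
  expect_equal(sc$truth$y_max, max(sccRows))

  # overlapping lesions: most severe class wins
  ov <- makeScene(20, 20,
                  data.frame(class = c("dysplasia", "SCC"),
                             cx = c(10, 12), cy = c(10, 10),
                             rx = c(6, 4), ry = c(5, 3)), seed = 4)
  inBoth <- ov$classMap[10, 11]
  expect_equal(inBoth, "SCC")
})

test_that("tissue classes separate in the 415-540 nm window as specified", {
  specs <- defaultTissueSpecs()
  bandMean <- function(s)
    mean(spectralValues(bandSlice(tissueMeanSpectrum(s), c(415, 540))))
  mN <- bandMean(specs$normal); mD <- bandMean(specs$dysplasia); mS <- bandMean(specs$SCC)
  expect_gt(mN, mD)
  expect_gt(mD, mS)
  expect_gt(min(mN - mD, mD - mS), 0.05)   # separation margin
  # pipeline-level recovery preserves the ordering
  fx <- noiselessModel(seed = 7)
  sc <- makeScene(20, 20,
                  data.frame(class = c("dysplasia", "SCC"),
                             cx = c(6, 14), cy = c(6, 14), rx = c(3, 3), ry = c(3, 3)),
                  seed = 6)
  cube <- convertImage(sc$image, fx$model)
  rec <- function(cl) mean(spectralValues(bandSlice(
    regionSpectrum(cube, sc$classMap == cl)$mean, c(415, 540))))
  expect_gt(rec("normal"), rec("dysplasia"))
  expect_gt(rec("dysplasia"), rec("SCC"))
})

test_that("end-to-end region spectra recover the generating class means", {
  fx <- noiselessModel(seed = 7)
  sc <- makeScene(16, 16, data.frame(class = "dysplasia", cx = 8, cy = 8,
                                     rx = 4, ry = 4), seed = 5)
  cube <- convertImage(sc$image, fx$model)
  for (cl in c("normal", "dysplasia")) {
    got <- regionSpectrum(cube, sc$classMap == cl)$mean
    want <- tissueMeanSpectrum(defaultTissueSpecs()[[cl]])
    expect_lt(rmse(spectralValues(got), spectralValues(want)), 1e-3)
  }
})

test_that("synthetic detections honor their configured rates at the extremes", {
  truth <- lapply(1:30, function(i) {
    if (i <= 15)
      frameRecord(paste0("n", i),
                  truth = data.frame(class = "SCC", x_min = 10, y_min = 10,
                                     x_max = 50, y_max = 45))
    else frameRecord(paste0("h", i))
  })
  # perfect detector: accuracy 100%, kappa 1
  perfect <- makeDetections(truth, sensitivity = 1, fpRate = 0, seed = 2)
  ev <- evaluateDataset(perfect)
  expect_equal(ev$multiclass$accuracy, 1)
  expect_equal(ev$multiclass$kappa, 1)
  # jittered matches stay above the 0.5 IoU threshold by construction
  expect_true(all(ev$outcomes$detected[1:15]))
  # blind detector: every neoplasm frame missed
  blind <- makeDetections(truth, sensitivity = 0, fpRate = 0, seed = 2)
  evb <- evaluateDataset(blind)
  expect_equal(unname(evb$binary$counts["TP"]), 0)
  expect_equal(unname(evb$binary$counts["FN"]), 15)
})

test_that("deterministic count allocation reproduces any target confusion matrix", {
  cms <- referenceConfusionMatrices()
  for (nm in names(cms)) {
    ev <- evaluateDataset(framesFromConfusion(cms[[nm]]))
    expect_equal(unclass(ev$confusion), unclass(cms[[nm]]))
  }
  # binary allocation
  ev2 <- evaluateDataset(framesFromCounts(5, 3, 7, 2))
  expect_equal(unname(ev2$binary$counts), c(5, 3, 7, 2))
})

test_that("patch recovery error grows with camera noise", {
  sigmas <- c(0, 0.002, 0.01)
  seeds <- 1:8
  err <- vapply(sigmas, function(s) {
    mean(vapply(seeds, function(sd) {
      ck <- makeColorChecker(sd, syntheticCamera(noiseSigma = s))
      mean(fitConversionModel(ck)@patchRMSE)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(err) > 0))
  expect_lt(err[1], 1e-6)
})
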