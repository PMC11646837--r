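#' Synthetic trichromatic camera model
#'
#' Forward model used to render synthetic scenes and color checkers:
#' normalized scene XYZ is mixed by an invertible 3x3 matrix into linear
#' RGB, optionally perturbed by additive Gaussian noise, clipped to [0, 1]
#' and gamma-encoded. The default mixing matrix is the inverse of the
#' sRGB primaries matrix with a small fixed channel crosstalk, so the
#' camera is realistic but not trivially the standard inverse. An optional
#' \code{distortion} matrix (3 x p, camera-to-reference) defines the
#' reference XYZ as an exact polynomial of the camera-derived XYZ, which
#' keeps the generating map inside the family the calibration assumes.
#'
#' @param mixing 3x3 invertible matrix (normalized XYZ -> linear RGB).
#' @param crosstalk Fixed off-diagonal perturbation strength applied to
#'   the default mixing matrix (ignored when \code{mixing} is given).
#' @param gamma Apply sRGB encoding (default TRUE).
#' @param noiseSigma Additive Gaussian noise sd in linear RGB (default 0).
#' @param distortion Optional 3 x p polynomial matrix with
#'   \code{distortionOrder} (see above); NULL = no distortion.
#' @param distortionOrder Expansion order of \code{distortion}.
#' @return List of class \code{syntheticCamera}.
#' @export
syntheticCamera <- function(mixing = NULL, crosstalk = 0.02, gamma = TRUE,
                            noiseSigma = 0, distortion = NULL,
                            distortionOrder = 2L) {
  if (is.null(mixing)) {
    base <- solve(srgbToXYZMatrix())
    pert <- matrix(c(0, 1, -1, 1, 0, 1, -1, 1, 0), 3, 3) * crosstalk
    mixing <- base + pert
  }
  if (abs(det(mixing)) < 1e-9) stop("mixing matrix must be invertible")
  if (noiseSigma < 0) stop("noise sigma must be >= 0")
  structure(list(mixing = mixing, gamma = gamma, noiseSigma = noiseSigma,
                 distortion = distortion,
                 distortionOrder = as.integer(distortionOrder)),
            class = "syntheticCamera")
}

#' Render XYZ values through a synthetic camera
#'
#' @param camera A [syntheticCamera()].
#' @param xyz n x 3 matrix of scene XYZ (Y scale 0-100).
#' @return n x 3 matrix of encoded camera RGB in [0, 1].
#' @export
renderCameraRGB <- function(camera, xyz) {
  lin <- rbind(xyz) %*% t(camera$mixing) / 100
  if (camera$noiseSigma > 0)
    lin <- lin + matrix(stats::rnorm(length(lin), 0, camera$noiseSigma),
                        nrow(lin), ncol(lin))
  lin <- pmin(pmax(lin, 0), 1)
  if (camera$gamma) gammaEncode(lin) else lin
}

#' Reference XYZ under a camera's distortion model
#'
#' When the camera carries a polynomial distortion, the reference
#' (spectrometer-equivalent) XYZ is that polynomial of the camera-derived
#' XYZ; otherwise it is the camera XYZ itself.
#'
#' @param camera A [syntheticCamera()].
#' @param cameraXYZ n x 3 matrix.
#' @return n x 3 matrix.
#' @export
cameraReferenceXYZ <- function(camera, cameraXYZ) {
  if (is.null(camera$distortion)) return(rbind(cameraXYZ))
  expandFeatures(rbind(cameraXYZ), camera$distortionOrder) %*% t(camera$distortion)
}

# smooth positive Gaussian bump on the standard grid
.bump <- function(center, width, amp = 1) {
  wl <- hsiWavelengths()
  amp * exp(-((wl - center) / width)^2)
}

# The three fixed Gaussian components spanning the synthetic reflectance
# family (401 x 3). Every synthetic reflectance - checker patches and
# tissue classes alike - is base + this matrix times a coefficient
# triplet, so the family is 3-dimensional and tristimulus values
# determine a member uniquely (no metamerism); that is what makes the
# noiseless calibration loop exactly invertible. The middle component is
# centered in the 415-540 nm analysis window.
.synthBumps <- function() {
  cbind(b430 = .bump(430, 45), b477 = .bump(477, 55), b630 = .bump(630, 120))
}

.synthBase <- 0.06

#' Spectrum of the synthetic reflectance family
#'
#' @param coef Length-3 non-negative coefficients of the fixed Gaussian
#'   components (centers 430, 477, 630 nm).
#' @return A reflectance [SpectralCurve-class].
#' @export
synthReflectance <- function(coef) {
  spectralCurve(pmin(pmax(.synthBase + as.numeric(.synthBumps() %*% coef),
                          0.02), 0.95))
}

#' Synthetic illuminant spectra
#'
#' \code{flat} is a constant spectrum; \code{broadband} a smooth strictly
#' positive daylight-like curve; \code{dual-narrowband} two Gaussian bands
#' centered at 415 and 540 nm with 30 nm FWHM, emulating narrow-band
#' endoscopic illumination.
#'
#' @param kind "flat", "broadband" or "dual-narrowband".
#' @return An illuminant [SpectralCurve-class].
#' @export
makeIlluminant <- function(kind = c("flat", "broadband", "dual-narrowband")) {
  kind <- match.arg(kind)
  wl <- hsiWavelengths()
  v <- switch(kind,
    flat = rep(1, length(wl)),
    broadband = 0.55 + 0.45 * exp(-((wl - 560) / 160)^2) +
      0.10 * exp(-((wl - 450) / 60)^2),
    `dual-narrowband` = {
      s <- 30 / (2 * sqrt(log(2)))   # FWHM 30 nm
      exp(-((wl - 415) / s)^2) + exp(-((wl - 540) / s)^2)
    })
  spectralCurve(v, kind = "illuminant")
}

#' Synthetic 24-patch color checker
#'
#' Generates 24 smooth reflectance spectra as three-component Gaussian
#' mixtures over 380-780 nm (fixed component shapes, random per-patch
#' amplitudes, clipped to [0.02, 0.95]; the amplitude range is chosen so
#' the clip is never active and the family stays exactly 3-dimensional),
#' computes the spectrometer XYZ of each patch under the illuminant, and
#' renders the camera RGB through the synthetic camera. Fully
#' deterministic for a fixed seed.
#'
#' @param seed Integer RNG seed.
#' @param camera A [syntheticCamera()].
#' @param illuminant Illuminant [SpectralCurve-class].
#' @return A [ColorChecker-class].
#' @export
makeColorChecker <- function(seed = 1L, camera = syntheticCamera(),
                             illuminant = makeIlluminant("broadband")) {
  set.seed(seed)
  coefs <- matrix(stats::runif(24 * 3, 0.02, 0.30), 24, 3)
  refl <- t(vapply(seq_len(24),
                   function(i) spectralValues(synthReflectance(coefs[i, ])),
                   numeric(401)))
  xyz <- t(apply(refl, 1, function(r) spectrumToXYZ(illuminant, r)))
  colnames(xyz) <- c("X", "Y", "Z")
  # camera sees the reference scene; distortion (if any) defines the
  # reference values as a polynomial of what the camera reports
  camRGB <- renderCameraRGB(camera, xyz)
  new("ColorChecker",
      patchId = sprintf("patch%02d", 1:24),
      cameraRGB = camRGB, reflectance = refl, spectrometerXYZ = xyz,
      illuminant = illuminant)
}

#' Tissue class spectral specification
#'
#' Each class is a smooth background reflectance plus a class-dependent
#' amplitude on a broad 415-540 nm band feature, so the three classes
#' separate specifically inside the analysis window (normal most
#' reflective, SCC least). \code{withinSigma} scales per-pixel variability
#' of the band amplitude.
#'
#' @param class "normal", "dysplasia" or "SCC".
#' @param bandAmplitude Reflectivity amplitude of the 415-540 nm feature.
#' @param withinSigma Within-class variability (sd of the amplitude
#'   multiplier), default 0.
#' @return List of class \code{tissueClassSpec}.
#' @export
tissueClassSpec <- function(class, bandAmplitude, withinSigma = 0) {
  stopifnot(class %in% tissueClasses(), bandAmplitude >= 0, withinSigma >= 0)
  structure(list(class = class, bandAmplitude = bandAmplitude,
                 withinSigma = withinSigma), class = "tissueClassSpec")
}

#' @rdname tissueClassSpec
#' @param withinSigma Shared within-class variability for all classes.
#' @export
defaultTissueSpecs <- function(withinSigma = 0) {
  list(normal = tissueClassSpec("normal", 0.30, withinSigma),
       dysplasia = tissueClassSpec("dysplasia", 0.18, withinSigma),
       SCC = tissueClassSpec("SCC", 0.06, withinSigma))
}

# class mean spectrum: smooth reddish background + window band feature;
# a member of the same 3-dimensional family as the checker patches, so a
# noiseless calibrated model represents tissue spectra exactly
.tissueSpectrum <- function(spec, ampMultiplier = 1) {
  spectralValues(synthReflectance(
    c(0.05, spec$bandAmplitude * ampMultiplier, 0.26)))
}

#' Mean reflectance spectrum of a tissue class
#'
#' @param spec A [tissueClassSpec()].
#' @return A reflectance [SpectralCurve-class].
#' @export
tissueMeanSpectrum <- function(spec) spectralCurve(.tissueSpectrum(spec))

#' Synthetic lesion scene
#'
#' Builds a frame: a background of normal tissue with elliptical lesions
#' of the requested classes, per-pixel reflectance spectra drawn from the
#' class specifications, camera RGB rendered under the illuminant, and a
#' tight ground-truth bounding box per lesion (0-based, half-open pixel
#' coordinates; x along columns, y along rows). Where lesions of
#' different classes overlap, the most severe class wins.
#'
#' @param height,width Image size in pixels.
#' @param lesions data.frame with columns class, cx, cy, rx, ry (ellipse
#'   centers/radii in pixels); zero rows = all-normal frame.
#' @param tissue List of class specs from [defaultTissueSpecs()].
#' @param camera A [syntheticCamera()].
#' @param illuminant Illuminant curve.
#' @param seed RNG seed (per-pixel variability and camera noise).
#' @return List: image (H x W x 3 encoded RGB), truth (box data.frame),
#'   classMap (H x W character matrix), spectra (H x W x 401 array of the
#'   generating reflectances).
#' @export
makeScene <- function(height = 32, width = 32, lesions = NULL,
                      tissue = defaultTissueSpecs(),
                      camera = syntheticCamera(),
                      illuminant = makeIlluminant("broadband"), seed = 1L) {
  set.seed(seed)
  if (is.null(lesions)) lesions <- data.frame(class = character(), cx = numeric(),
                                              cy = numeric(), rx = numeric(),
                                              ry = numeric())
  classMap <- matrix("normal", height, width)
  truth <- emptyBoxes()
  if (nrow(lesions)) {
    cols <- matrix(rep(seq_len(width), each = height), height, width)
    rows <- matrix(rep(seq_len(height), width), height, width)
    for (i in seq_len(nrow(lesions))) {
      l <- lesions[i, ]
      inside <- ((cols - 0.5 - l$cx) / l$rx)^2 + ((rows - 0.5 - l$cy) / l$ry)^2 <= 1
      if (!any(inside)) stop("lesion ", i, " has no pixels inside the frame")
      replace <- inside & .severity(classMap) < .severity(l$class)
      classMap[replace] <- l$class
      truth <- rbind(truth, data.frame(
        class = l$class,
        x_min = min(cols[inside]) - 1, y_min = min(rows[inside]) - 1,
        x_max = max(cols[inside]), y_max = max(rows[inside])))
    }
  }
  wl <- hsiWavelengths()
  n <- height * width
  spectra <- matrix(0, n, length(wl))
  for (cl in tissueClasses()) {
    idx <- which(as.vector(classMap) == cl)
    if (!length(idx)) next
    spc <- tissue[[cl]]
    if (spc$withinSigma > 0) {
      mult <- 1 + stats::rnorm(length(idx), 0, spc$withinSigma)
      spectra[idx, ] <- t(vapply(mult, function(m) .tissueSpectrum(spc, m),
                                 numeric(length(wl))))
    } else {
      spectra[idx, ] <- matrix(.tissueSpectrum(spc), length(idx),
                               length(wl), byrow = TRUE)
    }
  }
  xyz <- t(apply(spectra, 1, function(r) spectrumToXYZ(illuminant, r)))
  rgbFlat <- renderCameraRGB(camera, xyz)
  image <- array(rgbFlat, dim = c(height, width, 3))
  list(image = image, truth = truth, classMap = classMap,
       spectra = array(spectra, dim = c(height, width, length(wl))))
}

#' Synthetic detector outputs for frame records
#'
#' Generates predicted boxes for a list of ground-truth frames with
#' controlled error rates. Each neoplasm frame is detected with
#' probability \code{sensitivity}; a detection reproduces the truth box
#' jittered by a fraction of its size (bounded so the IoU stays >= 0.5 by
#' construction) and carries a class drawn from \code{classConfusion}
#' (row-stochastic, rows = true class). Normal frames receive a spurious
#' box with probability \code{fpRate}, with class probabilities
#' \code{fpClassProbs}.
#'
#' @param records List of [frameRecord()] with truth boxes.
#' @param sensitivity Detection probability per neoplasm frame.
#' @param classConfusion 3x3 row-stochastic matrix (default identity).
#' @param fpRate False-positive rate on normal frames.
#' @param fpClassProbs Probabilities of (dysplasia, SCC) for spurious boxes.
#' @param jitter Box-shift fraction, capped at 0.15 (IoU >= 0.5 guaranteed).
#' @param seed RNG seed.
#' @return The records with \code{pred} filled in.
#' @export
makeDetections <- function(records, sensitivity = 0.85,
                           classConfusion = diag(3), fpRate = 0.08,
                           fpClassProbs = c(0.6, 0.4), jitter = 0.08,
                           seed = 1L) {
  set.seed(seed)
  if (sensitivity < 0 || sensitivity > 1 || fpRate < 0 || fpRate > 1)
    stop("rates must lie in [0, 1]")
  jitter <- min(jitter, 0.15)
  dimnames(classConfusion) <- list(tissueClasses(), tissueClasses())
  lapply(records, function(rec) {
    pred <- emptyBoxes(TRUE)
    if (nrow(rec$truth)) {
      if (stats::runif(1) < sensitivity) {
        severe <- rec$truth[which.max(.severity(rec$truth$class)), ]
        w <- severe$x_max - severe$x_min; h <- severe$y_max - severe$y_min
        dx <- stats::runif(1, -jitter, jitter) * w
        dy <- stats::runif(1, -jitter, jitter) * h
        cls <- sample(tissueClasses(), 1,
                      prob = classConfusion[severe$class, ])
        pred <- data.frame(class = cls,
                           x_min = severe$x_min + dx, y_min = severe$y_min + dy,
                           x_max = severe$x_max + dx, y_max = severe$y_max + dy,
                           confidence = stats::runif(1, 0.6, 0.99))
      }
    } else if (stats::runif(1) < fpRate) {
      cls <- sample(c("dysplasia", "SCC"), 1, prob = fpClassProbs)
      x0 <- stats::runif(1, 0, 20); y0 <- stats::runif(1, 0, 20)
      pred <- data.frame(class = cls, x_min = x0, y_min = y0,
                         x_max = x0 + 8, y_max = y0 + 8,
                         confidence = stats::runif(1, 0.5, 0.9))
    }
    rec$pred <- pred
    rec
  })
}

#' Deterministic frame fixtures from target count tables
#'
#' Deterministic count-allocation generators: rather than sampling error
#' rates, these emit exactly the frames needed so that [evaluateDataset()]
#' reproduces a target table. \code{framesFromConfusion} realizes a 3x3
#' confusion matrix (true x predicted); \code{framesFromCounts} a binary
#' TP/FN/TN/FP table. Matched predictions are constructed at IoU about
#' 0.68 (> 0.5); misses have no prediction; false positives are boxes on
#' truth-empty frames.
#'
#' @param cm 3x3 confusion matrix (rows true, columns predicted).
#' @param modality Modality tag.
#' @return List of [frameRecord()] objects.
#' @export
framesFromConfusion <- function(cm, modality = "WLI") {
  cm <- .checkCM(cm)
  records <- list(); id <- 0L
  mkTruth <- function(cls) data.frame(class = cls, x_min = 10, y_min = 10,
                                      x_max = 60, y_max = 50)
  mkPred <- function(cls, matched) {
    if (matched)
      data.frame(class = cls, x_min = 15, y_min = 14, x_max = 65, y_max = 54,
                 confidence = 0.9)
    else
      data.frame(class = cls, x_min = 70, y_min = 60, x_max = 90, y_max = 80,
                 confidence = 0.8)
  }
  for (i in tissueClasses()) for (j in tissueClasses()) {
    nij <- cm[i, j]
    if (nij == 0) next
    for (r in seq_len(nij)) {
      id <- id + 1L
      truth <- if (i == "normal") emptyBoxes() else mkTruth(i)
      pred <- if (j == "normal") emptyBoxes(TRUE) else mkPred(j, matched = (i != "normal"))
      records[[id]] <- frameRecord(sprintf("frame%05d", id), truth, pred, modality)
    }
  }
  records
}

#' @rdname framesFromConfusion
#' @param TP,FN,TN,FP Binary frame counts (neoplasm class fixed to SCC).
#' @export
framesFromCounts <- function(TP, FN, TN, FP, modality = "WLI") {
  cm <- matrix(0, 3, 3)
  cm[1, 1] <- TN; cm[1, 3] <- FP; cm[3, 3] <- TP; cm[3, 1] <- FN
  framesFromConfusion(cm, modality)
}
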