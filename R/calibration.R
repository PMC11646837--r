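#' Monomial feature expansion of an XYZ triplet
#'
#' Expands (X, Y, Z) into the full polynomial basis up to the given order,
#' in a fixed documented order: linear terms, then (for order >= 2) squares
#' and pairwise products, then (order 3) cubes and remaining cubic
#' monomials, with the constant term last. This is the variable vector of
#' the pseudoinverse regression that fits the XYZ correction and the
#' score transformation.
#'
#' @param xyz XYZ triplet or n x 3 matrix.
#' @param order Polynomial order, 1-3. Default 2 (10 terms; with 24
#'   calibration patches this keeps the regression well-determined).
#' @return Numeric vector of length \code{featureCount(order)}, or an
#'   n x p matrix.
#' @export
#' @examples
#' expandFeatures(c(1, 2, 3), order = 1)  # 1 2 3 1
expandFeatures <- function(xyz, order = 2L) {
  order <- as.integer(order)
  if (!order %in% 1:3) stop("expansion order must be 1, 2 or 3")
  m <- if (is.matrix(xyz)) xyz else matrix(xyz, nrow = 1)
  if (any(!is.finite(m))) stop("XYZ values must be finite")
  X <- m[, 1]; Y <- m[, 2]; Z <- m[, 3]
  cols <- list(X = X, Y = Y, Z = Z)
  if (order >= 2L)
    cols <- c(cols, list(X2 = X^2, Y2 = Y^2, Z2 = Z^2,
                         XY = X * Y, XZ = X * Z, YZ = Y * Z))
  if (order >= 3L)
    cols <- c(cols, list(X3 = X^3, Y3 = Y^3, Z3 = Z^3,
                         X2Y = X^2 * Y, X2Z = X^2 * Z, Y2X = Y^2 * X,
                         Y2Z = Y^2 * Z, Z2X = Z^2 * X, Z2Y = Z^2 * Y,
                         XYZ = X * Y * Z))
  cols <- c(cols, list(const = rep(1, nrow(m))))
  out <- do.call(cbind, cols)
  if (is.matrix(xyz)) out else out[1, ]
}

#' @rdname expandFeatures
#' @export
featureCount <- function(order) c(4L, 10L, 20L)[as.integer(order)]

#' Root-mean-square error
#'
#' @param a,b Numeric vectors of equal length.
#' @return sqrt(mean((a - b)^2)).
#' @export
rmse <- function(a, b) {
  if (length(a) != length(b)) stop("rmse: length mismatch")
  sqrt(mean((a - b)^2))
}

#' Fit the XYZ correction matrix
#'
#' Least-squares fit of a 3 x p coefficient matrix C mapping expanded
#' camera-derived XYZ features onto spectrometer XYZ, solved through the
#' pseudoinverse of the p x n variable matrix V:
#' C = XYZ_spectrometer . pinv(V). With a rank-deficient V the
#' minimum-norm solution is returned with a warning.
#'
#' @param spectrometerXYZ n x 3 matrix of reference XYZ (one row per patch).
#' @param cameraXYZ n x 3 matrix of camera-derived XYZ.
#' @param order Expansion order (1-3); \code{featureCount(order)} must not
#'   exceed the patch count for a full-rank fit.
#' @return A [CorrectionModel-class] storing C and per-patch residual RMSE.
#' @export
fitCorrection <- function(spectrometerXYZ, cameraXYZ, order = 2L) {
  spectrometerXYZ <- rbind(spectrometerXYZ)
  cameraXYZ <- rbind(cameraXYZ)
  if (nrow(spectrometerXYZ) != nrow(cameraXYZ))
    stop("patch counts differ between reference and camera XYZ")
  V <- t(expandFeatures(cameraXYZ, order))          # p x n
  if (qr(V)$rank < nrow(V))
    warning("rank-deficient variable matrix; returning the minimum-norm fit")
  C <- t(spectrometerXYZ) %*% pracma::pinv(V)       # 3 x p
  fitted <- t(C %*% V)
  perPatch <- sqrt(rowMeans((fitted - spectrometerXYZ)^2))
  new("CorrectionModel", order = as.integer(order), coefficients = unname(C),
      patchRMSE = as.numeric(perPatch))
}

#' Apply a fitted XYZ correction
#'
#' @param model A [CorrectionModel-class].
#' @param xyz XYZ triplet or n x 3 matrix.
#' @return Corrected XYZ triplet or n x 3 matrix.
#' @export
applyCorrection <- function(model, xyz) {
  feats <- expandFeatures(xyz, model@order)
  if (is.matrix(xyz)) {
    out <- feats %*% t(model@coefficients)
    colnames(out) <- c("X", "Y", "Z")
    return(out)
  }
  out <- as.numeric(model@coefficients %*% feats)
  names(out) <- c("X", "Y", "Z")
  out
}

#' Fit a PCA basis for reflectance spectra
#'
#' Mean-centered principal components of a set of spectra on the standard
#' grid, ordered by decreasing explained variance. The number of retained
#' components is either given explicitly or chosen as the smallest k
#' reaching the explained-variance threshold (capped at \code{maxK}).
#'
#' @param spectra n x 401 matrix (rows are spectra), n >= 2.
#' @param k Number of components; NULL = pick by threshold.
#' @param varianceThreshold Fraction of variance to retain (default 0.999).
#' @param maxK Cap on the automatic choice (default 12).
#' @return A [SpectralBasis-class].
#' @export
fitSpectralBasis <- function(spectra, k = NULL, varianceThreshold = 0.999,
                             maxK = 12L) {
  spectra <- rbind(spectra)
  n <- nrow(spectra)
  if (n < 2L) stop("at least two spectra are required")
  mu <- colMeans(spectra)
  Xc <- sweep(spectra, 2, mu)
  sv <- svd(Xc)
  totVar <- sum(sv$d^2)
  rank <- sum(sv$d > max(sv$d) * 1e-12)
  if (totVar == 0) {
    # all spectra identical: a single null direction with zero variance
    comp <- matrix(0, ncol(spectra), 1); comp[1, 1] <- 1
    return(new("SpectralBasis", mean = mu, components = comp, explained = 0))
  }
  explainedAll <- sv$d^2 / totVar
  if (is.null(k)) {
    k <- min(which(cumsum(explainedAll) >= varianceThreshold))
    k <- min(k, maxK, rank)
  } else {
    if (k > min(n - 1L, rank))
      stop("k exceeds the available rank of the spectra")
  }
  new("SpectralBasis", mean = mu,
      components = sv$v[, seq_len(k), drop = FALSE],
      explained = explainedAll[seq_len(k)])
}

#' Project spectra onto a basis
#'
#' @param basis A [SpectralBasis-class].
#' @param spectra n x 401 matrix.
#' @return n x k score matrix.
#' @export
basisScores <- function(basis, spectra) {
  sweep(rbind(spectra), 2, basis@mean) %*% basis@components
}

#' Fit the feature-to-score transformation matrix
#'
#' Fits the k x q matrix M mapping expanded corrected-XYZ features to PCA
#' scores of the calibration reflectances (pseudoinverse least squares,
#' minimum-norm under rank deficiency), and assembles the full
#' [ConversionModel-class]. The stored per-patch RMSE compares each
#' patch's simulated spectrum, reconstructed from its corrected XYZ,
#' with its measured spectrum.
#'
#' @param basis [SpectralBasis-class] fitted on \code{reflectance}.
#' @param correction The [CorrectionModel-class] that produced
#'   \code{correctedXYZ}.
#' @param correctedXYZ n x 3 matrix of corrected patch XYZ.
#' @param reflectance n x 401 matrix of measured patch reflectances.
#' @param order Expansion order for M's features (default 2).
#' @param bandWindow Analysis window in nm, default c(415, 540).
#' @param modality "WLI" or "NBI".
#' @param clipReflectance Clip reconstructions to [0, 1] (default TRUE).
#' @param provenance Optional list carried into the model.
#' @return A [ConversionModel-class].
#' @export
fitTransformation <- function(basis, correction, correctedXYZ, reflectance,
                              order = 2L, bandWindow = c(415, 540),
                              modality = "WLI", clipReflectance = TRUE,
                              provenance = list()) {
  correctedXYZ <- rbind(correctedXYZ)
  reflectance <- rbind(reflectance)
  scores <- basisScores(basis, reflectance)          # n x k
  V <- t(expandFeatures(correctedXYZ, order))        # q x n
  if (qr(V)$rank < nrow(V))
    warning("rank-deficient variable matrix; returning the minimum-norm fit")
  M <- t(scores) %*% pracma::pinv(V)                 # k x q
  model <- new("ConversionModel", correction = correction, basis = basis,
               M = unname(M), order = as.integer(order),
               bandWindow = as.numeric(bandWindow), modality = modality,
               patchRMSE = numeric(nrow(reflectance)),
               clipReflectance = clipReflectance, provenance = provenance)
  sim <- .reconstructFromCorrected(model, correctedXYZ, clip = FALSE)
  model@patchRMSE <- sqrt(rowMeans((t(sim) - reflectance)^2))
  model
}

# reconstruction from already-corrected XYZ; returns 401 x n matrix
.reconstructFromCorrected <- function(model, correctedXYZ, clip) {
  feats <- expandFeatures(rbind(correctedXYZ), model@order)   # n x q
  scores <- feats %*% t(model@M)                              # n x k
  spec <- model@basis@mean + model@basis@components %*% t(scores)
  clippedFraction <- colMeans(spec < 0 | spec > 1)
  if (clip) spec <- pmin(pmax(spec, 0), 1)
  attr(spec, "clippedFraction") <- clippedFraction
  spec
}

#' Calibrate a full conversion model from a color checker
#'
#' Runs the complete calibration chain on a 24-patch checker: gamma decode
#' of the camera RGB, XYZ conversion (with optional chromatic adaptation),
#' pseudoinverse fit of the XYZ correction, PCA basis of the measured
#' reflectances, and the feature-to-score transformation. Separate models
#' are fitted per imaging modality.
#'
#' @param checker A [ColorChecker-class].
#' @param order Expansion order for both regressions (default 2).
#' @param k,varianceThreshold,maxK Passed to [fitSpectralBasis()].
#' @param adaptation 3x3 chromatic-adaptation matrix applied between the
#'   sRGB D65 space and the scene illuminant (default identity; the linear
#'   part of the correction absorbs any residual linear mismatch).
#' @param modality "WLI" or "NBI".
#' @param bandWindow Analysis window, default c(415, 540).
#' @param clipReflectance Clip reconstructed spectra to [0, 1].
#' @return A fitted [ConversionModel-class]. Slot \code{patchRMSE} holds
#'   the per-patch simulated-vs-measured spectrum RMSE; the correction's
#'   own per-patch XYZ RMSE sits in \code{correctionModel(model)@patchRMSE}.
#' @export
fitConversionModel <- function(checker, order = 2L, k = NULL,
                               varianceThreshold = 0.999, maxK = 12L,
                               adaptation = diag(3), modality = "WLI",
                               bandWindow = c(415, 540),
                               clipReflectance = TRUE) {
  cameraLinear <- gammaDecode(checker@cameraRGB)
  cameraXYZ <- linearRGBToXYZ(cameraLinear, adaptation)
  correction <- fitCorrection(checker@spectrometerXYZ, cameraXYZ, order)
  correctedXYZ <- applyCorrection(correction, cameraXYZ)
  basis <- fitSpectralBasis(checker@reflectance, k = k,
                            varianceThreshold = varianceThreshold, maxK = maxK)
  fitTransformation(basis, correction, correctedXYZ, checker@reflectance,
                    order = order, bandWindow = bandWindow,
                    modality = modality, clipReflectance = clipReflectance,
                    provenance = list(patches = nrow(checker@reflectance)))
}

#' @rdname reconstructSpectrum
#' @export
setMethod("reconstructSpectrum", "ConversionModel", function(model, xyz, clip = NULL) {
  clip <- if (is.null(clip)) model@clipReflectance else clip
  if (is.matrix(xyz)) {
    corrected <- applyCorrection(model@correction, xyz)
    return(.reconstructFromCorrected(model, corrected, clip))
  }
  corrected <- applyCorrection(model@correction, rbind(xyz))
  spec <- .reconstructFromCorrected(model, corrected, clip)
  out <- spectralCurve(pmin(pmax(spec[, 1], 0), 1))
  if (!clip) out <- spectralCurve(spec[, 1], kind = "radiance")
  attr(out, "clippedFraction") <- attr(spec, "clippedFraction")[1]
  out
})

#' @rdname model-accessors
#' @export
setMethod("correctionModel", "ConversionModel", function(x) x@correction)

#' @rdname model-accessors
#' @export
setMethod("spectralBasis", "ConversionModel", function(x) x@basis)

#' @rdname model-accessors
#' @export
setMethod("transformationMatrix", "ConversionModel", function(x) x@M)

#' @rdname model-accessors
#' @export
setMethod("bandWindow", "ConversionModel", function(x) x@bandWindow)

#' @rdname model-accessors
#' @export
setMethod("modality", "ConversionModel", function(x) x@modality)

setMethod("show", "ConversionModel", function(object) {
  cat("ConversionModel (", object@modality, ")\n", sep = "")
  cat("  expansion order:", object@order,
      " | PCA components:", ncol(object@basis@components), "\n")
  cat("  band window:", object@bandWindow[1], "-", object@bandWindow[2], "nm\n")
  cat("  mean patch spectrum RMSE:", signif(mean(object@patchRMSE), 4), "\n")
})

#' Serialize a conversion model to JSON
#'
#' Matrices are stored row-major with explicit dimensions, together with
#' the wavelength grid, expansion order, band window and provenance.
#'
#' @param model A [ConversionModel-class].
#' @param path Output JSON path.
#' @return The path, invisibly.
#' @export
writeConversionModel <- function(model, path) {
  ser <- function(m) list(dim = dim(m), data = as.numeric(t(m)))
  obj <- list(
    format = "endoHSI-conversion-model-1",
    modality = model@modality,
    order = model@order,
    bandWindow = model@bandWindow,
    clipReflectance = model@clipReflectance,
    wavelengths = hsiWavelengths(),
    correction = list(order = model@correction@order,
                      C = ser(model@correction@coefficients),
                      patchRMSE = model@correction@patchRMSE),
    basis = list(mean = model@basis@mean,
                 components = ser(model@basis@components),
                 explained = model@basis@explained),
    M = ser(model@M),
    patchRMSE = model@patchRMSE,
    provenance = model@provenance
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeConversionModel
#' @export
readConversionModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "endoHSI-conversion-model-1"))
    stop("not a conversion-model JSON file")
  des <- function(s) matrix(s$data, nrow = s$dim[1], byrow = TRUE)
  correction <- new("CorrectionModel", order = as.integer(obj$correction$order),
                    coefficients = des(obj$correction$C),
                    patchRMSE = as.numeric(obj$correction$patchRMSE))
  basis <- new("SpectralBasis", mean = as.numeric(obj$basis$mean),
               components = des(obj$basis$components),
               explained = as.numeric(obj$basis$explained))
  new("ConversionModel", correction = correction, basis = basis,
      M = des(obj$M), order = as.integer(obj$order),
      bandWindow = as.numeric(obj$bandWindow),
      modality = obj$modality, patchRMSE = as.numeric(obj$patchRMSE),
      clipReflectance = isTRUE(obj$clipReflectance),
      provenance = as.list(obj$provenance))
}
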