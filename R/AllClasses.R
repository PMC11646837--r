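#' @import methods
NULL

#' SpectralCurve: a spectrum on the standard visible grid
#'
#' A single spectrum sampled on the 380-780 nm, 1 nm grid (401 points).
#' `kind` distinguishes bounded reflectance curves from illuminant/radiance
#' curves in arbitrary units; reflectance values must lie in [0, 1].
#'
#' @slot wavelengths Numeric, the 401-point grid (strictly increasing).
#' @slot values Numeric, one value per wavelength.
#' @slot kind Character, one of "reflectance", "illuminant", "radiance".
#' @export
setClass("SpectralCurve",
  representation(wavelengths = "numeric", values = "numeric", kind = "character"),
  prototype(wavelengths = 380:780, values = rep(0, 401), kind = "reflectance")
)

# The full-grid (401-point) requirement is enforced by the spectralCurve()
# constructor; the class itself also represents band-sliced curves.
setValidity("SpectralCurve", function(object) {
  msgs <- character()
  if (length(object@values) != length(object@wavelengths))
    msgs <- c(msgs, "values and wavelengths lengths differ")
  if (any(diff(object@wavelengths) <= 0))
    msgs <- c(msgs, "wavelength grid must be strictly increasing")
  if (!object@kind %in% c("reflectance", "illuminant", "radiance"))
    msgs <- c(msgs, "kind must be reflectance, illuminant or radiance")
  if (any(!is.finite(object@values)))
    msgs <- c(msgs, "values must be finite")
  if (identical(object@kind, "reflectance") &&
      (any(object@values < -1e-9) || any(object@values > 1 + 1e-9)))
    msgs <- c(msgs, "reflectance values must lie in [0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' Construct a SpectralCurve
#'
#' @param values Numeric vector of 401 values on [hsiWavelengths()].
#' @param kind "reflectance" (bounded to [0,1]), "illuminant" or "radiance".
#' @param wavelengths Wavelength grid; defaults to the standard grid.
#' @return A [SpectralCurve-class] object.
#' @export
#' @examples
#' flat <- spectralCurve(rep(0.5, 401))
spectralCurve <- function(values, kind = "reflectance",
                          wavelengths = hsiWavelengths()) {
  if (length(wavelengths) != 401L)
    stop("a full SpectralCurve needs the 401-point 380-780 nm grid; ",
         "use bandSlice() to derive windowed curves")
  new("SpectralCurve", wavelengths = as.numeric(wavelengths),
      values = as.numeric(values), kind = kind)
}

#' ColorChecker: paired camera/spectrometer calibration target
#'
#' A 24-patch calibration set: encoded camera RGB per patch, the measured
#' reflectance spectrum per patch, and the spectrometer XYZ per patch
#' (illuminant-weighted tristimulus of the measured spectra).
#'
#' @slot patchId Character vector of 24 patch identifiers (row-major order).
#' @slot cameraRGB 24 x 3 matrix of encoded (gamma) RGB in [0, 1].
#' @slot reflectance 24 x 401 matrix of patch reflectances in [0, 1].
#' @slot spectrometerXYZ 24 x 3 matrix of XYZ values (Y scale 0-100).
#' @slot illuminant SpectralCurve used to weight the spectra.
#' @export
setClass("ColorChecker",
  representation(patchId = "character", cameraRGB = "matrix",
                 reflectance = "matrix", spectrometerXYZ = "matrix",
                 illuminant = "SpectralCurve")
)

setValidity("ColorChecker", function(object) {
  msgs <- character()
  if (length(object@patchId) != 24L) msgs <- c(msgs, "exactly 24 patches required")
  if (anyDuplicated(object@patchId)) msgs <- c(msgs, "patch ids must be unique")
  if (!all(dim(object@cameraRGB) == c(24L, 3L)))
    msgs <- c(msgs, "cameraRGB must be 24 x 3")
  if (!all(dim(object@reflectance) == c(24L, 401L)))
    msgs <- c(msgs, "reflectance must be 24 x 401")
  if (!all(dim(object@spectrometerXYZ) == c(24L, 3L)))
    msgs <- c(msgs, "spectrometerXYZ must be 24 x 3")
  if (any(object@reflectance < -1e-9 | object@reflectance > 1 + 1e-9))
    msgs <- c(msgs, "reflectances must lie in [0, 1]")
  if (any(object@cameraRGB < -1e-9 | object@cameraRGB > 1 + 1e-9))
    msgs <- c(msgs, "camera RGB must be normalized to [0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' CorrectionModel: polynomial XYZ correction
#'
#' Maps camera-derived XYZ to spectrometer XYZ through a fixed monomial
#' expansion and a 3 x p coefficient matrix fitted by pseudoinverse
#' regression on the 24 checker patches.
#'
#' @slot order Integer polynomial order of the expansion (1-3).
#' @slot C 3 x p coefficient matrix.
#' @slot patchRMSE Numeric per-patch residual RMSE on the training set.
#' @export
setClass("CorrectionModel",
  representation(order = "integer", coefficients = "matrix", patchRMSE = "numeric")
)

setValidity("CorrectionModel", function(object) {
  msgs <- character()
  if (!object@order %in% 1:3) msgs <- c(msgs, "expansion order must be 1, 2 or 3")
  if (nrow(object@coefficients) != 3L) msgs <- c(msgs, "C must have 3 rows")
  if (ncol(object@coefficients) != featureCount(object@order))
    msgs <- c(msgs, "C column count must match the expansion")
  if (any(!is.finite(object@coefficients))) msgs <- c(msgs, "C must be finite")
  if (length(msgs)) msgs else TRUE
})

#' SpectralBasis: mean + principal components of reflectance spectra
#'
#' @slot mean Numeric length-401 mean spectrum.
#' @slot components 401 x k orthonormal component matrix (decreasing variance).
#' @slot explained Numeric length-k explained-variance fractions.
#' @export
setClass("SpectralBasis",
  representation(mean = "numeric", components = "matrix", explained = "numeric")
)

setValidity("SpectralBasis", function(object) {
  msgs <- character()
  if (length(object@mean) != 401L) msgs <- c(msgs, "mean spectrum must have 401 values")
  if (nrow(object@components) != 401L) msgs <- c(msgs, "components must be 401 x k")
  k <- ncol(object@components)
  if (k < 1L) msgs <- c(msgs, "at least one component required")
  if (length(object@explained) != k)
    msgs <- c(msgs, "one explained-variance fraction per component")
  gram <- crossprod(object@components)
  if (max(abs(gram - diag(k))) > 1e-8)
    msgs <- c(msgs, "components must be orthonormal")
  if (sum(object@explained) > 1 + 1e-9)
    msgs <- c(msgs, "explained-variance fractions must sum to <= 1")
  if (length(msgs)) msgs else TRUE
})

#' ConversionModel: full RGB-to-spectrum conversion
#'
#' Bundles the XYZ correction, the PCA spectral basis, and the k x q
#' transformation matrix M mapping expanded corrected-XYZ features to PCA
#' scores, together with the analysis band window and provenance.
#'
#' @slot correction A [CorrectionModel-class].
#' @slot basis A [SpectralBasis-class].
#' @slot M k x q transformation matrix (features -> scores).
#' @slot order Integer expansion order used for M's features.
#' @slot bandWindow Numeric length-2, analysis window in nm.
#' @slot modality Character, "WLI" or "NBI".
#' @slot patchRMSE Per-patch simulated-vs-measured spectrum RMSE.
#' @slot clipReflectance Logical; clip reconstructions to [0, 1].
#' @slot provenance List (seed, config hash, notes).
#' @export
setClass("ConversionModel",
  representation(correction = "CorrectionModel", basis = "SpectralBasis",
                 M = "matrix", order = "integer", bandWindow = "numeric",
                 modality = "character", patchRMSE = "numeric",
                 clipReflectance = "logical", provenance = "list")
)

setValidity("ConversionModel", function(object) {
  msgs <- character()
  if (nrow(object@M) != ncol(object@basis@components))
    msgs <- c(msgs, "M rows must match basis component count")
  if (ncol(object@M) != featureCount(object@order))
    msgs <- c(msgs, "M column count must match the expansion")
  if (any(!is.finite(object@M))) msgs <- c(msgs, "M must be finite")
  bw <- object@bandWindow
  if (length(bw) != 2L || bw[1] >= bw[2] || bw[1] < 380 || bw[2] > 780)
    msgs <- c(msgs, "band window must satisfy 380 <= low < high <= 780")
  if (!object@modality %in% c("WLI", "NBI"))
    msgs <- c(msgs, "modality must be WLI or NBI")
  if (length(msgs)) msgs else TRUE
})

#' HyperspectralCube: per-pixel reconstructed reflectance
#'
#' An H x W x 401 reflectance array plus a mask of pixels whose
#' reconstruction failed (non-finite values or excessive clipping).
#'
#' @slot data H x W x 401 numeric array of reflectance in [0, 1].
#' @slot wavelengths Band grid (401 values, 380-780 nm).
#' @slot modality "WLI" or "NBI".
#' @slot mask H x W logical matrix, TRUE = masked (failed) pixel.
#' @slot provenance List: model id/hash, clipped-fraction stats, flags.
#' @export
setClass("HyperspectralCube",
  representation(data = "array", wavelengths = "numeric", modality = "character",
                 mask = "matrix", provenance = "list")
)

setValidity("HyperspectralCube", function(object) {
  msgs <- character()
  d <- dim(object@data)
  if (length(d) != 3L) msgs <- c(msgs, "data must be a 3-d array")
  else {
    if (d[3] != length(object@wavelengths))
      msgs <- c(msgs, "third dimension must match the band grid")
    if (!all(dim(object@mask) == d[1:2]))
      msgs <- c(msgs, "mask shape must match the image")
  }
  if (any(diff(object@wavelengths) <= 0))
    msgs <- c(msgs, "band grid must be strictly increasing")
  if (!object@modality %in% c("WLI", "NBI"))
    msgs <- c(msgs, "modality must be WLI or NBI")
  if (length(msgs)) msgs else TRUE
})
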