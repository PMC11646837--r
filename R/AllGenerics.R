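#' @rdname spectralValues
#' @export
setGeneric("spectralValues", function(x) standardGeneric("spectralValues"))

#' @rdname spectralValues
#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))

#' Reconstruct a reflectance spectrum from camera XYZ
#'
#' Applies the fitted XYZ correction, expands the corrected triplet into
#' monomial features, maps them to PCA scores through M, and rebuilds the
#' spectrum as mean + components x scores. When the model's
#' \code{clipReflectance} flag is set, the result is clipped to [0, 1] and
#' the clipped-band fraction is recorded in the returned curve's attributes.
#'
#' @param model A fitted [ConversionModel-class].
#' @param xyz Numeric XYZ triplet (Y scale 0-100), or a n x 3 matrix.
#' @param clip Override the model's clipping flag.
#' @return A [SpectralCurve-class] (or 401 x n matrix for matrix input,
#'   with attribute \code{clippedFraction}).
#' @export
setGeneric("reconstructSpectrum",
           function(model, xyz, clip = NULL) standardGeneric("reconstructSpectrum"))

#' Accessors for fitted conversion models
#'
#' \code{correctionModel}, \code{spectralBasis}, \code{transformationMatrix}
#' and \code{bandWindow} extract the corresponding pieces of a
#' [ConversionModel-class]; \code{modality} reports the imaging modality a
#' model or cube belongs to.
#'
#' @param x A ConversionModel or HyperspectralCube.
#' @name model-accessors
NULL

#' @rdname model-accessors
#' @export
setGeneric("correctionModel", function(x) standardGeneric("correctionModel"))

#' @rdname model-accessors
#' @export
setGeneric("spectralBasis", function(x) standardGeneric("spectralBasis"))

#' @rdname model-accessors
#' @export
setGeneric("transformationMatrix", function(x) standardGeneric("transformationMatrix"))

#' @rdname model-accessors
#' @export
setGeneric("bandWindow", function(x) standardGeneric("bandWindow"))

#' @rdname model-accessors
#' @export
setGeneric("modality", function(x) standardGeneric("modality"))

#' Accessors for hyperspectral cubes
#'
#' \code{cubeArray} returns the raw H x W x bands array, \code{cubeMask} the
#' logical mask of failed pixels, and \code{maskedPixelCount} their number.
#'
#' @param x A [HyperspectralCube-class].
#' @name cube-accessors
NULL

#' @rdname cube-accessors
#' @export
setGeneric("cubeArray", function(x) standardGeneric("cubeArray"))

#' @rdname cube-accessors
#' @export
setGeneric("cubeMask", function(x) standardGeneric("cubeMask"))

#' @rdname cube-accessors
#' @export
setGeneric("maskedPixelCount", function(x) standardGeneric("maskedPixelCount"))

#' Slice a cube (or curve) to a wavelength window
#'
#' Selects the bands whose wavelength lies inside the closed window.
#' The default window, 415-540 nm, is the analysis range in which the three
#' tissue classes separate most strongly; on the 1 nm grid it keeps 126 bands.
#'
#' @param x A [HyperspectralCube-class] or [SpectralCurve-class].
#' @param window Numeric length-2 (low, high) in nm, within 380-780.
#' @return Object of the same class restricted to the window.
#' @export
setGeneric("bandSlice", function(x, window = c(415, 540)) standardGeneric("bandSlice"))
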