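#' Convert an RGB image to a hyperspectral cube
#'
#' Applies the fitted conversion per pixel: gamma decode, XYZ conversion
#' (with the model-level adaptation folded into the fitted correction),
#' polynomial XYZ correction, and PCA-based spectral reconstruction. Pixels
#' whose reconstruction is non-finite, or whose clipped-band fraction
#' exceeds \code{maskThreshold}, are masked and counted; a frame with more
#' than \code{failThreshold} masked pixels is flagged failed in the cube's
#' provenance (conversions can fail on out-of-gamut content, which is why a
#' converted dataset may hold fewer usable frames than its RGB source).
#'
#' @param image H x W x 3 array of encoded RGB in [0, 1] (or 0-255 integers).
#' @param model A fitted [ConversionModel-class].
#' @param adaptation 3x3 chromatic-adaptation matrix (default identity).
#' @param maskThreshold Max tolerated fraction of clipped bands per pixel
#'   (default 0.5).
#' @param failThreshold Masked-pixel fraction above which the frame is
#'   flagged failed (default 0.2).
#' @return A [HyperspectralCube-class].
#' @export
convertImage <- function(image, model, adaptation = diag(3),
                         maskThreshold = 0.5, failThreshold = 0.2) {
  if (length(dim(image)) != 3L || dim(image)[3] != 3L)
    stop("image must be an H x W x 3 RGB array")
  if (max(image) > 1) image <- image / 255
  h <- dim(image)[1]; w <- dim(image)[2]
  px <- matrix(image, ncol = 3)                       # (h*w) x 3, column-major
  xyz <- linearRGBToXYZ(gammaDecode(px), adaptation)
  spec <- reconstructSpectrum(model, xyz)             # 401 x n
  clippedFraction <- attr(spec, "clippedFraction")
  bad <- !apply(is.finite(spec), 2, all) | clippedFraction > maskThreshold
  spec[, bad] <- NA_real_
  cube <- array(t(spec), dim = c(h, w, nrow(spec)))
  mask <- matrix(bad, h, w)
  failed <- mean(bad) > failThreshold
  new("HyperspectralCube", data = cube, wavelengths = hsiWavelengths(),
      modality = model@modality, mask = mask,
      provenance = list(maskedPixels = sum(bad),
                        maskedFraction = mean(bad),
                        meanClippedFraction = mean(clippedFraction),
                        frameFailed = failed,
                        modality = model@modality))
}

#' @rdname cube-accessors
#' @export
setMethod("cubeArray", "HyperspectralCube", function(x) x@data)

#' @rdname cube-accessors
#' @export
setMethod("cubeMask", "HyperspectralCube", function(x) x@mask)

#' @rdname cube-accessors
#' @export
setMethod("maskedPixelCount", "HyperspectralCube", function(x) sum(x@mask))

#' @rdname model-accessors
#' @export
setMethod("modality", "HyperspectralCube", function(x) x@modality)

setMethod("show", "HyperspectralCube", function(object) {
  d <- dim(object@data)
  cat("HyperspectralCube (", object@modality, "): ", d[1], " x ", d[2],
      " pixels, ", d[3], " bands (",
      min(object@wavelengths), "-", max(object@wavelengths), " nm)\n", sep = "")
  cat("  masked pixels:", sum(object@mask),
      if (isTRUE(object@provenance$frameFailed)) " [frame flagged failed]" else "",
      "\n")
})

#' @rdname bandSlice
#' @export
setMethod("bandSlice", "HyperspectralCube", function(x, window = c(415, 540)) {
  sel <- .bandSelect(x@wavelengths, window)
  new("HyperspectralCube", data = x@data[, , sel, drop = FALSE],
      wavelengths = x@wavelengths[sel], modality = x@modality,
      mask = x@mask, provenance = c(x@provenance, list(window = window)))
})

#' @rdname bandSlice
#' @export
setMethod("bandSlice", "SpectralCurve", function(x, window = c(415, 540)) {
  sel <- .bandSelect(x@wavelengths, window)
  out <- new("SpectralCurve", wavelengths = x@wavelengths[sel],
             values = x@values[sel], kind = x@kind)
  validObject(out, complete = FALSE)
  out
})

.bandSelect <- function(wl, window) {
  if (length(window) != 2L || window[1] >= window[2])
    stop("window must be (low, high) with low < high")
  if (window[1] < min(wl) || window[2] > max(wl))
    stop("window lies outside the band grid")
  which(wl >= window[1] & wl <= window[2])
}

#' Mean spectrum (and spread) over a pixel mask
#'
#' Per-band mean and standard deviation of the cube spectra over the
#' pixels selected by a logical mask; masked (failed) cube pixels are
#' excluded.
#'
#' @param cube A [HyperspectralCube-class].
#' @param mask H x W logical matrix with at least one TRUE pixel.
#' @return List with \code{mean} (a [SpectralCurve-class]), \code{sd}
#'   (numeric per band) and \code{pixels} (count used).
#' @export
regionSpectrum <- function(cube, mask) {
  if (!all(dim(mask) == dim(cube@data)[1:2]))
    stop("mask shape must match the cube")
  use <- mask & !cube@mask
  if (!any(use)) stop("empty mask: no usable pixels selected")
  flat <- matrix(cube@data, ncol = dim(cube@data)[3])
  sel <- flat[as.vector(use), , drop = FALSE]
  mu <- colMeans(sel)
  sdv <- if (nrow(sel) > 1) apply(sel, 2, stats::sd) else rep(0, ncol(sel))
  list(mean = new("SpectralCurve", wavelengths = cube@wavelengths,
                  values = pmin(pmax(mu, 0), 1), kind = "reflectance"),
       sd = sdv, pixels = nrow(sel))
}

#' Narrow-band rendering specification
#'
#' Two Gaussian passbands (center, FWHM) with a channel-mapping rule. The
#' defaults emulate narrow-band endoscopic illumination: a 415 nm band
#' (strong hemoglobin absorption, superficial capillaries) displayed on the
#' blue and green channels, and a 540 nm band (deeper vessels) on red.
#'
#' @param centers Band centers in nm (length 2).
#' @param fwhm Full widths at half maximum in nm (recycled, > 0).
#' @param mapping List: display channels fed by band 1 and band 2.
#' @return List of class \code{nbiBandSpec}.
#' @export
nbiBandSpec <- function(centers = c(415, 540), fwhm = c(30, 30),
                        mapping = list(band1 = c("B", "G"), band2 = "R")) {
  fwhm <- rep(fwhm, length.out = 2)
  if (any(fwhm <= 0)) stop("FWHM must be positive")
  wl <- hsiWavelengths()
  if (any(centers < min(wl) | centers > max(wl)))
    stop("passband centers must lie within the band grid")
  structure(list(centers = centers, fwhm = fwhm, mapping = mapping),
            class = "nbiBandSpec")
}

#' Render a simulated narrow-band image from a cube
#'
#' Integrates each pixel's reflectance against the two Gaussian passbands,
#' maps the band responses to display channels per the spec, normalizes the
#' image by its min-max range (so the rendering is invariant to cube-wide
#' scalar rescaling), and applies sRGB encoding. Masked pixels render black.
#'
#' @param cube A [HyperspectralCube-class].
#' @param spec An [nbiBandSpec()].
#' @return H x W x 3 array of encoded RGB in [0, 1].
#' @export
simulateNBI <- function(cube, spec = nbiBandSpec()) {
  wl <- cube@wavelengths
  weight <- function(center, fwhm) {
    w <- exp(-4 * log(2) * ((wl - center) / fwhm)^2)
    s <- sum(w)
    if (s <= 0) stop("degenerate passband: no overlap with the band grid")
    w / s
  }
  flat <- matrix(cube@data, ncol = length(wl))
  flat[!is.finite(flat)] <- 0
  r1 <- as.numeric(flat %*% weight(spec$centers[1], spec$fwhm[1]))
  r2 <- as.numeric(flat %*% weight(spec$centers[2], spec$fwhm[2]))
  h <- dim(cube@data)[1]; w <- dim(cube@data)[2]
  chan <- matrix(0, h * w, 3, dimnames = list(NULL, c("R", "G", "B")))
  for (ch in spec$mapping$band1) chan[, ch] <- r1
  for (ch in spec$mapping$band2) chan[, ch] <- r2
  lo <- min(chan); hi <- max(chan)
  # a spectrally flat image has no contrast to stretch; guard against
  # amplifying quadrature round-off into full-range noise
  norm <- if (hi - lo > 1e-9 * max(abs(hi), 1)) (chan - lo) / (hi - lo)
          else matrix(0.5, h * w, 3)
  norm[as.vector(cube@mask), ] <- 0
  array(gammaEncode(norm), dim = c(h, w, 3))
}

#' ENVI cube I/O
#'
#' Writes a cube as a band-sequential (BSQ) 32-bit float raw file with a
#' plain-text ENVI header carrying the band wavelengths;
#' \code{readENVI} reads the pair back. Masked pixels are stored as NaN.
#'
#' @param cube A [HyperspectralCube-class].
#' @param path Base path; \code{.hdr} and \code{.raw} are appended.
#' @return The base path (write) or a [HyperspectralCube-class] (read).
#' @export
writeENVI <- function(cube, path) {
  d <- dim(cube@data)
  hdr <- c("ENVI",
           "description = {endoHSI hyperspectral cube}",
           paste0("samples = ", d[2]),
           paste0("lines = ", d[1]),
           paste0("bands = ", d[3]),
           "header offset = 0", "file type = ENVI Standard",
           "data type = 4", "interleave = bsq", "byte order = 0",
           paste0("modality = ", cube@modality),
           paste0("wavelength units = Nanometers"),
           paste0("wavelength = {",
                  paste(cube@wavelengths, collapse = ", "), "}"))
  writeLines(hdr, paste0(path, ".hdr"))
  # BSQ: band-major, within band row-major (line by line)
  vals <- aperm(cube@data, c(2, 1, 3))
  con <- file(paste0(path, ".raw"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(vals), con, size = 4, endian = "little")
  invisible(path)
}

#' @rdname writeENVI
#' @export
readENVI <- function(path) {
  hdr <- readLines(paste0(path, ".hdr"))
  getNum <- function(key) as.integer(sub(paste0(key, " = "), "",
                                         grep(paste0("^", key, " ="), hdr, value = TRUE)))
  samples <- getNum("samples"); lines <- getNum("lines"); bands <- getNum("bands")
  modality <- sub("modality = ", "", grep("^modality =", hdr, value = TRUE))
  if (!length(modality)) modality <- "WLI"
  wlLine <- grep("^wavelength = ", hdr, value = TRUE)
  wl <- as.numeric(strsplit(gsub("wavelength = \\{|\\}", "", wlLine), ",")[[1]])
  n <- samples * lines * bands
  con <- file(paste0(path, ".raw"), "rb")
  on.exit(close(con))
  vals <- readBin(con, "numeric", n = n, size = 4, endian = "little")
  cube <- aperm(array(vals, dim = c(samples, lines, bands)), c(2, 1, 3))
  mask <- !apply(is.finite(cube), c(1, 2), all)
  cube[!is.finite(cube)] <- NA_real_
  new("HyperspectralCube", data = cube, wavelengths = wl, modality = modality,
      mask = mask, provenance = list(maskedPixels = sum(mask), source = path))
}

#' PNG image I/O helpers
#'
#' Thin wrappers over the png package: \code{readImagePNG} returns an
#' H x W x 3 encoded-RGB array in [0, 1] (alpha dropped, gray expanded);
#' \code{writeImagePNG} writes such an array.
#'
#' @param path PNG file path.
#' @return Array (read) or the path invisibly (write).
#' @export
readImagePNG <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), dim = c(dim(img), 3))
  img[, , 1:3, drop = FALSE]
}

#' @rdname readImagePNG
#' @param image H x W x 3 array in [0, 1].
#' @export
writeImagePNG <- function(image, path) {
  png::writePNG(pmin(pmax(image, 0), 1), path)
  invisible(path)
}
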