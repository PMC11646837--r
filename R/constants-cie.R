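#' Standard visible-band wavelength grid
#'
#' The package works on a fixed 401-point grid, 380-780 nm at 1 nm steps.
#' Every spectral object, fitted basis and hyperspectral cube uses this grid.
#'
#' @return Integer vector of 401 wavelengths in nanometres.
#' @export
#' @examples
#' length(hsiWavelengths())  # 401
hsiWavelengths <- function() 380:780

# piecewise-sigma Gaussian lobe used by the analytic CMF representation
.cmfLobe <- function(wl, amp, mu, s1, s2) {
  s <- ifelse(wl < mu, s1, s2)
  amp * exp(-0.5 * ((wl - mu) / s)^2)
}

.cmfCache <- new.env(parent = emptyenv())

#' CIE 1931 2-degree color-matching functions
#'
#' Returns the observer curves xbar, ybar, zbar sampled on the package grid.
#' The curves are generated from the published multi-lobe Gaussian analytic
#' representation of the 1931 2-degree observer, so no external table is
#' needed at run time. All values are non-negative and ybar peaks near 555 nm.
#'
#' @return A 401 x 3 numeric matrix with columns \code{xbar}, \code{ybar},
#'   \code{zbar} on the grid of [hsiWavelengths()].
#' @export
cieCMF <- function() {
  if (!is.null(.cmfCache$cmf)) return(.cmfCache$cmf)
  wl <- hsiWavelengths()
  xbar <- .cmfLobe(wl, 0.362, 442.0, 16.0, 26.7) +
    .cmfLobe(wl, 1.056, 599.8, 37.9, 31.0) +
    .cmfLobe(wl, -0.065, 501.1, 20.4, 26.2)
  ybar <- .cmfLobe(wl, 0.821, 568.8, 46.9, 40.5) +
    .cmfLobe(wl, 0.286, 530.9, 16.3, 31.1)
  zbar <- .cmfLobe(wl, 1.217, 437.0, 11.8, 36.0) +
    .cmfLobe(wl, 0.681, 459.0, 26.0, 13.8)
  cmf <- cbind(xbar = pmax(xbar, 0), ybar = pmax(ybar, 0), zbar = pmax(zbar, 0))
  rownames(cmf) <- as.character(wl)
  .cmfCache$cmf <- cmf
  cmf
}

#' Export the embedded observer tables to CSV
#'
#' Writes the embedded color-matching functions to a CSV file
#' (columns \code{wavelength_nm,xbar,ybar,zbar}) for audit.
#'
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
writeCMFTables <- function(path) {
  cmf <- cieCMF()
  df <- data.frame(wavelength_nm = hsiWavelengths(), cmf)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' sRGB (D65) primaries matrix
#'
#' The standard 3x3 matrix taking linear sRGB to XYZ (Y of white = 1).
#'
#' @return 3x3 numeric matrix.
#' @export
srgbToXYZMatrix <- function() {
  matrix(c(
    0.4124564, 0.3575761, 0.1804375,
    0.2126729, 0.7151522, 0.0721750,
    0.0193339, 0.1191920, 0.9503041
  ), nrow = 3, byrow = TRUE,
  dimnames = list(c("X", "Y", "Z"), c("R", "G", "B")))
}

# Bradford cone-response matrix
.bradfordMatrix <- function() {
  matrix(c(
    0.8951, 0.2664, -0.1614,
    -0.7502, 1.7135, 0.0367,
    0.0389, -0.0685, 1.0296
  ), nrow = 3, byrow = TRUE)
}

#' Reference white points
#'
#' `whitePointD65()` is the standard D65 white of the sRGB space;
#' `whitePointE()` is the equal-energy white. Both are on the Y = 100 scale.
#'
#' @return Named numeric vector (X, Y, Z).
#' @export
whitePointD65 <- function() c(X = 95.047, Y = 100, Z = 108.883)

#' @rdname whitePointD65
#' @export
whitePointE <- function() c(X = 100, Y = 100, Z = 100)
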