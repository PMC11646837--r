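#' Spectrum accessors
#'
#' \code{spectralValues} returns the sampled values of a curve and
#' \code{wavelengths} its grid.
#'
#' @param x A [SpectralCurve-class] or [HyperspectralCube-class].
#' @return Numeric vector.
#' @name spectralValues
NULL

#' @rdname spectralValues
#' @export
setMethod("spectralValues", "SpectralCurve", function(x) x@values)

#' @rdname spectralValues
#' @export
setMethod("wavelengths", "SpectralCurve", function(x) x@wavelengths)

#' @rdname spectralValues
#' @export
setMethod("wavelengths", "HyperspectralCube", function(x) x@wavelengths)

setMethod("show", "SpectralCurve", function(object) {
  cat("SpectralCurve (", object@kind, "), ",
      length(object@wavelengths), " bands ",
      min(object@wavelengths), "-", max(object@wavelengths), " nm, range [",
      signif(min(object@values), 4), ", ", signif(max(object@values), 4),
      "]\n", sep = "")
})

#' sRGB transfer function
#'
#' `gammaDecode` inverts the standard sRGB encoding (linear segment below
#' the 0.04045 threshold, exponent 2.4 above); `gammaEncode` is its inverse.
#' Both operate componentwise on values in [0, 1].
#'
#' @param x Numeric in [0, 1] (vector, matrix or array).
#' @return Numeric of the same shape.
#' @export
#' @examples
#' gammaDecode(128 / 255)  # 0.21586
gammaDecode <- function(x) {
  if (any(x < 0 | x > 1, na.rm = TRUE))
    stop("encoded sRGB values must lie in [0, 1]")
  ifelse(x <= 0.04045, x / 12.92, ((x + 0.055) / 1.055)^2.4)
}

#' @rdname gammaDecode
#' @export
gammaEncode <- function(x) {
  if (any(x < 0 | x > 1, na.rm = TRUE))
    stop("linear values must lie in [0, 1]")
  ifelse(x <= 0.0031308, 12.92 * x, 1.055 * x^(1 / 2.4) - 0.055)
}

#' Linear RGB to XYZ
#'
#' XYZ = MA . T . rgb x 100, with T the sRGB (D65) primaries matrix and MA
#' an optional chromatic-adaptation matrix (identity by default). The
#' resulting Y is on the 0-100 luminance scale, so sRGB white maps to
#' (95.047, 100, 108.883) under identity adaptation.
#'
#' @param rgb Linear RGB triplet in [0, 1], or an n x 3 matrix.
#' @param adaptation 3x3 adaptation matrix, default identity.
#' @return Named XYZ triplet, or n x 3 matrix.
#' @export
linearRGBToXYZ <- function(rgb, adaptation = diag(3)) {
  m <- adaptation %*% srgbToXYZMatrix()
  if (is.matrix(rgb)) {
    out <- rgb %*% t(m) * 100
    colnames(out) <- c("X", "Y", "Z")
    return(out)
  }
  out <- as.numeric(m %*% rgb) * 100
  names(out) <- c("X", "Y", "Z")
  out
}

#' Chromatic-adaptation matrix between two white points
#'
#' Bradford-type von Kries adaptation: both whites are mapped into cone
#' space, scaled componentwise, and mapped back. The returned matrix sends
#' the source white exactly onto the destination white.
#'
#' @param sourceWhite,destWhite XYZ triplets with positive components.
#' @return 3x3 adaptation matrix.
#' @export
adaptationMatrix <- function(sourceWhite, destWhite) {
  if (any(sourceWhite <= 0) || any(destWhite <= 0))
    stop("white points must have strictly positive components")
  B <- .bradfordMatrix()
  coneS <- as.numeric(B %*% sourceWhite)
  coneD <- as.numeric(B %*% destWhite)
  solve(B) %*% diag(coneD / coneS) %*% B
}

#' Tristimulus integration of an illuminated reflectance
#'
#' Computes XYZ from an illuminant S and reflectance R by quadrature of
#' S(l) R(l) against the observer curves, with the luminance normalization
#' k = 100 / sum(S ybar) so that a perfect reflector has Y = 100 under any
#' illuminant. A rectangle rule at the 1 nm grid step is used; the step
#' cancels between numerator and k, so the result is step-invariant.
#'
#' @param S Illuminant [SpectralCurve-class] (or length-401 numeric).
#' @param R Reflectance [SpectralCurve-class] (or length-401 numeric).
#' @param cmf 401 x 3 observer matrix, default [cieCMF()].
#' @return Named XYZ triplet.
#' @export
spectrumToXYZ <- function(S, R, cmf = cieCMF()) {
  s <- if (is(S, "SpectralCurve")) S@values else as.numeric(S)
  r <- if (is(R, "SpectralCurve")) R@values else as.numeric(R)
  if (length(s) != nrow(cmf) || length(r) != nrow(cmf))
    stop("spectra must be sampled on the standard 401-point grid")
  denom <- sum(s * cmf[, "ybar"])
  if (denom <= 0) stop("degenerate illuminant: no overlap with ybar")
  k <- 100 / denom
  c(X = k * sum(s * r * cmf[, "xbar"]),
    Y = k * sum(s * r * cmf[, "ybar"]),
    Z = k * sum(s * r * cmf[, "zbar"]))
}

#' XYZ to CIELAB
#'
#' @param xyz XYZ triplet (Y scale 0-100) or n x 3 matrix.
#' @param white Reference white, default D65.
#' @return Named Lab triplet or n x 3 matrix.
#' @export
xyzToLab <- function(xyz, white = whitePointD65()) {
  if (any(white <= 0)) stop("white point components must be positive")
  f <- function(t) ifelse(t > (6 / 29)^3, t^(1 / 3), t / (3 * (6 / 29)^2) + 4 / 29)
  if (is.matrix(xyz)) {
    fx <- f(xyz[, 1] / white[1]); fy <- f(xyz[, 2] / white[2]); fz <- f(xyz[, 3] / white[3])
    out <- cbind(L = 116 * fy - 16, a = 500 * (fx - fy), b = 200 * (fy - fz))
    return(out)
  }
  fx <- f(xyz[1] / white[1]); fy <- f(xyz[2] / white[2]); fz <- f(xyz[3] / white[3])
  c(L = 116 * fy - 16, a = 500 * (fx - fy), b = 200 * (fy - fz))
}

#' CIE76 color difference between two Lab triplets
#'
#' @param lab1,lab2 Lab triplets.
#' @return Non-negative scalar.
#' @export
deltaE76 <- function(lab1, lab2) unname(sqrt(sum((lab1 - lab2)^2)))

#' CIEDE2000 color difference between two Lab triplets
#'
#' Full CIEDE2000 formula with unit weighting factors (kL = kC = kH = 1).
#'
#' @param lab1,lab2 Lab triplets.
#' @return Non-negative scalar.
#' @export
deltaE2000 <- function(lab1, lab2) {
  L1 <- lab1[1]; a1 <- lab1[2]; b1 <- lab1[3]
  L2 <- lab2[1]; a2 <- lab2[2]; b2 <- lab2[3]
  C1 <- sqrt(a1^2 + b1^2); C2 <- sqrt(a2^2 + b2^2)
  Cbar <- (C1 + C2) / 2
  G <- 0.5 * (1 - sqrt(Cbar^7 / (Cbar^7 + 25^7)))
  a1p <- (1 + G) * a1; a2p <- (1 + G) * a2
  C1p <- sqrt(a1p^2 + b1^2); C2p <- sqrt(a2p^2 + b2^2)
  h1p <- if (C1p == 0) 0 else (atan2(b1, a1p) * 180 / pi) %% 360
  h2p <- if (C2p == 0) 0 else (atan2(b2, a2p) * 180 / pi) %% 360
  dLp <- L2 - L1
  dCp <- C2p - C1p
  dhp <- if (C1p * C2p == 0) 0 else {
    d <- h2p - h1p
    if (abs(d) <= 180) d else if (d > 180) d - 360 else d + 360
  }
  dHp <- 2 * sqrt(C1p * C2p) * sin(dhp * pi / 360)
  Lbp <- (L1 + L2) / 2
  Cbp <- (C1p + C2p) / 2
  hbp <- if (C1p * C2p == 0) h1p + h2p else {
    d <- abs(h1p - h2p); s <- h1p + h2p
    if (d <= 180) s / 2 else if (s < 360) (s + 360) / 2 else (s - 360) / 2
  }
  Tt <- 1 - 0.17 * cos((hbp - 30) * pi / 180) + 0.24 * cos(2 * hbp * pi / 180) +
    0.32 * cos((3 * hbp + 6) * pi / 180) - 0.20 * cos((4 * hbp - 63) * pi / 180)
  dTheta <- 30 * exp(-((hbp - 275) / 25)^2)
  RC <- 2 * sqrt(Cbp^7 / (Cbp^7 + 25^7))
  SL <- 1 + 0.015 * (Lbp - 50)^2 / sqrt(20 + (Lbp - 50)^2)
  SC <- 1 + 0.045 * Cbp
  SH <- 1 + 0.015 * Cbp * Tt
  RT <- -sin(2 * dTheta * pi / 180) * RC
  unname(sqrt((dLp / SL)^2 + (dCp / SC)^2 + (dHp / SH)^2 +
                RT * (dCp / SC) * (dHp / SH)))
}

#' Color difference between two XYZ triplets
#'
#' Converts both triplets to CIELAB under the supplied white point, then
#' applies CIEDE2000 (default) or CIE76.
#'
#' @param a,b XYZ triplets.
#' @param white Reference white point.
#' @param method "ciede2000" or "cie76".
#' @return Non-negative scalar.
#' @export
colorDifference <- function(a, b, white = whitePointD65(),
                            method = c("ciede2000", "cie76")) {
  method <- match.arg(method)
  la <- xyzToLab(a, white); lb <- xyzToLab(b, white)
  if (method == "cie76") deltaE76(la, lb) else deltaE2000(la, lb)
}

#' Read/write a spectrum CSV
#'
#' Two-column CSV with header \code{wavelength_nm,value}; the grid is
#' validated against the standard 401-point grid on read.
#'
#' @param path CSV path.
#' @param kind Curve kind for the returned object.
#' @return [SpectralCurve-class] (read) or the path invisibly (write).
#' @export
readSpectrumCSV <- function(path, kind = "reflectance") {
  df <- utils::read.csv(path)
  if (!all(c("wavelength_nm", "value") %in% names(df)))
    stop("spectrum CSV must have columns wavelength_nm,value")
  if (!isTRUE(all.equal(as.numeric(df$wavelength_nm), as.numeric(hsiWavelengths()))))
    stop("spectrum grid must be 380-780 nm at 1 nm steps")
  spectralCurve(df$value, kind = kind)
}

#' @rdname readSpectrumCSV
#' @param curve A [SpectralCurve-class] to write.
#' @export
writeSpectrumCSV <- function(curve, path) {
  utils::write.csv(
    data.frame(wavelength_nm = curve@wavelengths, value = curve@values),
    path, row.names = FALSE)
  invisible(path)
}
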