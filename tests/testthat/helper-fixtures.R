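# shared fixture builders and independent oracles

box <- function(x_min, y_min, x_max, y_max) {
  c(x_min = x_min, y_min = y_min, x_max = x_max, y_max = y_max)
}

# brute-force IoU by rasterizing integer-coordinate boxes on a unit grid;
# exact for integer corners, fully independent of the analytic formula
rasterIoU <- function(a, b) {
  xs <- max(a["x_max"], b["x_max"])
  ys <- max(a["y_max"], b["y_max"])
  inBox <- function(bx, cx, cy) {
    cx >= bx["x_min"] & cx < bx["x_max"] & cy >= bx["y_min"] & cy < bx["y_max"]
  }
  cx <- rep(seq(0.5, xs - 0.5), times = ys)
  cy <- rep(seq(0.5, ys - 0.5), each = xs)
  ina <- inBox(a, cx, cy); inb <- inBox(b, cx, cy)
  sum(ina & inb) / sum(ina | inb)
}

randomIntBox <- function(maxCoord = 40) {
  x <- sort(sample.int(maxCoord + 1, 2) - 1)
  y <- sort(sample.int(maxCoord + 1, 2) - 1)
  while (x[1] == x[2]) x <- sort(sample.int(maxCoord + 1, 2) - 1)
  while (y[1] == y[2]) y <- sort(sample.int(maxCoord + 1, 2) - 1)
  box(x[1], y[1], x[2], y[2])
}

# normal-equations least squares, the independent check for pinv fits
lsqOracle <- function(targets, design) {
  # targets n x 3, design n x p; returns 3 x p coefficient matrix
  t(solve(crossprod(design), crossprod(design, targets)))
}

# smooth random spectra of unconstrained shape (full-rank family), for
# PCA tests that must not rely on the 3-component generator family
randomSmoothSpectra <- function(n, seed) {
  set.seed(seed)
  wl <- hsiWavelengths()
  t(vapply(seq_len(n), function(i) {
    v <- rep(stats::runif(1, 0.1, 0.5), length(wl))
    for (j in 1:5) {
      v <- v + stats::runif(1, -0.1, 0.1) *
        exp(-((wl - stats::runif(1, 380, 780)) / stats::runif(1, 30, 150))^2)
    }
    pmin(pmax(v, 0), 1)
  }, numeric(length(wl))))
}

noiselessModel <- function(seed = 7, ...) {
  ck <- makeColorChecker(seed)
  list(checker = ck, model = fitConversionModel(ck, ...))
}

cameraXYZOf <- function(checker) {
  linearRGBToXYZ(gammaDecode(checker@cameraRGB))
}
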