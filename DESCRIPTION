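Package: endoHSI
Title: Visible-Band Hyperspectral Conversion and Evaluation for Endoscopic Imaging
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Reconstructs 401-band visible-range reflectance spectra (380-780 nm)
    from ordinary RGB endoscopic images via 24-patch color-checker calibration:
    sRGB linearization, XYZ conversion with chromatic adaptation, polynomial
    XYZ correction fitted by pseudoinverse regression, and a PCA spectral basis
    with a learned XYZ-to-score transformation. Provides per-pixel cube
    conversion, 415-540 nm band analysis, simulated narrow-band-imaging
    rendering, frame-level detection/classification evaluation (IoU matching,
    confusion matrices, sensitivity/specificity/precision/F1/accuracy, Cohen's
    kappa), a composite detection loss with scale-dependent objectness gain,
    and seeded synthetic-data generators for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    pracma,
    png
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
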