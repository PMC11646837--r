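# FNV-1a hash of a character string, hex encoded; used for config provenance.
# Kept in doubles (exact below 2^53); xor with a byte only touches the low
# 8 bits, so it is done there to stay inside R's 32-bit bitwXor range.
.fnv1a <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h <- 2166136261
  for (b in bytes) {
    h <- (h %/% 256) * 256 + bitwXor(h %% 256, b)
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

.pipelineDefaults <- function() list(
  seed = 1L,
  modality = "WLI",
  expansionOrder = 2L,
  pcaVarianceThreshold = 0.999,
  pcaMaxK = 12L,
  bandWindow = c(415, 540),
  nbiCenters = c(415, 540),
  nbiFwhm = c(30, 30),
  iouThreshold = 0.5,
  noiseSigma = 0,
  sceneSize = 24L,
  nFrames = 40L,
  sensitivity = 0.85,
  fpRate = 0.08,
  outputDir = ".",
  stages = c("synth", "calibrate", "convert", "simulate-nbi", "evaluate")
)

#' Validate a pipeline configuration
#'
#' Fills defaults and rejects unknown keys (schema validation). The
#' configuration drives [runPipeline()]; all randomness downstream is
#' funneled through its single \code{seed}.
#'
#' @param config Named list of settings (possibly partial).
#' @return Completed config list with a \code{configHash} attribute.
#' @export
pipelineConfig <- function(config = list()) {
  defaults <- .pipelineDefaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)
  if (!cfg$modality %in% c("WLI", "NBI")) stop("modality must be WLI or NBI")
  bad <- setdiff(cfg$stages, .pipelineDefaults()$stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  # hash the scientific settings only, so identical analyses written to
  # different directories carry the same provenance hash
  hashed <- cfg[setdiff(names(cfg), "outputDir")]
  attr(cfg, "configHash") <- .fnv1a(jsonlite::toJSON(hashed, auto_unbox = TRUE))
  cfg
}

#' @rdname pipelineConfig
#' @param path JSON config file.
#' @export
readPipelineConfig <- function(path) {
  pipelineConfig(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' Run the synthetic calibration-conversion-evaluation pipeline
#'
#' Orchestrates the stages end to end on seeded synthetic data:
#' generate a color checker, lesion scene and detector outputs
#' (\code{synth}), fit the conversion model (\code{calibrate}), convert
#' the scene to a hyperspectral cube (\code{convert}), render the
#' simulated narrow-band image (\code{simulate-nbi}) and evaluate the
#' detector outputs (\code{evaluate}). Every artifact is written under
#' \code{outputDir} with the config hash embedded; rerunning with an
#' unchanged config reproduces identical outputs.
#'
#' @param config A [pipelineConfig()] (or plain list passed through it).
#' @return Invisible list of stage results (model, cube, nbi image,
#'   evaluation, timings, paths).
#' @export
runPipeline <- function(config = list()) {
  cfg <- if (is.null(attr(config, "configHash"))) pipelineConfig(config) else config
  hash <- attr(cfg, "configHash")
  dir.create(cfg$outputDir, showWarnings = FALSE, recursive = TRUE)
  out <- list(configHash = hash)
  timings <- c()
  tic <- function() proc.time()[["elapsed"]]
  logStage <- function(stage, t0)
    message(sprintf("[endoHSI] stage=%s elapsed=%.2fs hash=%s", stage, tic() - t0, hash))

  illum <- makeIlluminant(if (cfg$modality == "NBI") "dual-narrowband" else "broadband")
  camera <- syntheticCamera(noiseSigma = cfg$noiseSigma)

  if ("synth" %in% cfg$stages) {
    t0 <- tic()
    out$checker <- makeColorChecker(cfg$seed, camera, illum)
    lesions <- data.frame(class = c("dysplasia", "SCC"),
                          cx = c(cfg$sceneSize * 0.3, cfg$sceneSize * 0.7),
                          cy = c(cfg$sceneSize * 0.35, cfg$sceneSize * 0.65),
                          rx = c(cfg$sceneSize * 0.15, cfg$sceneSize * 0.18),
                          ry = c(cfg$sceneSize * 0.12, cfg$sceneSize * 0.15))
    out$scene <- makeScene(cfg$sceneSize, cfg$sceneSize, lesions,
                           camera = camera, illuminant = illum,
                           seed = cfg$seed)
    writeImagePNG(out$scene$image, file.path(cfg$outputDir, "scene.png"))
    truthRecords <- .sceneFrameSet(out$scene, cfg)
    out$records <- makeDetections(truthRecords, sensitivity = cfg$sensitivity,
                                  fpRate = cfg$fpRate, seed = cfg$seed)
    logStage("synth", t0); timings["synth"] <- tic() - t0
  }
  if ("calibrate" %in% cfg$stages) {
    t0 <- tic()
    if (is.null(out$checker)) stop("stage calibrate: no checker (run synth or supply one)")
    out$model <- fitConversionModel(out$checker, order = cfg$expansionOrder,
                                    varianceThreshold = cfg$pcaVarianceThreshold,
                                    maxK = cfg$pcaMaxK, modality = cfg$modality,
                                    bandWindow = cfg$bandWindow)
    out$model@provenance$configHash <- hash
    out$model@provenance$seed <- cfg$seed
    writeConversionModel(out$model, file.path(cfg$outputDir, "model.json"))
    logStage("calibrate", t0); timings["calibrate"] <- tic() - t0
  }
  if ("convert" %in% cfg$stages) {
    t0 <- tic()
    if (is.null(out$model)) stop("stage convert: no fitted model")
    out$cube <- convertImage(out$scene$image, out$model)
    out$cube@provenance$configHash <- hash
    writeENVI(out$cube, file.path(cfg$outputDir, "cube"))
    logStage("convert", t0); timings["convert"] <- tic() - t0
  }
  if ("simulate-nbi" %in% cfg$stages) {
    t0 <- tic()
    if (is.null(out$cube)) stop("stage simulate-nbi: no cube")
    spec <- nbiBandSpec(cfg$nbiCenters, cfg$nbiFwhm)
    out$nbi <- simulateNBI(out$cube, spec)
    writeImagePNG(out$nbi, file.path(cfg$outputDir, "nbi.png"))
    logStage("simulate-nbi", t0); timings["simulate-nbi"] <- tic() - t0
  }
  if ("evaluate" %in% cfg$stages) {
    t0 <- tic()
    if (is.null(out$records)) stop("stage evaluate: no frame records")
    out$evaluation <- evaluateDataset(out$records, cfg$iouThreshold)
    writeMetricsReport(out$evaluation, file.path(cfg$outputDir, "report.json"))
    logStage("evaluate", t0); timings["evaluate"] <- tic() - t0
  }
  out$timings <- timings
  invisible(out)
}

# replicate the synthetic scene's truth across a small frame set:
# half neoplasm frames (scene truth), half normal frames
.sceneFrameSet <- function(scene, cfg) {
  n <- cfg$nFrames
  lapply(seq_len(n), function(i) {
    if (i <= n / 2)
      frameRecord(sprintf("neoplasm%03d", i), truth = scene$truth,
                  modality = cfg$modality)
    else
      frameRecord(sprintf("normal%03d", i), modality = cfg$modality)
  })
}
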