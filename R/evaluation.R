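#' @include phantom.R detection.R correction.R baseline.R
NULL

#' Root-mean-square error between two images
#'
#' @param a,b [ImageGrid-class] objects (or matrices) of equal shape.
#' @param roi an [ArtifactMask-class]/logical matrix restricting the
#'   comparison, or `"all"` (default) for the whole image; must be
#'   nonempty.
#' @return The RMS difference over the ROI pixels.
#' @export
rmse <- function(a, b, roi = "all") {
  pa <- if (is(a, "ImageGrid")) a@pixels else a
  pb <- if (is(b, "ImageGrid")) b@pixels else b
  if (!all(dim(pa) == dim(pb))) stop("shape mismatch")
  if (identical(roi, "all")) {
    d <- pa - pb
  } else {
    rf <- if (is(roi, "ArtifactMask")) roi@flags else roi
    if (!all(dim(rf) == dim(pa))) stop("ROI shape mismatch")
    if (!any(rf)) stop("empty ROI")
    d <- (pa - pb)[rf]
  }
  sqrt(mean(d^2))
}

.mean_abs <- function(a, b) mean(abs(a@pixels - b@pixels))

#' Run the simulation study comparing MAR methods
#'
#' For every (implant count, seed) condition: builds the head phantom,
#' inserts a seeded implant layout, simulates the corrupted acquisition and
#' the paired pseudo-MR, and scores three reconstructions — `uncorrected`
#' (the streaky image), `li` (sinogram linear interpolation given the true
#' metal mask) and `proposed` (Otsu detection + MR-guided correction) —
#' against the clean FBP round trip, so reconstruction discretization error
#' is not charged to any MAR method. With zero implants there is nothing to
#' correct and all three methods report the identical uncorrected image.
#'
#' The artifact ROI is the detected artifact mask minus true metal (the
#' same ROI for all methods of a condition); metal pixels are excluded
#' because no method is asked to invent metal values.
#'
#' @param spec a [PhantomSpec-class], default [headPhantomSpec()].
#' @param implantCounts integer vector of implant counts, default `1:3`.
#' @param seeds integer vector of seeds, default `0:4`.
#' @param detCfg,corCfg,phys,mrCfg module configurations (seeds inside
#'   `phys`/`mrCfg` are replaced by the per-condition seed).
#' @param geom acquisition [Geometry-class], default [geometryFor()] of the
#'   phantom grid.
#' @param radiusRange implant radius range in px, default `c(2, 4)`.
#' @param collectImages keep per-condition image triplets for
#'   [renderGrid()].
#' @return An [EvaluationReport-class].
#' @export
runStudy <- function(spec = headPhantomSpec(), implantCounts = 1:3,
                     seeds = 0:4, detCfg = detectionConfig(),
                     corCfg = correctionConfig(), phys = physicsConfig(),
                     mrCfg = mrSynthesisConfig(), geom = NULL,
                     radiusRange = c(2, 4), collectImages = FALSE) {
  clean <- makePhantom(spec)
  if (is.null(geom)) geom <- geometryFor(clean)
  clean_rt <- fbpReconstruct(forwardProject(clean, geom), dim(clean),
                             pixelSpacing = clean@spacing[1])
  body <- .body_support(.normalize01(clean_rt@pixels), detCfg@bodyThreshold)
  rows <- list(); images <- list()
  for (count in implantCounts) {
    for (seed in seeds) {
      imp <- sampleImplantSpec(spec, count, seed = seed,
                               radiusRange = radiusRange)
      ins <- insertImplants(clean, imp)
      physSeed <- physicsConfig(saturationCap = phys@saturationCap,
                                beamHardeningGamma = phys@beamHardeningGamma,
                                noisePhotons = phys@noisePhotons,
                                traceThreshold = phys@traceThreshold,
                                muPerUnit = phys@muPerUnit,
                                randomSeed = seed)
      sim <- simulateArtifactCT(ins$ct, ins$mask, geom, physSeed)
      if (count == 0L || !any(ins$mask@flags)) {
        outs <- list(uncorrected = sim$ct, li = sim$ct, proposed = sim$ct)
        roi <- NULL
      } else {
        mrSeed <- new("MRSynthesisConfig", ctLevels = mrCfg@ctLevels,
                      mrLevels = mrCfg@mrLevels, voidRadius = mrCfg@voidRadius,
                      smoothSigma = mrCfg@smoothSigma,
                      noiseSigma = mrCfg@noiseSigma, shift = mrCfg@shift,
                      randomSeed = as.integer(seed))
        mr <- synthesizeMR(clean, ins$mask, mrSeed)
        detected <- detectArtifacts(sim$ct, detCfg)
        corrected <- correctImage(sim$ct, mr, detected, corCfg,
                                  metalMask = ins$mask)
        li <- liMAR(sim$ct, ins$mask, geom)
        outs <- list(uncorrected = sim$ct, li = li, proposed = corrected$ct)
        roi <- detected@flags & !ins$mask@flags
        if (!any(roi)) roi <- NULL
      }
      for (method in names(outs)) {
        out <- outs[[method]]
        rows[[length(rows) + 1L]] <- data.frame(
          method = method, implant_count = count, seed = seed,
          rmse_global = rmse(out, clean_rt),
          rmse_artifact_roi = if (is.null(roi)) 0 else rmse(out, clean_rt, roi),
          rmse_outside_body = rmse(out, clean_rt, !body),
          mean_abs_error = .mean_abs(out, clean_rt))
      }
      if (collectImages) {
        key <- sprintf("implants%d_seed%d", count, seed)
        images[[key]] <- list(artifact = outs$uncorrected, li = outs$li,
                              proposed = outs$proposed)
      }
    }
  }
  new("EvaluationReport", metrics = do.call(rbind, rows),
      config = list(implant_counts = implantCounts, seeds = seeds,
                    grid = spec@grid, n_angles = length(geom@angles),
                    radius_range = radiusRange),
      images = images)
}

#' Write an evaluation report to CSV and JSON
#'
#' @param report an [EvaluationReport-class].
#' @param dir output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
writeReport <- function(report, dir) {
  stopifnot(is(report, "EvaluationReport"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  csv <- file.path(dir, "report.csv")
  js <- file.path(dir, "report.json")
  write.csv(report@metrics, csv, row.names = FALSE)
  jsonlite::write_json(list(config = report@config, metrics = report@metrics),
                       js, auto_unbox = TRUE, digits = NA)
  invisible(c(csv = csv, json = js))
}

#' Render a study montage
#'
#' Writes one PNG whose rows are the study conditions and whose three
#' columns are the simulated artifact image, the linear-interpolation
#' result and the proposed method's result.
#'
#' @param report an [EvaluationReport-class] produced with
#'   `collectImages = TRUE`.
#' @param path output PNG path.
#' @return Invisibly, `path`.
#' @export
renderGrid <- function(report, path) {
  stopifnot(is(report, "EvaluationReport"))
  if (length(report@images) == 0L)
    stop("report has no images; run the study with collectImages = TRUE")
  cols <- c("artifact", "li", "proposed")
  tiles <- lapply(names(report@images), function(key) {
    trip <- report@images[[key]]
    for (cn in cols) if (is.null(trip[[cn]]))
      stop(sprintf("missing %s image for condition %s", cn, key))
    do.call(cbind, lapply(trip[cols], function(im) im@pixels))
  })
  mont <- do.call(rbind, tiles)
  rng <- range(mont)
  mont <- if (rng[2] > rng[1]) (mont - rng[1]) / (rng[2] - rng[1]) else mont * 0
  png::writePNG(mont, path)
  invisible(path)
}
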