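#' @include AllGenerics.R
NULL

.sidecar_path <- function(path) paste0(path, ".json")

.read_sidecar <- function(path) {
  sc <- .sidecar_path(path)
  if (file.exists(sc)) jsonlite::read_json(sc, simplifyVector = TRUE) else NULL
}

.write_sidecar <- function(path, meta) {
  jsonlite::write_json(meta, .sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
}

.ext_of <- function(path) tolower(tools::file_ext(sub("\\.gz$", "", path)))

.as_gray_matrix <- function(arr, path) {
  if (length(dim(arr)) == 3L) {
    if (dim(arr)[3] >= 3L)
      stop(sprintf("'%s' is an RGB image; convert it to grayscale first", path))
    arr <- arr[, , 1L]                       # grayscale + alpha: keep gray
  }
  arr
}

#' Read a 2D image into an ImageGrid
#'
#' Supported formats: grayscale PNG (8/16-bit), grayscale TIFF (including
#' float32), and NIfTI-1 (the first slice of a volume; spacing taken from
#' pixdim). PNG/TIFF files written by [writeImageGrid()] carry a JSON
#' sidecar recording the affine intensity transform and the pixel spacing,
#' which is applied on read; without a sidecar, intensities are used as
#' stored and spacing defaults to (1, 1).
#'
#' @param path file to read.
#' @param format override the extension-based format detection
#'   (`"png"`, `"tif"`, `"nii"`).
#' @return An [ImageGrid-class].
#' @seealso [writeImageGrid()]
#' @export
readImageGrid <- function(path, format = NULL) {
  if (!file.exists(path)) stop(sprintf("cannot read '%s': no such file", path))
  fmt <- if (is.null(format)) .ext_of(path) else format
  fmt <- switch(fmt, tiff = "tif", nii = "nii", png = "png", tif = "tif",
                stop(sprintf("unsupported image format '%s'", fmt)))
  spacing <- c(1, 1)
  if (fmt == "nii") {
    vol <- RNifti::readNifti(path)
    pd <- RNifti::pixdim(vol)
    arr <- array(as.numeric(vol), dim = dim(vol))
    if (length(dim(arr)) == 3L) arr <- arr[, , 1L]
    if (length(pd) >= 2L && all(pd[1:2] > 0)) spacing <- pd[1:2]
    mat <- arr
  } else {
    arr <- if (fmt == "png") png::readPNG(path) else tiff::readTIFF(path)
    mat <- .as_gray_matrix(arr, path)
    sc <- .read_sidecar(path)
    if (!is.null(sc)) {
      if (!is.null(sc$slope)) mat <- mat * sc$slope + sc$intercept
      if (!is.null(sc$spacing)) spacing <- as.numeric(sc$spacing)
    }
  }
  if (anyNA(mat) || any(!is.finite(mat)))
    stop(sprintf("'%s' contains NaN or non-finite pixels", path))
  imageGrid(mat, spacing = spacing)
}

#' Write an ImageGrid to disk
#'
#' NIfTI stores double-precision values and the pixel spacing directly and
#' round-trips losslessly. TIFF stores float32 samples affinely mapped to
#' [0, 1]; PNG stores 8-bit samples. For both, the affine transform
#' (`slope`, `intercept`), the spacing and the quantization step are
#' recorded in a JSON sidecar next to the file, so [readImageGrid()]
#' recovers values losslessly up to the format precision (one quantization
#' step for PNG, float32 rounding for TIFF).
#'
#' @param img an [ImageGrid-class].
#' @param path destination; extension selects the format (`.nii`, `.tif`,
#'   `.png`).
#' @return Invisibly, `path`.
#' @export
writeImageGrid <- function(img, path) {
  stopifnot(is(img, "ImageGrid"))
  if (!dir.exists(dirname(path)))
    stop(sprintf("cannot write '%s': parent directory does not exist", path))
  fmt <- .ext_of(path)
  px <- img@pixels
  if (fmt == "nii") {
    vol <- RNifti::asNifti(px)
    RNifti::pixdim(vol) <- img@spacing
    RNifti::writeNifti(vol, path)
    return(invisible(path))
  }
  lo <- min(px); hi <- max(px)
  slope <- if (hi > lo) hi - lo else 1
  stored <- (px - lo) / slope
  if (fmt %in% c("tif", "tiff")) {
    tiff::writeTIFF(stored, path, bits.per.sample = 32L)
    step <- 0
  } else if (fmt == "png") {
    stored <- round(stored * 255) / 255
    png::writePNG(stored, path)
    step <- slope / 255
  } else stop(sprintf("unsupported image format '%s'", fmt))
  .write_sidecar(path, list(slope = slope, intercept = lo,
                            spacing = img@spacing, quantization_step = step))
  invisible(path)
}

#' Sinogram persistence
#'
#' Sinograms are stored as float32 TIFF plus a JSON sidecar carrying the
#' affine intensity transform, the view angles and the detector bin
#' spacing.
#'
#' @param sino a [Sinogram-class].
#' @param path destination `.tif` path.
#' @return Invisibly, `path`.
#' @export
writeSinogram <- function(sino, path) {
  stopifnot(is(sino, "Sinogram"))
  v <- sino@values
  lo <- min(v); hi <- max(v)
  slope <- if (hi > lo) hi - lo else 1
  tiff::writeTIFF((v - lo) / slope, path, bits.per.sample = 32L)
  .write_sidecar(path, list(slope = slope, intercept = lo,
                            angles = sino@geometry@angles,
                            n_bins = sino@geometry@nBins,
                            bin_spacing = sino@geometry@binSpacing))
  invisible(path)
}

#' @rdname writeSinogram
#' @export
readSinogram <- function(path) {
  sc <- .read_sidecar(path)
  if (is.null(sc)) stop(sprintf("'%s' has no sinogram sidecar", path))
  v <- tiff::readTIFF(path) * sc$slope + sc$intercept
  geom <- parallelGeometry(nBins = sc$n_bins, binSpacing = sc$bin_spacing,
                           angles = sc$angles)
  sinogram(v, geom)
}

.config_as_list <- function(cfg) {
  out <- lapply(slotNames(cfg), function(sn) {
    v <- slot(cfg, sn)
    if (is(v, "PhantomSpec")) list(grid = v@grid, ellipses = v@ellipses) else v
  })
  names(out) <- slotNames(cfg)
  out
}

#' Load / save a full run configuration
#'
#' The configuration round-trips losslessly through YAML: every field of
#' the detection, correction, physics and MR-synthesis configs plus the
#' I/O paths and the global seed.
#'
#' @param path YAML file.
#' @return `loadRunConfig` returns a [RunConfig-class]; `saveRunConfig`
#'   invisibly returns `path`.
#' @export
loadRunConfig <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read config '%s'", path))
  y <- yaml::read_yaml(path)
  build <- function(ctor, lst) do.call(ctor, lst[!vapply(lst, is.null, TRUE)])
  runConfig(
    detection = build(detectionConfig, y$detection %||% list()),
    correction = build(correctionConfig, y$correction %||% list()),
    physics = build(physicsConfig, y$physics %||% list()),
    mr = build(mrSynthesisConfig, y$mr %||% list()),
    paths = y$paths %||% list(),
    seed = y$seed %||% 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname loadRunConfig
#' @param cfg a [RunConfig-class].
#' @export
saveRunConfig <- function(cfg, path) {
  stopifnot(is(cfg, "RunConfig"))
  y <- list(detection = .config_as_list(cfg@detection),
            correction = .config_as_list(cfg@correction),
            physics = .config_as_list(cfg@physics),
            mr = .config_as_list(cfg@mr),
            paths = cfg@paths, seed = cfg@seed)
  yaml::write_yaml(y, path, precision = 15L)
  invisible(path)
}
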