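#' @include AllClasses.R
NULL

#' Accessors for the raster and sinogram classes
#'
#' `pixels()` returns the intensity matrix of an [ImageGrid-class];
#' `spacing()` its (row, col) pixel spacing. `flags()` returns the logical
#' matrix of an [ArtifactMask-class] or [TraceMask-class]. `angles()`,
#' `nBins()` and `binSpacing()` expose a [Geometry-class];
#' `sinoValues()` the line-integral matrix of a [Sinogram-class].
#'
#' @param object the object to access.
#' @return The slot value; see Details.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("pixels", function(object) standardGeneric("pixels"))
#' @rdname accessors
#' @export
setGeneric("spacing", function(object) standardGeneric("spacing"))
#' @rdname accessors
#' @export
setGeneric("flags", function(object) standardGeneric("flags"))
#' @rdname accessors
#' @export
setGeneric("angles", function(object) standardGeneric("angles"))
#' @rdname accessors
#' @export
setGeneric("nBins", function(object) standardGeneric("nBins"))
#' @rdname accessors
#' @export
setGeneric("binSpacing", function(object) standardGeneric("binSpacing"))
#' @rdname accessors
#' @export
setGeneric("sinoValues", function(object) standardGeneric("sinoValues"))
#' @rdname accessors
#' @export
setGeneric("geometry", function(object) standardGeneric("geometry"))

#' @rdname accessors
#' @export
setMethod("pixels", "ImageGrid", function(object) object@pixels)
#' @rdname accessors
#' @export
setMethod("spacing", "ImageGrid", function(object) object@spacing)
#' @rdname accessors
#' @export
setMethod("flags", "ArtifactMask", function(object) object@flags)
#' @rdname accessors
#' @export
setMethod("flags", "TraceMask", function(object) object@flags)
#' @rdname accessors
#' @export
setMethod("angles", "Geometry", function(object) object@angles)
#' @rdname accessors
#' @export
setMethod("nBins", "Geometry", function(object) object@nBins)
#' @rdname accessors
#' @export
setMethod("binSpacing", "Geometry", function(object) object@binSpacing)
#' @rdname accessors
#' @export
setMethod("sinoValues", "Sinogram", function(object) object@values)
#' @rdname accessors
#' @export
setMethod("geometry", "Sinogram", function(object) object@geometry)
#' @rdname accessors
#' @export
setMethod("geometry", "TraceMask", function(object) object@geometry)

#' @describeIn ImageGrid-class image dimensions (rows, cols).
#' @param x an `ImageGrid` or `ArtifactMask`.
#' @export
setMethod("dim", "ImageGrid", function(x) dim(x@pixels))

#' @describeIn ArtifactMask-class mask dimensions (rows, cols).
#' @param x an `ArtifactMask`.
#' @export
setMethod("dim", "ArtifactMask", function(x) dim(x@flags))

setMethod("show", "ImageGrid", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("ImageGrid: %d x %d px, spacing (%.3g, %.3g), range [%.4g, %.4g]\n",
              d[1], d[2], object@spacing[1], object@spacing[2],
              min(object@pixels), max(object@pixels)))
})

setMethod("show", "ArtifactMask", function(object) {
  d <- dim(object@flags)
  cat(sprintf("ArtifactMask: %d x %d px, %d corrupted (%.2f%%)\n",
              d[1], d[2], sum(object@flags),
              100 * mean(object@flags)))
})

setMethod("show", "Geometry", function(object) {
  cat(sprintf("Geometry: %d views over [%g, %g] deg, %d bins at pitch %.3g\n",
              length(object@angles), min(object@angles), max(object@angles),
              object@nBins, object@binSpacing))
})

setMethod("show", "Sinogram", function(object) {
  cat(sprintf("Sinogram: %d views x %d bins, range [%.4g, %.4g]\n",
              nrow(object@values), ncol(object@values),
              min(object@values), max(object@values)))
})

setMethod("show", "TraceMask", function(object) {
  cat(sprintf("TraceMask: %d views x %d bins, %d flagged bins\n",
              nrow(object@flags), ncol(object@flags), sum(object@flags)))
})

setMethod("show", "EvaluationReport", function(object) {
  m <- object@metrics
  cat(sprintf("EvaluationReport: %d rows (%s; implants %s; %d seeds)\n",
              nrow(m), paste(unique(m$method), collapse = "/"),
              paste(sort(unique(m$implant_count)), collapse = ","),
              length(unique(m$seed))))
})
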