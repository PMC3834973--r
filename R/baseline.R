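#' @include projection.R
NULL

#' Linear interpolation across the metal trace
#'
#' Per view (sinogram row), each maximal run of flagged bins is replaced by
#' the straight line between the nearest unflagged bins on either side;
#' runs touching a detector edge are filled with the single available
#' boundary value. Unflagged bins are unchanged.
#'
#' @param sino a [Sinogram-class].
#' @param trace a [TraceMask-class] of the same shape.
#' @return A [Sinogram-class] with the trace inpainted.
#' @export
interpolateTrace <- function(sino, trace) {
  stopifnot(is(sino, "Sinogram"), is(trace, "TraceMask"))
  v <- sino@values
  f <- trace@flags
  if (!all(dim(v) == dim(f))) stop("shape mismatch between sinogram and trace")
  for (a in seq_len(nrow(v))) {
    fa <- f[a, ]
    if (!any(fa)) next
    keep <- which(!fa)
    if (length(keep) == 0L)
      stop(sprintf("view %d is entirely flagged; cannot interpolate", a))
    if (length(keep) == 1L) {
      v[a, fa] <- v[a, keep]
    } else {
      v[a, fa] <- approx(keep, v[a, keep], xout = which(fa), rule = 2)$y
    }
  }
  sinogram(v, sino@geometry)
}

#' Sinogram-domain linear-interpolation MAR baseline
#'
#' The standard comparison method: compute (or take) the corrupted
#' sinogram, flag the metal trace, bridge it by per-view linear
#' interpolation and reconstruct by filtered back-projection. Given an
#' image, it is first forward-projected (the simulation setting, where raw
#' data is synthetic); given a sinogram, it is used directly.
#'
#' @param artifactSource an [ImageGrid-class] (forward-projected first) or
#'   a [Sinogram-class].
#' @param metalMask metal-only [ArtifactMask-class] in image space.
#' @param geom a [Geometry-class]; defaults to [geometryFor()] of the image
#'   (required when a sinogram is supplied without one).
#' @param outShape reconstruction grid; defaults to the input image shape
#'   (required for sinogram input).
#' @return The corrected [ImageGrid-class]. With an empty metal mask the
#'   trace is empty: an image input is returned unchanged (nothing to
#'   correct) and a sinogram input reduces to its plain FBP.
#' @export
liMAR <- function(artifactSource, metalMask, geom = NULL, outShape = NULL) {
  stopifnot(is(metalMask, "ArtifactMask"))
  if (is(artifactSource, "ImageGrid")) {
    if (!all(dim(artifactSource) == dim(metalMask))) stop("shape mismatch")
    if (!any(metalMask@flags)) return(artifactSource)
    if (is.null(geom)) geom <- geometryFor(artifactSource)
    if (is.null(outShape)) outShape <- dim(artifactSource)
    ps <- artifactSource@spacing[1]
    sino <- forwardProject(artifactSource, geom)
  } else if (is(artifactSource, "Sinogram")) {
    sino <- artifactSource
    geom <- sino@geometry
    if (is.null(outShape)) stop("outShape is required for sinogram input")
    ps <- geom@binSpacing
  } else stop("artifactSource must be an ImageGrid or a Sinogram")
  trace <- metalTrace(metalMask, geom, pixelSpacing = ps)
  fixed <- interpolateTrace(sino, trace)
  fbpReconstruct(fixed, outShape, pixelSpacing = ps)
}
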