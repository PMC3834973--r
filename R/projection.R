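#' @include AllGenerics.R
NULL

.angles_rad <- function(geom) geom@angles * pi / 180

.check_isotropic <- function(img) {
  s <- img@spacing
  if (abs(s[1] - s[2]) > 1e-9 * max(s))
    stop("projection operations require isotropic pixel spacing")
  s[1]
}

.check_coverage <- function(dm, ps, geom) {
  diag_len <- ps * sqrt(sum(dm^2))
  det_len <- geom@nBins * geom@binSpacing
  if (det_len < diag_len)
    stop(sprintf(paste("geometry does not cover the image support:",
                       "detector length %.1f < image diagonal %.1f"),
                 det_len, diag_len))
}

#' Parallel-beam forward projection (Radon transform)
#'
#' Computes the discrete line integral of the image along each (view angle,
#' detector bin) ray, by bilinear sampling along the ray at half-pixel
#' steps. The transform is linear in the image to numerical precision.
#'
#' @param img an [ImageGrid-class] with finite values and isotropic spacing.
#' @param geom a [Geometry-class]; its detector must cover the image
#'   diagonal.
#' @return A [Sinogram-class] of shape (n_angles, n_bins).
#' @examples
#' img <- imageGrid(matrix(0, 32, 32))
#' sino <- forwardProject(img, geometryFor(img, nAngles = 16L))
#' max(abs(sinoValues(sino)))  # zero image -> zero sinogram
#' @seealso [fbpReconstruct()], [metalTrace()]
#' @export
forwardProject <- function(img, geom) {
  stopifnot(is(img, "ImageGrid"), is(geom, "Geometry"))
  ps <- .check_isotropic(img)
  .check_coverage(dim(img@pixels), ps, geom)
  vals <- cpp_forward_project(img@pixels, .angles_rad(geom), geom@nBins,
                              geom@binSpacing, ps, 0.5 * ps)
  sinogram(vals, geom)
}

# Frequency response of the band-limited ramp (Ram-Lak) filter of length n,
# from the discrete-space impulse response h[0] = 1/4, h[odd k] = -1/(pi k)^2
# (Kak & Slaney); this avoids the DC bias of sampling |w| directly.
.ramp_freq <- function(n, apodization = c("ramlak", "hann")) {
  apodization <- match.arg(apodization)
  h <- numeric(n)
  h[1] <- 0.25
  k <- seq_len(n %/% 2)
  odd <- k[k %% 2 == 1L]
  h[1 + odd] <- -1 / (pi * odd)^2          # positive lags
  h[n + 1 - odd] <- -1 / (pi * odd)^2      # negative lags (wrap-around)
  f <- 2 * Re(fft(h))
  if (apodization == "hann") {
    w <- fft_freq_hann(n)
    f <- f * w
  }
  f
}

fft_freq_hann <- function(n) {
  # Hann window over FFT frequencies, 1 at DC falling to 0 at Nyquist
  idx <- c(seq(0, n %/% 2), seq(-((n - 1) %/% 2), -1)) / n  # cycles/sample
  0.5 * (1 + cos(2 * pi * idx))
}

#' Ramp-filtered back-projection (FBP)
#'
#' Filters each view with the discrete Ram-Lak ramp (optionally Hann
#' apodized) and back-projects. For a smooth phantom measured with 180
#' views, the round trip `fbpReconstruct(forwardProject(x))` stays below 5%
#' relative RMSE inside the reconstruction circle.
#'
#' @param sino a [Sinogram-class].
#' @param outShape integer (rows, cols) of the reconstruction grid.
#' @param pixelSpacing isotropic pixel spacing of the output, default the
#'   detector bin spacing.
#' @param apodization `"ramlak"` (default; sharper, keeps streaks crisp) or
#'   `"hann"`.
#' @return An [ImageGrid-class].
#' @seealso [forwardProject()]
#' @export
fbpReconstruct <- function(sino, outShape, pixelSpacing = NULL,
                           apodization = c("ramlak", "hann")) {
  stopifnot(is(sino, "Sinogram"))
  geom <- sino@geometry
  outShape <- as.integer(outShape)
  if (is.null(pixelSpacing)) pixelSpacing <- geom@binSpacing
  .check_coverage(outShape, pixelSpacing, geom)
  v <- sino@values
  nb <- ncol(v)
  npad <- max(64L, 2L^ceiling(log2(2L * nb)))
  f <- .ramp_freq(npad, match.arg(apodization))
  padded <- matrix(0, npad, nrow(v))          # views as columns for mvfft
  padded[seq_len(nb), ] <- t(v)
  filtered <- Re(stats::mvfft(stats::mvfft(padded) * f, inverse = TRUE)) / npad
  filtered <- t(filtered[seq_len(nb), , drop = FALSE]) / geom@binSpacing
  bp <- cpp_back_project(filtered, .angles_rad(geom), outShape[1], outShape[2],
                         geom@binSpacing, pixelSpacing)
  # the factor 2 of the frequency filter (f = 2 Re FFT(h)) cancels here:
  # the view weight is pi / (2 n_angles)
  imageGrid(bp * pi / (2 * length(geom@angles)),
            spacing = c(pixelSpacing, pixelSpacing))
}

#' Metal trace: sinogram bins whose rays intersect metal
#'
#' Forward-projects the metal mask as a 0/1 image and flags every bin whose
#' line integral exceeds `threshold`. An empty metal mask yields an empty
#' trace; a superset metal mask yields a superset trace.
#'
#' @param metal an [ArtifactMask-class] marking metal-only pixels.
#' @param geom a [Geometry-class].
#' @param threshold non-negative line-integral threshold, default 0
#'   (any intersection flags the bin).
#' @param pixelSpacing isotropic pixel spacing of the mask grid, default 1.
#' @return A [TraceMask-class].
#' @export
metalTrace <- function(metal, geom, threshold = 0, pixelSpacing = 1) {
  stopifnot(is(metal, "ArtifactMask"), is(geom, "Geometry"))
  if (threshold < 0) stop("threshold must be >= 0")
  img <- imageGrid(metal@flags + 0, spacing = c(pixelSpacing, pixelSpacing))
  sino <- forwardProject(img, geom)
  traceMask(sino@values > threshold, geom)
}
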