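#' @include AllGenerics.R
NULL

# Normalize to [0, 1] over the slice's observed range; detection works on
# reconstructed gray values without assuming a calibrated HU scale, so the
# resulting mask is invariant to affine intensity rescaling of the input.
.normalize01 <- function(px) {
  rng <- range(px)
  if (rng[2] <= rng[1]) stop("degenerate histogram: image is constant")
  (px - rng[1]) / (rng[2] - rng[1])
}

#' Gray-level histogram of an image
#'
#' Histograms the slice after normalization to [0, 1] over its observed
#' range. Bins are half-open `[edge_i, edge_{i+1})` with the last bin
#' closed, so counts always sum to the pixel count.
#'
#' @param img an [ImageGrid-class] (or numeric matrix); must not be
#'   constant.
#' @param nBins number of histogram bins, default 256.
#' @return A list with `counts` (length `nBins`), `edges` (length
#'   `nBins + 1` spanning [0, 1]) and `mids` (bin centers).
#' @export
imageHistogram <- function(img, nBins = 256L) {
  px <- if (is(img, "ImageGrid")) img@pixels else img
  v <- .normalize01(px)
  nBins <- as.integer(nBins)
  edges <- seq(0, 1, length.out = nBins + 1L)
  bin <- findInterval(v, edges, rightmost.closed = TRUE)
  counts <- tabulate(bin, nbins = nBins)
  list(counts = counts, edges = edges,
       mids = (edges[-1] + edges[-(nBins + 1L)]) / 2)
}

#' Multi-level Otsu thresholding
#'
#' Finds the `nClasses - 1` cut points that maximize the between-class
#' variance (equivalently minimize the weighted within-class variance) of
#' the gray-level histogram. Solved exactly by dynamic programming over
#' contiguous bin ranges with precomputed cumulative sums, so the result
#' matches exhaustive enumeration of all threshold sets. For `nClasses = 2`
#' this is the classic Otsu threshold.
#'
#' @param hist a histogram as returned by [imageHistogram()].
#' @param nClasses number of intensity classes, >= 2.
#' @return A list with `thresholds` (strictly increasing cut points on the
#'   normalized intensity axis, taken at bin edges) and `objective` (the
#'   maximized between-class variance term `sum_k w_k mu_k^2`).
#' @export
multiOtsu <- function(hist, nClasses) {
  counts <- hist$counts
  nClasses <- as.integer(nClasses)
  nb <- length(counts)
  if (sum(counts > 0) < nClasses)
    stop("histogram has fewer nonempty bins than classes")
  p <- counts / sum(counts)
  mids <- hist$mids
  cp0 <- c(0, cumsum(p))           # cumulative probability, shifted
  cs0 <- c(0, cumsum(p * mids))    # cumulative first moment, shifted
  # q(i, j): w * mu^2 of a class covering bins i..j (1-based, inclusive);
  # vectorized over i or j
  qfun <- function(i, j) {
    w <- cp0[j + 1L] - cp0[i]
    s <- cs0[j + 1L] - cs0[i]
    ifelse(w > 0, s^2 / w, 0)
  }
  # dp[k, j]: best objective for splitting bins 1..j into k classes
  dp <- matrix(-Inf, nClasses, nb)
  arg <- matrix(0L, nClasses, nb)
  dp[1L, ] <- qfun(1L, seq_len(nb))
  for (k in 2L:nClasses) {
    for (j in k:nb) {
      i <- k:j                     # first bin of class k
      cand <- dp[k - 1L, i - 1L] + qfun(i, j)
      best <- which.max(cand)
      dp[k, j] <- cand[best]
      arg[k, j] <- i[best]
    }
  }
  # backtrack the class boundaries
  cuts <- integer(nClasses - 1L)
  j <- nb
  for (k in nClasses:2L) {
    i <- arg[k, j]
    cuts[k - 1L] <- i - 1L         # last bin of class k-1
    j <- i - 1L
  }
  list(thresholds = hist$edges[cuts + 1L], objective = dp[nClasses, nb])
}

#' Classify pixels against a threshold set
#'
#' A pixel's label is the number of thresholds strictly below its
#' (normalized) value, so labels run 0 to `nClasses - 1` and partition the
#' image.
#'
#' @param img an [ImageGrid-class] or numeric matrix; values are normalized
#'   to [0, 1] first.
#' @param thresholds strictly increasing cut points as from [multiOtsu()].
#' @return An integer matrix of class labels.
#' @export
classifyPixels <- function(img, thresholds) {
  px <- if (is(img, "ImageGrid")) img@pixels else img
  v <- .normalize01(px)
  if (is.list(thresholds)) thresholds <- thresholds$thresholds
  if (any(diff(thresholds) <= 0)) stop("thresholds must be strictly increasing")
  lab <- findInterval(v, thresholds, left.open = TRUE)
  matrix(as.integer(lab), nrow(px), ncol(px))
}

# winsorize at the given quantiles: the gray-value analogue of display
# windowing, under which metal and severe streaks saturate; quantiles are
# affine-equivariant, so the detected mask stays invariant to affine
# intensity rescaling of the input
.winsorize <- function(px, q) {
  if (q[1] <= 0 && q[2] >= 1) return(px)
  b <- stats::quantile(px, q, names = FALSE)
  pmin(pmax(px, b[1]), b[2])
}

# body support: largest connected component of pixels at or above the body
# threshold (on the normalized scale), holes filled
.body_support <- function(vnorm, bodyThreshold) {
  b <- vnorm >= bodyThreshold
  if (!any(b)) return(b)
  lab <- EBImage::bwlabel(EBImage::Image(b + 0))
  lab <- EBImage::imageData(lab)
  sizes <- tabulate(lab[lab > 0])
  keep <- which.max(sizes)
  comp <- lab == keep
  EBImage::imageData(EBImage::fillHull(EBImage::Image(comp + 0))) > 0
}

#' Detect corrupted pixels by multi-level Otsu thresholding
#'
#' Normalizes the slice, splits its histogram into `nClasses` (default 50)
#' intensity classes by exact multi-level Otsu, and flags as corrupted the
#' pixels of the `brightK` top classes (metal and bright streaks) together
#' with the pixels of the `darkK` bottom classes that lie inside the body
#' support (dark streaks; dark air outside the body is already correct and
#' is never flagged).
#'
#' @param img the artifact-laden CT [ImageGrid-class]; must not be constant.
#' @param cfg a [DetectionConfig-class].
#' @return An [ArtifactMask-class]; `TRUE` marks corrupted pixels.
#' @seealso [correctImage()]
#' @export
detectArtifacts <- function(img, cfg = detectionConfig()) {
  stopifnot(is(img, "ImageGrid"), is(cfg, "DetectionConfig"))
  vnorm <- .normalize01(img@pixels)
  pxw <- .winsorize(img@pixels, cfg@clipQuantiles)
  h <- imageHistogram(pxw, cfg@nHistogramBins)
  ot <- multiOtsu(h, cfg@nClasses)
  lab <- classifyPixels(pxw, ot$thresholds)
  bright <- lab >= cfg@nClasses - cfg@brightK
  dark <- lab < cfg@darkK
  if (cfg@brightK == 0L) bright[] <- FALSE
  if (cfg@darkK == 0L) {
    dark[] <- FALSE
  } else {
    dark <- dark & .body_support(vnorm, cfg@bodyThreshold)
  }
  artifactMask(bright | dark)
}
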