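#' @include AllGenerics.R
NULL

#' Replicate-pad an image
#'
#' Pads by `margin` rows/columns on every side, replicating the nearest
#' interior pixel, so a sliding window can be centered on border pixels
#' (for a 5x5 window the first two and last two rows and columns are
#' replicated).
#'
#' @param img an [ImageGrid-class] or matrix.
#' @param margin non-negative integer, `(window - 1) / 2`; may exceed the
#'   image size (a 1x1 image padded by 2 gives a 5x5 constant image).
#' @return Same type as the input, padded to
#'   `(rows + 2 margin, cols + 2 margin)`.
#' @export
padReplicate <- function(img, margin) {
  m <- as.integer(margin)
  if (m < 0L) stop("margin must be >= 0")
  mat <- if (is(img, "ImageGrid")) img@pixels else img
  ri <- c(rep(1L, m), seq_len(nrow(mat)), rep(nrow(mat), m))
  ci <- c(rep(1L, m), seq_len(ncol(mat)), rep(ncol(mat), m))
  out <- mat[ri, ci, drop = FALSE]
  if (is(img, "ImageGrid")) imageGrid(out, spacing = img@spacing) else out
}

# window offsets in row-major scan order (by row, then column), center
# excluded; similarity ties between candidates are broken by this order
.window_offsets <- function(window) {
  m <- (window - 1L) %/% 2L
  off <- expand.grid(dc = -m:m, dr = -m:m)[, c("dr", "dc")]  # row-major
  off <- off[order(off$dr, off$dc), ]
  off[!(off$dr == 0L & off$dc == 0L), ]
}

#' Find the donor position for a corrupted pixel
#'
#' Ranks all non-center window positions by ascending absolute difference
#' between their MR value and the MR value at the window center (ties broken
#' by row-major scan order) and returns the first whose CT position is
#' uncorrupted — the most MR-similar uncorrupted neighbor. Returns `NULL`
#' when every candidate is corrupted.
#'
#' @param mrWindow numeric square window of MR values centered on the
#'   corrupted pixel.
#' @param corruptWindow logical window of corruption flags, same shape.
#' @return A list with `dr`, `dc` (offset of the donor from the center) or
#'   `NULL` if no uncorrupted candidate exists.
#' @export
findDonor <- function(mrWindow, corruptWindow) {
  stopifnot(all(dim(mrWindow) == dim(corruptWindow)))
  w <- nrow(mrWindow)
  m <- (w - 1L) %/% 2L
  ctr <- mrWindow[m + 1L, m + 1L]
  off <- .window_offsets(w)
  r <- off$dr + m + 1L; c <- off$dc + m + 1L
  key <- abs(mrWindow[cbind(r, c)] - ctr)
  ord <- order(key)                       # stable: ties keep row-major order
  for (k in ord) {
    if (!corruptWindow[r[k], c[k]])
      return(list(dr = off$dr[k], dc = off$dc[k]))
  }
  NULL
}

#' MR-guided correction of corrupted CT pixels
#'
#' Implements the sliding-window replacement scheme: a `window` x `window`
#' (default 5x5) window is slid over the CT image; whenever the central
#' pixel is corrupted, the most MR-similar uncorrupted position in the
#' window donates its CT value, while uncorrupted pixels are left
#' undisturbed. Within one pass, donor values are read from the pre-pass CT,
#' so the result is independent of scan order; pixels corrected in pass p
#' become legal donors in pass p+1, which resolves fully corrupted
#' neighborhoods. Pixels still without a donor after `maxPasses` are
#' handled per the `fallback` policy and reported in `residual`.
#'
#' @param ct corrupted CT [ImageGrid-class].
#' @param mr co-registered MR [ImageGrid-class], same shape.
#' @param mask corrupted-pixel [ArtifactMask-class], same shape.
#' @param cfg a [CorrectionConfig-class].
#' @param metalMask optional metal [ArtifactMask-class]; with
#'   `cfg@reinsertMetal` the original values inside it are restored after
#'   correction.
#' @return A list with `ct` (corrected [ImageGrid-class]) and `residual`
#'   (an [ArtifactMask-class] of pixels never assigned a donor value,
#'   flagged before any fallback fill).
#' @export
correctImage <- function(ct, mr, mask, cfg = correctionConfig(),
                         metalMask = NULL) {
  stopifnot(is(ct, "ImageGrid"), is(mr, "ImageGrid"), is(mask, "ArtifactMask"),
            is(cfg, "CorrectionConfig"))
  if (!all(dim(ct) == dim(mr)) || !all(dim(ct) == dim(mask)))
    stop("shape mismatch between CT, MR and mask")
  if (all(mask@flags)) stop("no uncorrupted pixels available")
  w <- cfg@window
  m <- (w - 1L) %/% 2L
  off <- .window_offsets(w)
  mr_pad <- padReplicate(mr@pixels, m)
  cur_ct <- ct@pixels
  cur_mask <- mask@flags
  nr <- nrow(cur_ct); nc <- ncol(cur_ct)

  for (pass in seq_len(cfg@maxPasses)) {
    if (!any(cur_mask)) break
    ct_pad <- padReplicate(cur_ct, m)
    mk_pad <- padReplicate(cur_mask, m)
    targets <- which(cur_mask, arr.ind = TRUE)
    new_ct <- cur_ct
    new_mask <- cur_mask
    progress <- FALSE
    for (t in seq_len(nrow(targets))) {
      r <- targets[t, 1L]; c <- targets[t, 2L]
      pr <- r + m; pc <- c + m                     # padded coordinates
      ctr <- mr_pad[pr, pc]
      cr <- pr + off$dr; cc <- pc + off$dc
      key <- abs(mr_pad[cbind(cr, cc)] - ctr)
      ord <- order(key)
      for (k in ord) {
        if (!mk_pad[cr[k], cc[k]]) {
          new_ct[r, c] <- ct_pad[cr[k], cc[k]]
          new_mask[r, c] <- FALSE
          progress <- TRUE
          break
        }
      }
    }
    cur_ct <- new_ct
    cur_mask <- new_mask
    if (!progress) break
  }

  residual <- cur_mask
  if (any(residual) && cfg@fallback == "neighborhood_mean") {
    ct_pad <- padReplicate(cur_ct, m)
    mk_pad <- padReplicate(cur_mask, m)
    targets <- which(residual, arr.ind = TRUE)
    filled <- cur_ct
    for (t in seq_len(nrow(targets))) {
      r <- targets[t, 1L]; c <- targets[t, 2L]
      cr <- r + m + off$dr; cc <- c + m + off$dc
      ok <- !mk_pad[cbind(cr, cc)]
      if (any(ok)) filled[r, c] <- mean(ct_pad[cbind(cr, cc)][ok])
    }
    cur_ct <- filled
  }
  if (isTRUE(cfg@reinsertMetal) && !is.null(metalMask)) {
    cur_ct[metalMask@flags] <- ct@pixels[metalMask@flags]
  }
  list(ct = imageGrid(cur_ct, spacing = ct@spacing),
       residual = artifactMask(residual))
}
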