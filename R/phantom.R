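#' @include projection.R
NULL

#' Default head phantom at the dental level
#'
#' A 2D axial slice through the dental arch on the normalized intensity
#' convention (air ~ 0, soft tissue ~ 0.3, bone ~ 0.7): an outer
#' soft-tissue outline, a thin cranial bone ring, interior soft tissue at
#' 0.35, a dark airway (oral cavity), and a U-shaped row of tooth/mandible
#' ellipses in the lower (jaw) band — the structured anatomy dental
#' implants sit in, and the structure that sinogram interpolation destroys
#' when the metal trace crosses it. Dimensions scale with the grid so the
#' same anatomy renders at 128x128 (test scale) or 512x512 (clinical
#' matrix).
#'
#' @param rows,cols grid size in px, default 128.
#' @param nTeeth number of tooth ellipses along the dental arch, default 8.
#' @return A [PhantomSpec-class].
#' @examples
#' ph <- makePhantom(headPhantomSpec(64, 64))
#' sort(unique(as.vector(pixels(ph))))
#' @export
headPhantomSpec <- function(rows = 128L, cols = rows, nTeeth = 8L) {
  n <- min(rows, cols)
  ctr <- c((rows + 1) / 2, (cols + 1) / 2)
  ell <- function(crow, ccol, arow, acol, rot, val)
    list(center = c(crow, ccol), axes = c(arow, acol), rotation = rot,
         intensity = val)
  base <- list(
    ell(ctr[1], ctr[2], 0.45 * n, 0.37 * n, 0, 0.30),   # scalp / soft tissue
    ell(ctr[1], ctr[2], 0.42 * n, 0.34 * n, 0, 0.70),   # cranial bone ring
    ell(ctr[1], ctr[2], 0.38 * n, 0.30 * n, 0, 0.35),   # interior soft tissue
    ell(ctr[1] + 0.10 * n, ctr[2], 0.045 * n, 0.09 * n, 0, 0.05)  # airway
  )
  teeth <- lapply(.tooth_angles(nTeeth), function(phi) {
    ell(ctr[1] + 0.30 * n * cos(phi), ctr[2] + 0.26 * n * sin(phi),
        0.026 * n, 0.022 * n, 0, 0.70)
  })
  phantomSpec(c(rows, cols), c(base, teeth))
}

# tooth positions along the dental arch, as angles (radians) from the
# downward vertical through the phantom center
.tooth_angles <- function(nTeeth) {
  seq(-50, 50, length.out = nTeeth) * pi / 180
}

#' Rasterize a phantom specification
#'
#' Paints the ellipse stack in painter's order (later ellipses overwrite
#' earlier ones); a pixel belongs to an ellipse when its center lies inside.
#' The result is deterministic and takes exactly the configured tissue
#' intensities.
#'
#' @param spec a [PhantomSpec-class].
#' @param spacing pixel spacing passed through to the output grid.
#' @return An [ImageGrid-class] (the clean CT).
#' @export
makePhantom <- function(spec, spacing = c(1, 1)) {
  stopifnot(is(spec, "PhantomSpec"))
  nr <- spec@grid[1]; nc <- spec@grid[2]
  img <- matrix(0, nr, nc)
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  for (e in spec@ellipses) {
    rot <- e$rotation * pi / 180
    dr <- rr - e$center[1]; dc <- cc - e$center[2]
    u <- dr * cos(rot) + dc * sin(rot)
    v <- -dr * sin(rot) + dc * cos(rot)
    # bounding-box check: ellipse must fit inside the grid
    ext <- sqrt((e$axes[1] * cos(rot))^2 + (e$axes[2] * sin(rot))^2)
    extc <- sqrt((e$axes[1] * sin(rot))^2 + (e$axes[2] * cos(rot))^2)
    if (e$center[1] - ext < 0.5 || e$center[1] + ext > nr + 0.5 ||
        e$center[2] - extc < 0.5 || e$center[2] + extc > nc + 0.5)
      stop("ellipse extends outside the phantom grid")
    inside <- (u / e$axes[1])^2 + (v / e$axes[2])^2 <= 1
    img[inside] <- e$intensity
  }
  imageGrid(img, spacing = spacing)
}

#' Sample a dental implant layout in the jaw band
#'
#' Places `count` metal disk centers in the lower (jaw) band of a head
#' phantom, spread left-to-right with a seeded jitter, and draws radii
#' uniformly from `radiusRange`. Positions are guaranteed to lie inside the
#' body.
#'
#' @param spec the [PhantomSpec-class] the implants are for.
#' @param count number of implants, 0 to 8.
#' @param seed integer seed controlling jitter and radii.
#' @param radiusRange numeric (min, max) disk radius in px.
#' @param intensity metal intensity, default 3.0.
#' @return An [ImplantSpec-class].
#' @export
sampleImplantSpec <- function(spec, count, seed = 0L, radiusRange = c(2, 4),
                              intensity = 3.0) {
  stopifnot(is(spec, "PhantomSpec"), count >= 0, count <= 8)
  if (count == 0L) return(implantSpec(intensity = intensity))
  nr <- spec@grid[1]; nc <- spec@grid[2]; n <- min(nr, nc)
  set.seed(as.integer(seed) + 1000L * as.integer(count))
  # teeth = small bone ellipses of the spec; dental metal sits in teeth
  teeth <- Filter(function(e) e$intensity >= 0.6 && max(e$axes) < 0.06 * n,
                  spec@ellipses)
  if (length(teeth) >= count) {
    pick <- sample(length(teeth), count)
    centers <- t(vapply(teeth[pick], function(e) e$center, numeric(2)))
    centers <- centers + matrix(runif(2 * count, -0.006 * n, 0.006 * n),
                                count, 2)
  } else {
    # no tooth row in this spec: spread implants across the jaw band
    band_row <- (nr + 1) / 2 + 0.26 * n
    span <- 0.18 * n
    cols <- (nc + 1) / 2 +
      seq(-span, span, length.out = count + 2L)[-c(1L, count + 2L)]
    centers <- cbind(band_row + runif(count, -0.02 * n, 0.02 * n),
                     cols + runif(count, -0.02 * n, 0.02 * n))
  }
  radii <- runif(count, radiusRange[1], radiusRange[2])
  implantSpec(centers, radii, intensity)
}

#' Insert metal implants into a clean CT
#'
#' Paints each implant as a disk of metal intensity (pixel centers within
#' the radius) and returns the metal mask of exactly the overwritten
#' pixels. Each disk must lie fully inside the body (non-air tissue).
#'
#' @param cleanCT the artifact-free [ImageGrid-class].
#' @param imp an [ImplantSpec-class]; an empty spec returns the image
#'   unchanged with an all-false mask.
#' @return A list with `ct` (the [ImageGrid-class] with metal) and `mask`
#'   (the metal [ArtifactMask-class]).
#' @export
insertImplants <- function(cleanCT, imp) {
  stopifnot(is(cleanCT, "ImageGrid"), is(imp, "ImplantSpec"))
  px <- cleanCT@pixels
  nr <- nrow(px); nc <- ncol(px)
  mask <- matrix(FALSE, nr, nc)
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  for (i in seq_len(nrow(imp@centers))) {
    ctr <- imp@centers[i, ]; rad <- imp@radii[i]
    disk <- (rr - ctr[1])^2 + (cc - ctr[2])^2 <= rad^2
    if (!any(disk)) stop("implant disk covers no pixel")
    if (any(px[disk] < 0.1))
      stop("implant lies outside the body (air underneath)")
    mask <- mask | disk
  }
  px[mask] <- imp@intensity
  list(ct = imageGrid(px, spacing = cleanCT@spacing), mask = artifactMask(mask))
}

#' Simulate a metal-corrupted CT acquisition
#'
#' Forward-projects the metal-bearing slice, corrupts the metal-trace bins
#' with beam hardening (power law `cap * (v / cap)^gamma`) and photon
#' starvation (clip at `cap`), applies Poisson counting noise over the whole
#' sinogram, and reconstructs by filtered back-projection, producing the
#' characteristic bright/dark streaks radiating from the implants. With
#' identity physics (`gamma = 1`, infinite cap, noise off) the output equals
#' the plain FBP round trip.
#'
#' @param ctWithMetal [ImageGrid-class] with implants painted in.
#' @param metalMask metal-only [ArtifactMask-class].
#' @param geom a [Geometry-class], default [geometryFor()] of the image.
#' @param phys a [PhysicsConfig-class]; `saturationCap = NA` resolves to
#'   0.95 times the maximum clean line integral through metal.
#' @return A list with `ct` (the streaky [ImageGrid-class]), `trace` (the
#'   [TraceMask-class] used) and `sinogram` (the corrupted [Sinogram-class]).
#' @export
simulateArtifactCT <- function(ctWithMetal, metalMask, geom = NULL,
                               phys = physicsConfig()) {
  stopifnot(is(ctWithMetal, "ImageGrid"), is(metalMask, "ArtifactMask"),
            is(phys, "PhysicsConfig"))
  if (!all(dim(ctWithMetal) == dim(metalMask))) stop("shape mismatch")
  if (is.null(geom)) geom <- geometryFor(ctWithMetal)
  sino <- forwardProject(ctWithMetal, geom)
  trace <- metalTrace(metalMask, geom, threshold = phys@traceThreshold,
                      pixelSpacing = ctWithMetal@spacing[1])
  v <- sino@values
  tf <- trace@flags
  cap <- phys@saturationCap
  if (is.na(cap)) {
    cap <- if (any(tf)) 0.95 * max(v[tf]) else Inf
  }
  if (any(tf) && is.finite(cap)) {
    # power law under-measures attenuation below the cap (beam hardening),
    # the clip at the cap models photon starvation; an infinite cap disables
    # both and leaves an identity acquisition
    vt <- v[tf]
    vt <- cap * (vt / cap)^phys@beamHardeningGamma
    v[tf] <- pmin(vt, cap)
  }
  if (is.finite(phys@noisePhotons)) {
    set.seed(phys@randomSeed)
    mu <- phys@muPerUnit
    counts <- rpois(length(v), phys@noisePhotons * exp(-mu * v))
    counts <- pmax(counts, 0.5)           # avoid log(0) on starved bins
    v <- matrix(-log(counts / phys@noisePhotons) / mu, nrow(v), ncol(v))
  }
  corrupted <- sinogram(v, geom)
  recon <- fbpReconstruct(corrupted, dim(ctWithMetal),
                          pixelSpacing = ctWithMetal@spacing[1])
  list(ct = recon, trace = trace, sinogram = corrupted)
}

#' Synthesize a co-registered pseudo-MR slice from clean anatomy
#'
#' Remaps each pixel of the clean CT to the MR intensity of its nearest CT
#' tissue level, then applies Gaussian smoothing and seeded additive
#' Gaussian noise. If `voidRadius > 0`, intensities within that distance of
#' metal are zeroed, emulating the susceptibility signal voids implants
#' cause in MR. The output is co-registered with the CT by construction
#' unless a rigid `shift` is requested.
#'
#' @param cleanCT the artifact-free [ImageGrid-class] (MR carries clean
#'   anatomy: dental metal does not degrade the MR acquisition).
#' @param metalMask metal [ArtifactMask-class] (used for the void halo).
#' @param cfg an [MRSynthesisConfig-class].
#' @return An [ImageGrid-class] in arbitrary MR units.
#' @export
synthesizeMR <- function(cleanCT, metalMask, cfg = mrSynthesisConfig()) {
  stopifnot(is(cleanCT, "ImageGrid"), is(metalMask, "ArtifactMask"),
            is(cfg, "MRSynthesisConfig"))
  if (!all(dim(cleanCT) == dim(metalMask))) stop("shape mismatch")
  px <- cleanCT@pixels
  idx <- vapply(as.vector(px), function(v) which.min(abs(cfg@ctLevels - v)),
                integer(1))
  mr <- matrix(cfg@mrLevels[idx], nrow(px), ncol(px))
  if (cfg@smoothSigma > 0)
    mr <- EBImage::imageData(EBImage::gblur(EBImage::Image(mr), sigma = cfg@smoothSigma))
  if (cfg@noiseSigma > 0) {
    set.seed(cfg@randomSeed)
    mr <- mr + matrix(rnorm(length(mr), sd = cfg@noiseSigma), nrow(mr), ncol(mr))
  }
  if (cfg@voidRadius > 0 && any(metalMask@flags)) {
    d <- EBImage::imageData(EBImage::distmap(EBImage::Image(1 - (metalMask@flags + 0))))
    mr[d <= cfg@voidRadius | metalMask@flags] <- 0
  }
  mr <- pmax(mr, 0)
  if (any(cfg@shift != 0L)) {
    mr <- .shift_replicate(mr, cfg@shift[1], cfg@shift[2])
  }
  imageGrid(mr, spacing = cleanCT@spacing)
}

# rigid integer shift with edge replication (misregistration knob)
.shift_replicate <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr) - dr, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) - dc, 1L), nc)
  m[ri, ci, drop = FALSE]
}
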