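# mrmar: MR-guided metal artifact reduction for X-ray CT

Dental implants attenuate low-energy X-ray photons almost completely. The
projection bins whose rays intersect the metal are corrupted, and filtered
back-projection (FBP) turns that inconsistency into bright and dark streaks
radiating across the slice. `mrmar` implements an image-domain correction
for these artifacts that exploits a co-registered MR slice of the same
anatomy — dental metal does not degrade MR image quality, so the MR carries
the anatomical information the CT has lost. The package is aimed at
researchers studying metal-artifact-reduction (MAR) algorithms who need a
complete, reproducible 2D test bed: the method, a physics-based artifact
simulator, the standard sinogram-interpolation baseline, and an evaluation
harness.

## The method

**Detection.** The slice is winsorized at robust quantiles (the
affine-invariant analogue of display windowing), normalized to [0, 1], and
its gray-level histogram is split into *n* = 50 classes by exact
multi-level Otsu thresholding: the cut points `t_1 < ... < t_{n-1}`
maximize the between-class variance

    sum_k w_k (mu_k - mu)^2,   w_k = class probability, mu_k = class mean,

solved exactly by dynamic programming over histogram bins. The corrupted
mask is the union of the top `brightK` classes (metal and bright streaks)
and the bottom `darkK` classes restricted to the body support (dark
streaks).

**Correction.** A 5 x 5 window slides over the CT. When the central pixel
is flagged corrupted, the candidate window positions are ranked by
`|MR(p) - MR(center)|` and the first candidate whose CT pixel is
uncorrupted donates its CT value; uncorrupted pixels are left undisturbed,
bit-exact. Borders are handled by replicating the outer two rows and
columns. Pixels whose whole window is corrupted are retried in later
passes, where previously corrected pixels become legal donors.

**Validation apparatus.** A parallel-beam Radon transform and Ram-Lak FBP
(compiled code), a dental-level head phantom with seeded implant layouts, a
corruption model (beam hardening as a power law on metal-trace bins,
photon-starvation saturation, Poisson counting noise), a pseudo-MR
synthesizer, the per-view linear-interpolation MAR baseline (LI), and a
study runner that scores all methods against the artifact-free FBP round
trip.

## Worked example

```r
library(mrmar)

spec  <- headPhantomSpec(128)                  # dental-level head phantom
clean <- makePhantom(spec)
geom  <- geometryFor(clean)                    # 180 views, 1 deg spacing
ins   <- insertImplants(clean, sampleImplantSpec(spec, count = 2, seed = 1))
sim   <- simulateArtifactCT(ins$ct, ins$mask, geom,
                            physicsConfig(randomSeed = 1))
mr    <- synthesizeMR(clean, ins$mask, mrSynthesisConfig(randomSeed = 1))

mask  <- detectArtifacts(sim$ct)               # 50-class Otsu mask
fixed <- correctImage(sim$ct, mr, mask)

ref <- fbpReconstruct(forwardProject(clean, geom), dim(clean))
roi <- flags(mask) & !flags(ins$mask)
round(c(uncorrected = rmse(sim$ct, ref, roi),
        corrected   = rmse(fixed$ct, ref, roi)), 3)
#> uncorrected   corrected
#>       0.300       0.097
```

The two numbers are the RMS error, on the normalized intensity scale
(soft tissue ~ 0.3, bone ~ 0.7), over the detected artifact region
excluding metal: the MR-guided replacement removes about two thirds of the
artifact error while leaving every unflagged pixel untouched. The same
pipeline is scriptable from a shell via `exec/mrmar`
(`mrmar simulate | detect | correct | baseline | evaluate`).

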