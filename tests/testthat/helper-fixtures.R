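# Shared fixtures: small images, simulator conditions, independent oracles.

random_grid <- function(nr, nc = nr, seed = 1L, lo = 0, hi = 1) {
  set.seed(seed)
  imageGrid(matrix(runif(nr * nc, lo, hi), nr, nc))
}

# anti-aliased disk (4x4 subpixel coverage): the discrete stand-in for an
# analytic disk in the chord-length oracle
aa_disk <- function(n, r, value = 1) {
  ss <- 4L
  nss <- n * ss
  rr <- matrix(seq_len(nss), nss, nss)
  cc <- t(rr)
  ctr <- (nss + 1) / 2
  d <- ((rr - ctr)^2 + (cc - ctr)^2 <= (r * ss)^2) + 0
  coarse <- matrix(0, n, n)
  for (i in seq_len(n)) {
    rows <- ((i - 1) * ss + 1):(i * ss)
    coarse[i, ] <- colMeans(matrix(colSums(d[rows, ]), ss)) / ss
  }
  imageGrid(coarse * value)
}

smooth_head <- function(n = 128, sigma = 2) {
  ph <- makePhantom(headPhantomSpec(n))
  imageGrid(EBImage::imageData(EBImage::gblur(EBImage::Image(pixels(ph)),
                                              sigma = sigma)))
}

in_circle <- function(n, margin = 2) {
  rr <- matrix(seq_len(n), n, n)
  cc <- t(rr)
  ctr <- (n + 1) / 2
  (rr - ctr)^2 + (cc - ctr)^2 <= (n / 2 - margin)^2
}

# one full simulated condition at the study scale
sim_condition <- function(count, seed, n = 128, traceThreshold = 0.5,
                          mrCfg = mrSynthesisConfig(randomSeed = seed)) {
  spec <- headPhantomSpec(n)
  clean <- makePhantom(spec)
  geom <- geometryFor(clean)
  clean_rt <- fbpReconstruct(forwardProject(clean, geom), dim(clean))
  imp <- sampleImplantSpec(spec, count, seed = seed)
  ins <- insertImplants(clean, imp)
  sim <- simulateArtifactCT(ins$ct, ins$mask, geom,
                            physicsConfig(randomSeed = seed,
                                          traceThreshold = traceThreshold))
  mr <- synthesizeMR(clean, ins$mask, mrCfg)
  list(spec = spec, clean = clean, clean_rt = clean_rt, geom = geom,
       metal = ins$mask, ct_metal = ins$ct, artifact = sim$ct,
       trace = sim$trace, sinogram = sim$sinogram, mr = mr)
}

# independent ray-integration line-integral oracle (pure R, trapezoid-free
# fixed-step sampling like the projector's definition, written separately)
ray_integral_oracle <- function(px, angle_deg, s_offsets, step = 0.25) {
  nr <- nrow(px); nc <- ncol(px)
  cr0 <- (nr - 1) / 2; cc0 <- (nc - 1) / 2
  th <- angle_deg * pi / 180
  half <- 0.5 * sqrt(nr^2 + nc^2) + 2
  tvals <- seq(-half, half, by = step)
  vapply(s_offsets, function(s) {
    x <- s * cos(th) - tvals * sin(th)
    y <- s * sin(th) + tvals * cos(th)
    col <- x + cc0
    row <- cr0 - y
    r0 <- floor(row); c0 <- floor(col)
    fr <- row - r0; fc <- col - c0
    val <- numeric(length(tvals))
    for (dr in 0:1) for (dc in 0:1) {
      ri <- r0 + dr; ci <- c0 + dc
      w <- (if (dr == 0) 1 - fr else fr) * (if (dc == 0) 1 - fc else fc)
      ok <- ri >= 0 & ri < nr & ci >= 0 & ci < nc
      val[ok] <- val[ok] + w[ok] * px[cbind(ri[ok] + 1, ci[ok] + 1)]
    }
    sum(val) * step
  }, numeric(1))
}

# exhaustive multi-Otsu oracle: enumerate all threshold placements
exhaustive_otsu <- function(counts, mids, n_classes) {
  p <- counts / sum(counts)
  nb <- length(counts)
  score <- function(cuts) {
    bounds <- c(0L, cuts, nb)
    s <- 0
    for (k in seq_len(n_classes)) {
      idx <- (bounds[k] + 1L):bounds[k + 1L]
      w <- sum(p[idx])
      if (w > 0) s <- s + sum(p[idx] * mids[idx])^2 / w
    }
    s
  }
  combos <- utils::combn(nb - 1L, n_classes - 1L)
  best <- -Inf; best_cuts <- NULL
  for (i in seq_len(ncol(combos))) {
    sc <- score(combos[, i])
    if (sc > best) { best <- sc; best_cuts <- combos[, i] }
  }
  list(objective = best, cuts = best_cuts)
}

# classic two-class Otsu by direct between-class variance sweep
classic_otsu_cut <- function(counts, mids) {
  p <- counts / sum(counts)
  best <- -Inf; cut <- NA_integer_
  for (t in seq_len(length(counts) - 1L)) {
    w0 <- sum(p[1:t]); w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(p[1:t] * mids[1:t]) / w0
    mu1 <- sum(p[(t + 1):length(p)] * mids[(t + 1):length(p)]) / w1
    v <- w0 * w1 * (mu0 - mu1)^2
    if (v > best) { best <- v; cut <- t }
  }
  cut
}

# brute-force donor reference: full sort of all candidates with explicit
# row-major tie-keys, scanning in reverse order to cross-check order
# independence of the ranking
donor_reference <- function(mr_win, corrupt_win) {
  w <- nrow(mr_win)
  m <- (w - 1L) %/% 2L
  ctr <- mr_win[m + 1L, m + 1L]
  cand <- NULL
  for (r in seq_len(w)) for (c in seq_len(w)) {
    if (r == m + 1L && c == m + 1L) next
    cand <- rbind(cand, data.frame(r = r, c = c,
                                   key = abs(mr_win[r, c] - ctr),
                                   scan = (r - 1L) * w + c))
  }
  cand <- cand[order(cand$key, cand$scan), ]
  for (i in seq_len(nrow(cand))) {
    if (!corrupt_win[cand$r[i], cand$c[i]])
      return(c(cand$r[i] - m - 1L, cand$c[i] - m - 1L))
  }
  NULL
}
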