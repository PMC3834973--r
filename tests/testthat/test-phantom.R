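test_that("makePhantom rasterizes ellipses deterministically", {
  spec <- phantomSpec(c(32, 32), list(
    list(center = c(16.5, 16.5), axes = c(10, 8), rotation = 0,
         intensity = 0.3)))
  ph <- makePhantom(spec)
  expect_setequal(unique(as.vector(pixels(ph))), c(0, 0.3))
  expect_identical(pixels(makePhantom(spec)), pixels(ph))

  head <- makePhantom(headPhantomSpec(128))
  expect_equal(pixels(head)[64, 64], 0.35)   # interior soft tissue
  expect_equal(pixels(head)[1, 1], 0)        # air at the corner

  bad <- phantomSpec(c(32, 32), list(
    list(center = c(2, 2), axes = c(10, 10), rotation = 0, intensity = 1)))
  expect_error(makePhantom(bad), "outside")
})

test_that("insertImplants paints disks matching a distance oracle", {
  clean <- makePhantom(headPhantomSpec(64))
  none <- insertImplants(clean, implantSpec())
  expect_identical(pixels(none$ct), pixels(clean))
  expect_false(any(flags(none$mask)))

  ctr <- c(48, 32); rad <- 2
  one <- insertImplants(clean, implantSpec(matrix(ctr, 1), rad))
  oracle <- outer(seq_len(64), seq_len(64), function(r, c)
    (r - ctr[1])^2 + (c - ctr[2])^2 <= rad^2)
  expect_identical(flags(one$mask), oracle)
  expect_true(all(pixels(one$ct)[oracle] == 3.0))

  # union of single-implant masks
  spec <- headPhantomSpec(128)
  cl <- makePhantom(spec)
  imp3 <- sampleImplantSpec(spec, 3L, seed = 1L)
  all3 <- insertImplants(cl, imp3)$mask
  singles <- lapply(1:3, function(i)
    insertImplants(cl, implantSpec(imp3@centers[i, , drop = FALSE],
                                   imp3@radii[i]))$mask)
  expect_identical(flags(all3),
                   flags(singles[[1]]) | flags(singles[[2]]) |
                     flags(singles[[3]]))

  air <- implantSpec(matrix(c(3, 3), 1), 2)
  expect_error(insertImplants(clean, air), "outside the body")
})

test_that("identity physics reduces the simulator to the FBP round trip", {
  cond0 <- sim_condition(1L, seed = 0L)
  phys <- physicsConfig(saturationCap = Inf, beamHardeningGamma = 1,
                        noisePhotons = Inf)
  sim <- simulateArtifactCT(cond0$ct_metal, cond0$metal, cond0$geom, phys)
  plain <- fbpReconstruct(forwardProject(cond0$ct_metal, cond0$geom),
                          dim(cond0$ct_metal))
  expect_lt(max(abs(pixels(sim$ct) - pixels(plain))), 1e-10)
})

test_that("metal corruption adds error outside the metal, reproducibly", {
  worse <- sapply(0:4, function(sd) {
    spec <- headPhantomSpec(96)
    clean <- makePhantom(spec)
    geom <- geometryFor(clean, nAngles = 120L)
    clean_rt <- fbpReconstruct(forwardProject(clean, geom), dim(clean))
    phys <- physicsConfig(randomSeed = sd)
    base <- simulateArtifactCT(clean, artifactMask(matrix(FALSE, 96, 96)),
                               geom, phys)
    ins <- insertImplants(clean, sampleImplantSpec(spec, 2L, seed = sd))
    sim <- simulateArtifactCT(ins$ct, ins$mask, geom, phys)
    roi <- !flags(ins$mask)
    rmse(sim$ct, clean_rt, roi) > rmse(base$ct, clean_rt, roi)
  })
  expect_true(all(worse))

  cond_a <- sim_condition(2L, seed = 3L, n = 96)
  cond_b <- sim_condition(2L, seed = 3L, n = 96)
  expect_identical(pixels(cond_a$artifact), pixels(cond_b$artifact))
})

test_that("streak energy grows with implant count on average", {
  energy <- function(count) {
    mean(sapply(0:4, function(sd) {
      spec <- headPhantomSpec(96)
      clean <- makePhantom(spec)
      geom <- geometryFor(clean, nAngles = 120L)
      clean_rt <- fbpReconstruct(forwardProject(clean, geom), dim(clean))
      ins <- insertImplants(clean, sampleImplantSpec(spec, count, seed = sd))
      sim <- simulateArtifactCT(ins$ct, ins$mask, geom,
                                physicsConfig(randomSeed = sd))
      stats::var((pixels(sim$ct) - pixels(clean_rt))[!flags(ins$mask)])
    }))
  }
  e <- vapply(1:3, energy, numeric(1))
  expect_true(all(diff(e) > 0))
})

test_that("pseudo-MR synthesis obeys remap, void and seeding contracts", {
  clean <- makePhantom(headPhantomSpec(64))
  none <- artifactMask(matrix(FALSE, 64, 64))
  levels <- sort(unique(as.vector(pixels(clean))))
  ident <- mrSynthesisConfig(ctLevels = levels, mrLevels = levels,
                             smoothSigma = 0, noiseSigma = 0)
  expect_identical(pixels(synthesizeMR(clean, none, ident)), pixels(clean))

  # signal void: zero disk around metal matching the distance oracle
  metal <- matrix(FALSE, 64, 64); metal[40, 30] <- TRUE
  cfg <- mrSynthesisConfig(voidRadius = 3, smoothSigma = 0, noiseSigma = 0)
  mr <- synthesizeMR(clean, artifactMask(metal), cfg)
  d2 <- outer(seq_len(64), seq_len(64), function(r, c)
    (r - 40)^2 + (c - 30)^2)
  expect_true(all(pixels(mr)[d2 <= 9] == 0))
  expect_true(all(pixels(mr)[d2 > 16] > 0))

  noisy <- function(seed) pixels(synthesizeMR(
    clean, none, mrSynthesisConfig(noiseSigma = 0.05, randomSeed = seed)))
  expect_identical(noisy(1L), noisy(1L))
  expect_false(identical(noisy(1L), noisy(2L)))

  # rigid misregistration knob: integer shift with edge replication
  shifted <- synthesizeMR(clean, none,
                          mrSynthesisConfig(smoothSigma = 0, noiseSigma = 0,
                                            shift = c(2L, 0L)))
  unshifted <- synthesizeMR(clean, none,
                            mrSynthesisConfig(smoothSigma = 0, noiseSigma = 0))
  expect_identical(pixels(shifted)[3:64, ], pixels(unshifted)[1:62, ])

  expect_error(mrSynthesisConfig(noiseSigma = -1), "sigmas")
})
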