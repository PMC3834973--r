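test_that("padReplicate replicates borders and preserves the interior", {
  one <- imageGrid(matrix(7, 1, 1))
  p <- padReplicate(one, 2L)
  expect_equal(pixels(p), matrix(7, 5, 5))

  g <- random_grid(8, seed = 2)
  p <- pixels(padReplicate(g, 2L))
  expect_equal(p[3:10, 3:10], pixels(g))
  expect_equal(p[1, 1], pixels(g)[1, 1])
  expect_equal(p[12, 12], pixels(g)[8, 8])
  # margins beyond the image size keep replicating the nearest pixel
  big <- pixels(padReplicate(g, 9L))
  expect_equal(dim(big), c(26L, 26L))
  expect_equal(big[1, 1], pixels(g)[1, 1])
  expect_error(padReplicate(g, -1L), ">= 0")
})

test_that("findDonor picks the most MR-similar uncorrupted neighbor", {
  mr <- matrix(5, 5, 5)
  mr[2, 4] <- 5        # exact match, everything else off
  mr[-2, ] <- mr[-2, ] + 3
  mr[2, -4] <- mr[2, -4] + 2
  mr[3, 3] <- 5
  corrupt <- matrix(FALSE, 5, 5); corrupt[3, 3] <- TRUE
  d <- findDonor(mr, corrupt)
  expect_equal(c(d$dr, d$dc), c(-1L, 1L))

  all_bad <- matrix(TRUE, 5, 5)
  expect_null(findDonor(mr, all_bad))
})

test_that("findDonor matches the full-sort brute-force reference", {
  set.seed(123)
  for (trial in 1:200) {
    # quantized MR values force frequent ties; random corruption patterns
    mr <- matrix(sample(0:5, 25, replace = TRUE) / 5, 5, 5)
    corrupt <- matrix(runif(25) < 0.5, 5, 5)
    corrupt[3, 3] <- TRUE
    got <- findDonor(mr, corrupt)
    ref <- donor_reference(mr, corrupt)
    if (is.null(ref)) {
      expect_null(got)
    } else {
      expect_equal(c(got$dr, got$dc), ref)
    }
  }
})

test_that("uncorrupted pixels are left undisturbed, bit-exact", {
  ct <- random_grid(32, seed = 4)
  mr <- random_grid(32, seed = 5)
  empty <- artifactMask(matrix(FALSE, 32, 32))
  out <- correctImage(ct, mr, empty)
  expect_identical(pixels(out$ct), pixels(ct))

  set.seed(6)
  mk <- matrix(runif(32 * 32) < 0.2, 32, 32)
  out <- correctImage(ct, mr, artifactMask(mk))
  expect_identical(pixels(out$ct)[!mk], pixels(ct)[!mk])
})

test_that("a unique MR-identical neighbor donates its CT value", {
  ct <- imageGrid(matrix(runif(49), 7, 7))
  mrm <- matrix(seq(0, 4.8, length.out = 49), 7, 7)
  mrm[3, 5] <- mrm[4, 4]            # only neighbor matching the MR center
  mr <- imageGrid(mrm)
  mk <- matrix(FALSE, 7, 7); mk[4, 4] <- TRUE
  out <- correctImage(ct, mr, artifactMask(mk))
  expect_identical(pixels(out$ct)[4, 4], pixels(ct)[3, 5])
  expect_false(any(flags(out$residual)))
})

test_that("correctImage matches an independent reference implementation", {
  # straightforward nested-loop reference for the sliding-window scheme:
  # pad, rank candidates by |MR - center| with row-major tie order, donors
  # read from the pre-pass CT, pixels fixed in pass p donate in pass p+1;
  # scans pixels in reverse order to double as an order-independence check
  reference_correct <- function(ct, mr, mask, window = 5L, passes = 5L) {
    m <- (window - 1L) %/% 2L
    pad <- function(x) {
      ri <- c(rep(1, m), seq_len(nrow(x)), rep(nrow(x), m))
      ci <- c(rep(1, m), seq_len(ncol(x)), rep(ncol(x), m))
      x[ri, ci]
    }
    mr_p <- pad(mr)
    for (p in seq_len(passes)) {
      if (!any(mask)) break
      ct_p <- pad(ct); mk_p <- pad(mask)
      nxt_ct <- ct; nxt_mk <- mask
      idx <- which(mask, arr.ind = TRUE)
      for (t in rev(seq_len(nrow(idx)))) {
        r <- idx[t, 1]; c <- idx[t, 2]
        best <- NULL
        for (dr in -m:m) for (dc in -m:m) {
          if (dr == 0 && dc == 0) next
          key <- abs(mr_p[r + m + dr, c + m + dc] - mr_p[r + m, c + m])
          if (!mk_p[r + m + dr, c + m + dc]) {
            # strict < keeps the first (row-major) candidate among ties
            if (is.null(best) || key < best$key)
              best <- list(key = key, dr = dr, dc = dc)
          }
        }
        if (!is.null(best)) {
          nxt_ct[r, c] <- ct_p[r + m + best$dr, c + m + best$dc]
          nxt_mk[r, c] <- FALSE
        }
      }
      ct <- nxt_ct; mask <- nxt_mk
    }
    list(ct = ct, residual = mask)
  }

  set.seed(77)
  ctm <- matrix(runif(32 * 32), 32, 32)
  # quantized MR induces similarity ties, exercising the row-major rule
  mrm <- matrix(sample(0:7, 32 * 32, replace = TRUE) / 7, 32, 32)
  mk <- matrix(runif(32 * 32) < 0.2, 32, 32)
  mk[1, ] <- FALSE   # keep at least one uncorrupted pixel everywhere
  got <- correctImage(imageGrid(ctm), imageGrid(mrm), artifactMask(mk),
                      correctionConfig(fallback = "leave"))
  ref <- reference_correct(ctm, mrm, mk)
  expect_identical(flags(got$residual), ref$residual)
  expect_identical(pixels(got$ct)[!ref$residual], ref$ct[!ref$residual])
})

test_that("later passes use pixels corrected in earlier passes as donors", {
  # a 3-wide corrupted block: its center has no clean donor in pass 1
  ct <- imageGrid(matrix(1, 9, 9))
  px <- pixels(ct); px[, 4:6] <- 9; ct <- imageGrid(px)
  mr <- imageGrid(matrix(1, 9, 9))
  mk <- matrix(FALSE, 9, 9); mk[, 3:7] <- TRUE
  one_pass <- correctImage(ct, mr, artifactMask(mk),
                           correctionConfig(maxPasses = 1L, fallback = "leave"))
  expect_true(any(flags(one_pass$residual)))
  multi <- correctImage(ct, mr, artifactMask(mk),
                        correctionConfig(maxPasses = 5L, fallback = "leave"))
  expect_false(any(flags(multi$residual)))
})

test_that("every corrected value originates from an unmasked input pixel", {
  set.seed(8)
  ct <- random_grid(24, seed = 8)
  mr <- random_grid(24, seed = 9)
  mk <- matrix(runif(24 * 24) < 0.25, 24, 24)
  mk[12, ] <- FALSE
  out <- correctImage(ct, mr, artifactMask(mk),
                      correctionConfig(fallback = "leave"))
  fixed <- mk & !flags(out$residual)
  legal <- pixels(ct)[!mk]
  expect_true(all(pixels(out$ct)[fixed] %in% legal))
})

test_that("degenerate masks and shape mismatches are rejected", {
  ct <- random_grid(8, seed = 1)
  mr <- random_grid(8, seed = 2)
  expect_error(correctImage(ct, mr, artifactMask(matrix(TRUE, 8, 8))),
               "no uncorrupted pixels")
  expect_error(correctImage(ct, random_grid(9, seed = 2),
                            artifactMask(matrix(FALSE, 8, 8))),
               "shape mismatch")
})

test_that("metal reinsertion restores input values inside the metal mask", {
  ct <- random_grid(16, seed = 10)
  mr <- random_grid(16, seed = 11)
  mk <- matrix(FALSE, 16, 16); mk[6:10, 6:10] <- TRUE
  metal <- matrix(FALSE, 16, 16); metal[7:9, 7:9] <- TRUE
  out <- correctImage(ct, mr, artifactMask(mk),
                      correctionConfig(reinsertMetal = TRUE),
                      metalMask = artifactMask(metal))
  expect_identical(pixels(out$ct)[metal], pixels(ct)[metal])
})
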