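test_that("a ball is its own maximal sphere", {
  b <- ballMask(5, spacingUm = 1)
  lt <- voxelData(localThickness(b))
  fg <- voxelData(b)
  expect_true(all(abs(lt[fg] - 5) <= 1))
  expect_true(all(lt[!fg] == 0))
})

test_that("cylinder cores carry the tube radius; scaling follows spacing", {
  cy <- cylinderMask(5, 60, spacingUm = 62)
  lt <- voxelData(localThickness(cy))
  core <- lt[10, 10, 20:45]
  expect_true(all(abs(core / 62 - 5) <= 1))
})

test_that("an isolated voxel has half-spacing thickness", {
  a <- array(FALSE, c(5, 5, 5))
  a[3, 3, 3] <- TRUE
  lt <- localThickness(BinaryMask(a, spacing = 62))
  expect_equal(voxelData(lt)[3, 3, 3], 31)
})

test_that("the diameter convention doubles the field", {
  b <- ballMask(4, spacingUm = 1)
  r <- voxelData(localThickness(b))
  d <- voxelData(localThickness(b, convention = "diameter"))
  expect_equal(d, 2 * r)
})

test_that("local thickness matches the brute-force maximal-sphere oracle", {
  withSeed(31, {
    for (i in 1:6) {
      dims <- c(sample(8:14, 1), sample(8:14, 1), sample(8:14, 1))
      m <- randomBlobMask(dims, nBlobs = sample(2:4, 1))
      if (!any(voxelData(m))) next
      lt <- voxelData(localThickness(m))
      oracle <- bruteLocalThickness(m)
      expect_lt(max(abs(lt - oracle)), 1 + 1e-6)
    }
  })
})

test_that("thickness never falls below the inscribed-sphere radius at a voxel", {
  withSeed(32, {
    m <- randomBlobMask(c(15, 15, 15), nBlobs = 3)
    lt <- voxelData(localThickness(m))
    rad <- distanceTransform(m) - 0.5
    fg <- voxelData(m)
    expect_true(all(lt[fg] >= rad[fg] - 1e-9))
  })
})

test_that("dilation never decreases local thickness", {
  withSeed(33, {
    m <- randomBlobMask(c(12, 12, 12), nBlobs = 2)
    a <- voxelData(m)
    dil <- a
    for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
      sh <- array(FALSE, dim(a))
      zi <- pmax(1, 1 + dz):pmin(dim(a)[1], dim(a)[1] + dz)
      sh[zi, pmax(1, 1 + dy):pmin(dim(a)[2], dim(a)[2] + dy),
         pmax(1, 1 + dx):pmin(dim(a)[3], dim(a)[3] + dx)] <-
        a[zi - dz, pmax(1, 1 + dy):pmin(dim(a)[2], dim(a)[2] + dy) - dy,
          pmax(1, 1 + dx):pmin(dim(a)[3], dim(a)[3] + dx) - dx]
      dil <- dil | sh
    }
    lt1 <- voxelData(localThickness(m))
    lt2 <- voxelData(localThickness(BinaryMask(dil, spacing(m))))
    fg <- voxelData(m)
    expect_true(all(lt2[fg] >= lt1[fg] - 1e-9))
  })
})

test_that("thickness histograms are unimodal for tubes, bimodal for mixtures", {
  cy <- cylinderMask(5, 40, spacingUm = 1)
  h <- thicknessHistogram(localThickness(cy), binWidthUm = 1)
  occupied <- h$count > 0.05 * sum(h$count)
  expect_lte(sum(occupied), 2)

  a3 <- voxelData(cylinderMask(3, 40, spacingUm = 1, padVx = 3L))
  a9 <- voxelData(cylinderMask(9, 40, spacingUm = 1, padVx = 3L))
  big <- array(FALSE, c(dim(a3)[1] + dim(a9)[1], dim(a9)[2], dim(a9)[3]))
  big[seq_len(dim(a3)[1]), seq_len(dim(a3)[2]), seq_len(dim(a3)[3])] <- a3
  big[dim(a3)[1] + seq_len(dim(a9)[1]), , ] <- a9
  lt <- localThickness(BinaryMask(big, spacing = 1))
  h2 <- thicknessHistogram(lt, binWidthUm = 1)
  peaks <- h2$bin_lo_um[h2$count > 0.1 * max(h2$count)]
  expect_true(any(peaks <= 3) && any(peaks >= 7))

  labs <- LabelVolume(array(0L, dim(big)),
                      labelNames = c("1" = "empty"), spacing = 1)
  h3 <- thicknessHistogram(lt, labs, binWidthUm = 1)
  expect_true(all(h3$count[h3$label == "empty"] == 0))
})

test_that("lognormal fitting is a proper MLE with edge handling", {
  x <- withSeed(5, rlnorm(10000, 0.5, 0.3))
  f <- fitLognormal(x)
  expect_lt(abs(f$mu - 0.5), 0.02)
  expect_lt(abs(f$sigma - 0.3), 0.02)
  expect_lt(f$ks, 0.02)

  ref <- suppressWarnings(
    fitdistrplus::fitdist(x, "lnorm", method = "mle"))
  expect_equal(unname(f$mu), unname(ref$estimate[["meanlog"]]),
               tolerance = 1e-3)
  expect_equal(unname(f$sigma), unname(ref$estimate[["sdlog"]]),
               tolerance = 1e-3)

  cst <- fitLognormal(rep(2.5, 20))
  expect_identical(cst$sigma, 0)
  expect_identical(cst$ks, 0)

  expect_error(fitLognormal(c(rep(1, 12), 0)), "positive")
  expect_error(fitLognormal(1:5), "10 samples")
})
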