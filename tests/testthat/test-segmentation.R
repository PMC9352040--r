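test_that("Otsu picks the lowest maximizing cut for symmetric two-class data", {
  h <- integer(256)
  h[11] <- 100
  h[201] <- 100
  expect_identical(otsuThreshold(h), 10L)
})

test_that("Otsu matches an exhaustive between-class-variance oracle", {
  withSeed(21, {
    for (i in 1:60) {
      h <- integer(256)
      nz <- sample(2:40, 1)
      h[sample(256, nz)] <- sample(1:500, nz, replace = TRUE)
      expect_identical(otsuThreshold(h), naiveOtsu(h))
    }
  })
})

test_that("degenerate histograms are rejected", {
  h <- integer(256)
  h[42] <- 1000
  expect_error(otsuThreshold(h), "degenerate")
  expect_error(otsuThreshold(integer(100)), "256")
})

test_that("segmentation recovers a noise-free phantom exactly", {
  ph <- voxelize(PhantomSpec(straightSegment(c(0, 0, 0), c(0, 0, 1860),
                                             radiusUm = 186),
                             grayscale = c(200, 30, 0)),
                 spacingUm = 62, noise = FALSE)
  m <- segmentVolume(ph$volume)
  expect_identical(voxelData(m), voxelData(ph$truth@occupancy))
})

test_that("segmentation tolerates moderate gray noise", {
  ph <- voxelize(PhantomSpec(straightSegment(c(0, 0, 0), c(0, 0, 1860),
                                             radiusUm = 186),
                             grayscale = c(200, 30, 10), seed = 3),
                 spacingUm = 62)
  m <- segmentVolume(ph$volume)
  agree <- mean(voxelData(m) == voxelData(ph$truth@occupancy))
  expect_gte(agree, 0.99)
})

test_that("constant volumes cannot be segmented", {
  expect_error(segmentVolume(VoxelVolume(array(7L, c(4, 4, 4)))),
               "degenerate")
})

test_that("connectivity-preserving smoothing keeps components and volume", {
  cyl <- cylinderMask(6, 20)
  sm <- smoothPreservingConnectivity(cyl)
  expect_equal(length(connectedComponents(sm)$sizes), 1L)
  expect_lt(abs(sum(voxelData(sm)) / sum(voxelData(cyl)) - 1), 0.1)

  a <- voxelData(ballMask(3, padVx = 8L))
  b <- array(FALSE, dim(a) + c(0L, 0L, 14L))
  b[, , seq_len(dim(a)[3])] <- a
  b[, , 14L + seq_len(dim(a)[3])] <- b[, , 14L + seq_len(dim(a)[3])] | a
  twoMask <- BinaryMask(b, spacing = 62)
  expect_equal(length(connectedComponents(twoMask)$sizes), 2L)
  sm2 <- smoothPreservingConnectivity(twoMask)
  expect_equal(length(connectedComponents(sm2)$sizes), 2L)

  empty <- BinaryMask(array(FALSE, c(5, 5, 5)))
  expect_identical(voxelData(smoothPreservingConnectivity(empty)),
                   voxelData(empty))
})

test_that("connected components obey the 6/18/26 neighbourhood definitions", {
  a <- array(FALSE, c(3, 3, 3))
  a[1, 1, 1] <- a[3, 3, 3] <- TRUE
  cc <- connectedComponents(BinaryMask(a))
  expect_identical(cc$sizes, c(1L, 1L))

  l <- array(FALSE, c(4, 4, 4))
  l[1:3, 2, 2] <- TRUE
  l[3, 2:4, 2] <- TRUE
  expect_equal(length(connectedComponents(BinaryMask(l), 6L)$sizes), 1L)

  dg <- array(FALSE, c(3, 3, 3))
  dg[1, 1, 1] <- dg[2, 2, 1] <- TRUE
  expect_equal(length(connectedComponents(BinaryMask(dg), 6L)$sizes), 2L)
  expect_equal(length(connectedComponents(BinaryMask(dg), 26L)$sizes), 1L)

  labs <- connectedComponents(BinaryMask(l), 26L)$labels
  expect_s4_class(labs, "LabelVolume")
  expect_true(all(voxelData(labs)[l] == 1L))
})
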