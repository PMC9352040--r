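test_that("thinning preserves topology on ball, cylinder and torus", {
  b <- ballMask(6)
  skb <- skeletonize(b)
  expect_identical(eulerCharacteristic(b), 1L)
  expect_identical(eulerCharacteristic(skb), 1L)
  expect_lte(sum(voxelData(skb)), 8)

  cy <- cylinderMask(4, 40)
  skc <- skeletonize(cy)
  expect_identical(eulerCharacteristic(skc), 1L)
  g <- buildGraph(skc)
  expect_identical(unname(graphCounts(g)), c(1L, 0L, 2L))
  expect_true(all(voxelData(skc) <= voxelData(cy)))

  to <- torusMask(10, 3)
  skt <- skeletonize(to)
  expect_identical(eulerCharacteristic(to), 0L)
  expect_identical(eulerCharacteristic(skt), 0L)
  gt <- buildGraph(skt)
  expect_identical(sum(gt@nodes$type == "endpoint"), 0L)
  expect_true(any(gt@branches$isLoop))
})

test_that("thinning preserves the component count of multi-object masks", {
  a <- voxelData(ballMask(3, padVx = 3L))
  b <- array(FALSE, dim(a) + c(0L, 0L, 12L))
  b[, , seq_len(dim(a)[3])] <- a
  b[, , 12L + seq_len(dim(a)[3])] <- b[, , 12L + seq_len(dim(a)[3])] | a
  m <- BinaryMask(b, spacing = 62)
  sk <- skeletonize(m)
  expect_equal(
    length(connectedComponents(BinaryMask(voxelData(sk), spacing(sk)))$sizes),
    length(connectedComponents(m)$sizes))
})

test_that("pruning removes short terminal twigs and only those", {
  skT <- ySkeleton(twigVx = 3)
  expect_identical(unname(graphCounts(buildGraph(skT))), c(4L, 1L, 4L))
  pr <- pruneSkeleton(skT, 4, 2)
  expect_identical(unname(graphCounts(buildGraph(pr))), c(3L, 1L, 3L))

  skL <- ySkeleton(twigVx = 9)
  pr2 <- pruneSkeleton(skL, 4, 2)
  expect_identical(unname(graphCounts(buildGraph(pr2))), c(4L, 1L, 4L))

  # a pruned twig that demotes the junction merges the flanking branches
  aa <- array(FALSE, c(9, 9, 30))
  aa[5, 5, 2:28] <- TRUE          # straight path
  aa[6:8, 5, 15] <- TRUE          # 3-voxel twig off the middle
  sk3 <- new("Skeleton", data = aa, ltLabel = array(numeric(0), c(0L, 0L, 0L)),
             spacing = c(62, 62, 62), origin = c(0, 0, 0))
  g3 <- buildGraph(pruneSkeleton(sk3, 4, 2))
  expect_identical(unname(graphCounts(g3)), c(1L, 0L, 2L))
})

test_that("closed loops and isolated paths resist pruning", {
  to <- torusMask(8, 2)
  sk <- skeletonize(to)
  pr <- pruneSkeleton(sk, 4, 2)
  expect_identical(voxelData(pr), voxelData(sk))

  p <- pathSkeleton(3)             # entire component shorter than the limit
  pr2 <- pruneSkeleton(p, 4, 2)
  expect_identical(voxelData(pr2), voxelData(p))
})

test_that("thickness labelling transfers calibre onto the medial axis", {
  cy <- cylinderMask(5, 40, spacingUm = 1)
  lt <- localThickness(cy)
  sk <- labelWithThickness(pruneSkeleton(skeletonize(cy)), lt)
  lab <- sk@ltLabel[voxelData(sk)]
  expect_true(all(abs(lab - 5) <= 1))

  # tapering cone: labels increase monotonically along the axis
  cone <- voxelize(PhantomSpec(straightSegment(c(0, 0, 0), c(0, 0, 3720),
                                               radiusUm = 124,
                                               radiusEndUm = 372),
                               grayscale = c(200, 30, 0)),
                   spacingUm = 62, noise = FALSE)
  m <- cone$truth@occupancy
  skc <- labelWithThickness(pruneSkeleton(skeletonize(m)), localThickness(m))
  g <- buildGraph(skc)
  path <- g@paths[[which.max(g@branches$pathLengthUm)]]
  labs <- skc@ltLabel[path]
  sm <- stats::filter(labs, rep(1 / 5, 5))
  sm <- sm[!is.na(sm)]
  expect_true(all(diff(sm) > -2))
  expect_gt(labs[length(labs)] - labs[1], 150)

  other <- cylinderMask(3, 20, spacingUm = 1)
  expect_error(labelWithThickness(skeletonize(cylinderMask(5, 40,
                                                           spacingUm = 1)),
                                  localThickness(other)))
})
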