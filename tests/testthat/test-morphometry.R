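test_that("label volumes are voxel counts times physical voxel volume", {
  a <- array(0L, c(10, 10, 10))
  a[1:10, , ] <- 1L
  v <- volumeByLabel(LabelVolume(a, c("1" = "umbrella"), spacing = 62))
  expect_equal(unname(v[["umbrella"]]), 1000 * 62^3 / 1e12)
  expect_equal(unname(v[["total"]]), unname(v[["umbrella"]]))

  ball <- ballMask(20, spacingUm = 62, padVx = 1L)
  lab <- LabelVolume(array(as.integer(voxelData(ball)), dim(voxelData(ball))),
                     c("1" = "ball"), spacing = 62)
  analytic <- (4 / 3) * pi * 20^3 * 62^3 / 1e12
  expect_lt(abs(volumeByLabel(lab)[["ball"]] / analytic - 1), 0.02)

  a2 <- array(0L, c(4, 4, 4))
  a2[1, 1, 1] <- 2L
  v2 <- volumeByLabel(LabelVolume(a2, c("1" = "gone", "2" = "there"),
                                  spacing = 62))
  expect_identical(unname(v2[["gone"]]), 0)
})

test_that("disjoint label partitions sum exactly to the total volume", {
  withSeed(51, {
    a <- array(sample(0:3, 6 * 7 * 8, replace = TRUE), c(6, 7, 8))
    v <- volumeByLabel(LabelVolume(a, spacing = 62))
    expect_equal(sum(v[-1]), unname(v[["total"]]))
  })
})

test_that("endpoints are assigned to the substructure at their voxel", {
  ph <- makeArmPhantom(c(4, 3, 3), 2, seed = 2, noise = FALSE)
  rep <- runPipeline(pipelineConfig(input = ph$volume, labels = ph$labels))
  op <- rep@openings
  expect_equal(unname(op[["wing_inner"]]), 4)
  expect_equal(unname(op[["wing_outer_1"]]), 3)
  expect_equal(unname(op[["wing_outer_2"]]), 3)
  expect_equal(unname(op[["central_canal"]]), 2)
})

test_that("endpoints on unlabelled voxels are warned and counted apart", {
  sk <- pathSkeleton(11)
  g <- buildGraph(sk)
  lab <- LabelVolume(array(0L, dim(voxelData(sk))),
                     labelNames = c("1" = "canal"),
                     spacing = spacing(sk))
  expect_warning(cnt <- endpointCountsByLabel(g, lab), "unlabelled")
  expect_identical(unname(cnt[["unassigned"]]), 2L)
})

test_that("whole-organism extrapolation reproduces the printed totals", {
  ex <- extrapolateOpenings(234, c(129, 128), 81, 8)
  expect_identical(ex$innerTotal, 1953L)
  expect_identical(ex$outerTotal, 2056L)

  expect_identical(extrapolateOpenings(0, c(0, 0), 0, 8)$innerTotal, 0L)
  u <- extrapolateOpenings(1, 1, 1, 1)
  expect_identical(c(u$innerTotal, u$outerTotal), c(2L, 1L))
  expect_error(extrapolateOpenings(-1, 1, 1), "non-negative")

  # linearity in each argument
  withSeed(52, {
    for (i in 1:5) {
      a <- sample(0:50, 1); b <- sample(0:50, 2); cc <- sample(0:50, 1)
      e1 <- extrapolateOpenings(a, b, cc, 8)
      e2 <- extrapolateOpenings(2 * a, 2 * b, 2 * cc, 8)
      expect_identical(e2$innerTotal, 2L * e1$innerTotal)
      expect_identical(e2$outerTotal, 2L * e1$outerTotal)
    }
  })
})

test_that("apparent diameter follows the hemisphere arc relation", {
  expect_equal(apparentDiameter(pi / 2), 1)
  expect_equal(apparentDiameter(22.9), 14.58, tolerance = 1e-3)
  expect_error(apparentDiameter(0), "> 0")
  withSeed(53, {
    rd <- runif(5, 1, 50)
    expect_equal(apparentDiameter(rd) / rd, rep(2 / pi, 5))
  })
})

test_that("adherence ratio is a guarded quotient", {
  expect_equal(adherenceRatio(3.5, 10), 0.35)
  expect_equal(adherenceRatio(7, 7), 1)
  expect_error(adherenceRatio(8, 7))
  expect_error(adherenceRatio(1, 0))
})

test_that("reports round-trip through JSON with explicit nulls", {
  rep <- makeReport(
    volumes = c(total = 26.05, scapulae = 5.955),
    openings = c(wing_inner = 234, wing_outer_1 = 129),
    extrapolation = extrapolateOpenings(234, c(129, 128), 81, 8),
    scalars = list(apparentDiameterCm = 14.6),
    notes = "endpoint counts are approximate")
  f <- tempfile(fileext = ".json")
  writeReport(rep, f)
  back <- readReport(f)
  expect_equal(back@volumesCm3, rep@volumesCm3)
  expect_equal(back@openings, rep@openings)
  expect_identical(back@extrapolation$innerTotal, 1953L)
  expect_identical(back@notes, rep@notes)

  bare <- makeReport(openings = c(total = 5))
  f2 <- tempfile(fileext = ".json")
  writeReport(bare, f2)
  obj <- jsonlite::read_json(f2)
  expect_true("volumes_cm3" %in% names(obj))
  expect_null(obj$volumes_cm3)
})
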