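test_that("tree specs follow perfect-binary-tree combinatorics", {
  sp <- sampleTreeSpec(nLevels = 3, seed = 1)
  expect_identical(nrow(sp@segments), 7L)
  ph <- voxelize(sp, spacingUm = 62, noise = FALSE)
  expect_identical(ph$truth@counts$B, 7L)
  expect_identical(ph$truth@counts$J, 3L)
  expect_identical(ph$truth@counts$E, 5L)    # 4 leaves + the root opening
})

test_that("tree specs are deterministic and straight at tortuosity 1", {
  s1 <- sampleTreeSpec(nLevels = 3, seed = 42)
  s2 <- sampleTreeSpec(nLevels = 3, seed = 42)
  expect_identical(s1@segments, s2@segments)

  st <- sampleTreeSpec(nLevels = 2, tortuosity = 1, seed = 7)
  expect_true(all(is.na(st@segments$vz)))
  chord <- with(st@segments, sqrt((ez - sz)^2 + (ey - sy)^2 + (ex - sx)^2))
  expect_equal(chord, st@segments$lengthUm, tolerance = 1e-9)

  expect_error(sampleTreeSpec(tortuosity = 0.5), "tortuosity")
})

test_that("ground-truth topology satisfies the tree identity", {
  withSeed(61, {
    for (s in 1:8) {
      nl <- sample(2:4, 1)
      tr <- voxelize(sampleTreeSpec(nLevels = nl, seed = 300 + s),
                     spacingUm = 62, noise = FALSE)$truth
      expect_identical(tr@counts$B, tr@counts$E + tr@counts$J - 1L)
      expect_equal(tr@branches$tortuosity,
                   rep(0.8, nrow(tr@branches)), tolerance = 0.01)
    }
  })
})

test_that("voxelized tube volume approaches the analytic cylinder volume", {
  seg <- straightSegment(c(0, 0, 0), c(0, 0, 3100), radiusUm = 250)
  vTrue <- pi * 250^2 * 3100 / 1e12
  ph <- voxelize(PhantomSpec(seg), spacingUm = 62, noise = FALSE)
  expect_equal(ph$truth@volumeCm3, vTrue, tolerance = 1e-9)
  vox <- function(sp) {
    occ <- voxelize(PhantomSpec(seg), spacingUm = sp, noise = FALSE)
    sum(voxelData(occ$truth@occupancy)) * sp^3 / 1e12
  }
  e62 <- abs(vox(62) / vTrue - 1)
  expect_lt(e62, 0.03)
  e15 <- abs(vox(15.5) / vTrue - 1)     # two refinement levels
  expect_lt(e15, e62 / 2)
})

test_that("noise-free rendering has exactly two gray levels", {
  ph <- voxelize(PhantomSpec(straightSegment(c(0, 0, 0), c(0, 0, 1240),
                                             radiusUm = 186)),
                 spacingUm = 62, noise = FALSE)
  expect_identical(sort(unique(as.vector(voxelData(ph$volume)))),
                   c(30L, 200L))
})

test_that("rendering with a fixed seed is reproducible", {
  sp <- PhantomSpec(straightSegment(c(0, 0, 0), c(0, 0, 1240),
                                    radiusUm = 186), seed = 9)
  v1 <- voxelize(sp, spacingUm = 62)
  v2 <- voxelize(sp, spacingUm = 62)
  expect_identical(voxelData(v1$volume), voxelData(v2$volume))
})

test_that("paired hemi-canals are two components unless bridged", {
  expect_identical(length(connectedComponents(hemiCanalMask())$sizes), 2L)
  expect_identical(
    length(connectedComponents(hemiCanalMask(bridged = TRUE))$sizes), 1L)
})

test_that("the voxel budget is enforced and the arm phantom auto-coarsens", {
  seg <- straightSegment(c(0, 0, 0), c(0, 0, 50000), radiusUm = 2000)
  expect_error(voxelize(PhantomSpec(seg), spacingUm = 10,
                        maxVoxels = 1e5), "voxel budget")
  expect_warning(
    ph <- makeArmPhantom(c(3, 2, 2), 2, seed = 1, maxVoxels = 1e5,
                         noise = FALSE),
    "coarsening")
  expect_lte(prod(dim(voxelData(ph$volume))), 1e5)
})

test_that("arm phantoms carry the requested per-wing opening counts", {
  ph <- makeArmPhantom(c(5, 3, 4), 3, seed = 4, noise = FALSE)
  pl <- ph$truth@counts$perLabel
  expect_identical(pl$E[match("wing_inner", pl$labelName)], 5L)
  expect_identical(pl$E[match("wing_outer_1", pl$labelName)], 3L)
  expect_identical(pl$E[match("wing_outer_2", pl$labelName)], 4L)
  expect_identical(pl$E[match("central_canal", pl$labelName)], 3L)

  p1 <- makeArmPhantom(c(3, 2, 2), 2, seed = 8)
  p2 <- makeArmPhantom(c(3, 2, 2), 2, seed = 8)
  expect_identical(voxelData(p1$volume), voxelData(p2$volume))
})
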