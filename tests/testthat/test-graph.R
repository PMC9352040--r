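test_that("a straight voxel path is one branch with unit tortuosity", {
  g <- buildGraph(pathSkeleton(11, spacingUm = 62))
  expect_identical(unname(graphCounts(g)), c(1L, 0L, 2L))
  expect_equal(g@branches$pathLengthUm, 620)
  expect_equal(g@branches$euclideanDistanceUm, 620)
  expect_identical(g@branches$edOverLength, 1)
})

test_that("a symmetric Y decomposes into three branches around one junction", {
  g <- buildGraph(ySkeleton())
  expect_identical(unname(graphCounts(g)), c(3L, 1L, 3L))
  cnt <- graphCounts(g)
  expect_identical(unname(cnt["B"]), unname(cnt["E"] + cnt["J"] - 1L))
  expect_true(all(g@branches$edOverLength > 0 &
                  g@branches$edOverLength <= 1))
})

test_that("tortuosity stays in (0, 1] and is 1 only for collinear branches", {
  withSeed(41, {
    for (s in 1:5) {
      ph <- voxelize(sampleTreeSpec(nLevels = 2, seed = 40 + s),
                     spacingUm = 62)
      m <- ph$truth@occupancy
      g <- buildGraph(pruneSkeleton(skeletonize(m)))
      ok <- !g@branches$isLoop
      expect_true(all(g@branches$edOverLength[ok] > 0))
      expect_true(all(g@branches$edOverLength[ok] <= 1 + 1e-12))
    }
  })
})

test_that("every skeleton voxel belongs to exactly one node or branch", {
  ph <- voxelize(sampleTreeSpec(nLevels = 3, seed = 77), spacingUm = 62)
  sk <- pruneSkeleton(skeletonize(ph$truth@occupancy))
  g <- buildGraph(sk)
  pathVox <- unique(do.call(rbind, g@paths))
  keys <- paste(pathVox[, 1], pathVox[, 2], pathVox[, 3])
  skelVox <- which(voxelData(sk), arr.ind = TRUE)
  skelKeys <- paste(skelVox[, 1], skelVox[, 2], skelVox[, 3])
  expect_true(all(skelKeys %in% keys) || {
    # node-only voxels (e.g. an isolated clump) are carried by the node
    # table instead of a path
    missing <- setdiff(skelKeys, keys)
    length(missing) <= sum(g@nodes$nVoxels)
  })
})

test_that("per-label branch statistics sum to the totals", {
  ph <- makeArmPhantom(c(4, 3, 3), 2, seed = 5, noise = FALSE)
  rep <- runPipeline(pipelineConfig(input = ph$volume, labels = ph$labels))
  st <- attr(rep, "stages")$statistics
  tot <- st[st$label == "total", ]
  parts <- st[!st$label %in% c("total", "unassigned"), ]
  expect_identical(sum(parts$nBranches), tot$nBranches)
  expect_identical(sum(parts$nEndpoints), tot$nEndpoints)
})

test_that("empty skeletons give empty graphs and all-zero statistics", {
  empty <- new("Skeleton", data = array(FALSE, c(4, 4, 4)),
               ltLabel = array(numeric(0), c(0L, 0L, 0L)),
               spacing = c(62, 62, 62), origin = c(0, 0, 0))
  g <- buildGraph(empty)
  expect_identical(nrow(g@branches), 0L)
  st <- branchStatistics(g)
  expect_identical(st$nBranches, 0L)
  expect_identical(st$avgBranchLengthMm, 0)
})

test_that("branch-length histograms count every branch once", {
  g <- buildGraph(ySkeleton())
  h <- branchLengthHistogram(g, binWidthMm = 0.5)
  expect_identical(sum(h$count), nrow(g@branches))
})

test_that("SWC export writes one record per skeleton voxel", {
  g <- buildGraph(ySkeleton())
  f <- tempfile(fileext = ".swc")
  writeSWC(g, f)
  ln <- readLines(f)
  body <- ln[!grepl("^#", ln)]
  flds <- do.call(rbind, strsplit(body, " "))
  expect_identical(ncol(flds), 7L)
  expect_identical(length(unique(flds[, 1])), length(body))
})
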