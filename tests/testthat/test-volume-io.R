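test_that("grid objects round-trip through TIFF and raw with metadata", {
  withSeed(11, {
    for (i in 1:4) {
      d <- c(sample(2:6, 1), sample(2:7, 1), sample(2:8, 1))
      sp <- runif(3, 10, 100)

      v <- VoxelVolume(array(sample(0:255, prod(d), replace = TRUE), d), sp)
      f <- tempfile(fileext = ".tif")
      writeVolume(v, f)
      v2 <- readVolume(f)
      expect_s4_class(v2, "VoxelVolume")
      expect_equal(voxelData(v2), voxelData(v))
      expect_equal(spacing(v2), spacing(v), tolerance = 1e-6)

      m <- BinaryMask(array(runif(prod(d)) > 0.5, d), sp)
      fm <- tempfile(fileext = ".tif")
      writeVolume(m, fm)
      m2 <- readVolume(fm)
      expect_s4_class(m2, "BinaryMask")
      expect_identical(voxelData(m2), voxelData(m))

      la <- array(sample(0:3, prod(d), replace = TRUE), d)
      lab <- LabelVolume(la, spacing = sp)
      fl <- tempfile(fileext = ".tif")
      writeVolume(lab, fl)
      lab2 <- readVolume(fl)
      expect_s4_class(lab2, "LabelVolume")
      expect_identical(voxelData(lab2), voxelData(lab))
      expect_identical(labelNames(lab2), labelNames(lab))
    }
  })
})

test_that("16-bit label volumes and real-valued fields take the raw path", {
  d <- c(3, 4, 5)
  lab <- LabelVolume(array(sample(c(0L, 300L, 70000L %% 65535L), prod(d),
                                  replace = TRUE), d), spacing = 62)
  f <- tempfile(fileext = ".tif")
  writeVolume(lab, f)
  expect_identical(voxelData(readVolume(f)), voxelData(lab))

  lt <- new("ThicknessField", values = array(abs(rnorm(prod(d))), d),
            spacing = c(62, 62, 62), origin = c(0, 0, 0),
            convention = "radius")
  fr <- tempfile(fileext = ".raw")
  writeVolume(lt, fr)
  lt2 <- readVolume(fr)
  expect_s4_class(lt2, "ThicknessField")
  expect_equal(voxelData(lt2), voxelData(lt))
  expect_identical(lt2@convention, "radius")
})

test_that("raw sidecar declares shape, dtype and spacing", {
  f <- tempfile(fileext = ".raw")
  writeBin(as.raw(rep(7, 1000)), f)
  writeLines(c("kind=volume", "shape=10,10,10", "dtype=uint8",
               "byteorder=little", "spacing_um=62.0,62.0,62.0"),
             paste0(f, ".meta"))
  v <- readVolume(f)
  expect_equal(spacing(v), c(62, 62, 62))
  expect_equal(dim(voxelData(v)), c(10L, 10L, 10L))
  expect_true(all(voxelData(v) == 7))
})

test_that("size mismatch between sidecar and file is an error", {
  f <- tempfile(fileext = ".raw")
  writeBin(as.raw(rep(0, 999)), f)
  writeLines(c("shape=10,10,10", "dtype=uint8", "spacing_um=1,1,1"),
             paste0(f, ".meta"))
  expect_error(readVolume(f), "size mismatch")
})

test_that("missing files and missing spacing are reported", {
  expect_error(readVolume(tempfile(fileext = ".tif")), "not found")
  v <- VoxelVolume(array(1:24, c(2, 3, 4)), spacing = 62)
  f <- tempfile(fileext = ".tif")
  writeVolume(v, f)
  file.remove(paste0(f, ".meta"))
  expect_warning(v2 <- readVolume(f), "spacing")
  expect_equal(spacing(v2), c(1, 1, 1))
})

test_that("a directory of slices reads in lexicographic order", {
  dirp <- tempfile()
  dir.create(dirp)
  for (i in 1:3) {
    sl <- VoxelVolume(array((i * 10L) + seq_len(6) %% 3L, c(1, 2, 3)))
    writeVolume(sl, file.path(dirp, sprintf("slice_%02d.tif", i)))
  }
  suppressWarnings(v <- readVolume(dirp))
  expect_equal(dim(voxelData(v)), c(3L, 2L, 3L))
  expect_true(all(voxelData(v)[1, , ] < voxelData(v)[3, , ]))
})
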