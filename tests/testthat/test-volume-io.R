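test_that("NIfTI round trip preserves data, spacing and exact values", {
  v <- randVol(c(8, 8, 8), seed = 3, spacing = c(0.5, 0.5, 2))
  v@data[1, 2, 3] <- 1024.0
  f <- tempfile(fileext = ".nii.gz")
  writeVolume(v, f)
  r <- readVolume(f)
  expect_identical(dim(volData(r)), dim(volData(v)))
  expect_identical(volData(r), volData(v))   # dyadic values, bit-faithful
  expect_equal(volSpacing(r), c(0.5, 0.5, 2))
  expect_equal(volData(r)[1, 2, 3], 1024.0)
  # overwriting an existing file succeeds
  expect_silent(writeVolume(v, f))
  unlink(f)
})

test_that("read/write error on missing files, bad dirs and non-3D images", {
  expect_error(readVolume(tempfile(fileext = ".nii")), "not found")
  f4 <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(array(0, c(4, 4, 4, 2))), f4)
  expect_error(readVolume(f4), "rank 4")
  unlink(f4)
  v <- randVol()
  expect_error(writeVolume(v, file.path(tempfile(), "nope", "x.nii")),
               "no such directory")
})

test_that("long-tail clipping caps voxels at the threshold and is idempotent", {
  v <- brainVolume(array(c(0, 500, 2000, 1024, 3000, 12, 1, 8),
                         dim = c(2, 2, 2)))
  cl <- clipLongTail(v, 1024)
  expect_equal(sort(unique(as.vector(volData(cl)))),
               c(0, 1, 8, 12, 500, 1024))
  expect_true(all(volData(cl) <= 1024))
  expect_equal(volData(clipLongTail(cl, 1024)), volData(cl))
  # all voxels already below the cap: identity
  lo <- brainVolume(array(runif(27) * 100, dim = c(3, 3, 3)))
  expect_equal(volData(clipLongTail(lo, 1024)), volData(lo))
})

test_that("min-max rescaling follows target_hi*(x-min)/(max-min) exactly", {
  v <- brainVolume(array(c(0, 512, 2048, rep(100, 5)), dim = c(2, 2, 2)))
  r <- rescaleMinMax(v, 1024)
  expect_equal(volData(r)[2, 1, 1], 256.0)       # 1024*(512-0)/2048
  expect_equal(min(volData(r)), 0)
  expect_equal(max(volData(r)), 1024)
  expect_equal(r@intensityRange, c(0, 1024))
  expect_error(rescaleMinMax(brainVolume(array(5, c(2, 2, 2)))),
               "degenerate")
})

test_that("unit-range rescaling maps min to 0, max to 1 and is idempotent", {
  v <- brainVolume(array(seq(0, 1024, length.out = 64), dim = c(4, 4, 4)))
  u <- toUnitRange(v)
  expect_equal(volData(u), volData(v) / 1024)
  expect_equal(volData(toUnitRange(u)), volData(u))
  two <- brainVolume(array(c(3, 7), dim = c(2, 1, 1)))
  expect_equal(as.vector(volData(toUnitRange(two))), c(0, 1))
  expect_error(toUnitRange(brainVolume(array(1, c(2, 2, 2)))), "degenerate")
})

test_that("ROI cropping extracts the stated box with half-open geometry", {
  big <- brainVolume(array(0, dim = c(221, 257, 221)))
  big@data[111, 129, 111] <- 7
  roi <- roiSpec(center = c(111, 129, 111))
  cr <- cropROI(big, roi)
  expect_identical(dim(volData(cr)), c(96L, 96L, 48L))
  # output voxel (1,1,1) corresponds to center - floor(size/2)
  expect_equal(volData(cr)[49, 49, 25], 7)   # 111 - 48 = 63; 111-63+1 = 49
  # crop of the full extent at the centre is the identity
  v <- randVol(c(8, 8, 8), seed = 9)
  full <- cropROI(v, roiSpec(center = c(5, 5, 5), size = c(8, 8, 8)))
  expect_equal(volData(full), volData(v))
  # cropping a centred crop of the same size is the identity
  cc <- cropROI(cr, roiSpec(center = dim(volData(cr)) %/% 2L + 1L,
                            size = dim(volData(cr))))
  expect_equal(volData(cc), volData(cr))
  expect_error(cropROI(v, roiSpec(center = c(1, 1, 1), size = c(8, 8, 8))),
               "out of bounds")
  pad <- cropROI(v, roiSpec(center = c(1, 1, 1), size = c(8, 8, 8)),
                 pad = TRUE)
  expect_identical(dim(volData(pad)), c(8L, 8L, 8L))
  expect_equal(pad@data[1, 1, 1], 0)
  expect_equal(pad@data[5, 5, 5], v@data[1, 1, 1])
})

test_that("spline resizing hits the stated shapes and is exact on constants", {
  big <- brainVolume(array(1:100 %% 7, dim = c(221, 257, 221)) * 1.0)
  rs <- resizeVolume(big, c(110, 128, 110))
  expect_identical(dim(volData(rs)), c(110L, 128L, 110L))
  v <- randVol(c(8, 8, 8), seed = 2)
  expect_equal(volData(resizeVolume(v, c(8, 8, 8))), volData(v))
  cst <- brainVolume(array(3.5, c(12, 12, 12)))
  rc <- resizeVolume(cst, c(7, 5, 9))
  expect_equal(as.vector(volData(rc)), rep(3.5, 7 * 5 * 9))
})

test_that("repeat averaging is the voxelwise mean with strict shape checks", {
  v <- randVol(c(6, 6, 6), seed = 4)
  expect_equal(volData(averageRepeats(list(v, v))), volData(v))
  z <- brainVolume(array(0, c(4, 4, 4)))
  o <- brainVolume(array(1, c(4, 4, 4)))
  expect_equal(as.vector(volData(averageRepeats(list(z, o)))), rep(0.5, 64))
  expect_equal(volData(averageRepeats(list(v))), volData(v))
  expect_error(averageRepeats(list()), "non-empty")
  expect_error(averageRepeats(list(v, z)), "shape mismatch")
})

test_that("clip followed by rescale lands in [0, 1024] for long-tailed data", {
  set.seed(8)
  v <- brainVolume(array(rexp(512, rate = 1 / 400), dim = c(8, 8, 8)))
  out <- rescaleMinMax(clipLongTail(v, 1024), 1024)
  expect_gte(min(volData(out)), 0)
  expect_lte(max(volData(out)), 1024)
})
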