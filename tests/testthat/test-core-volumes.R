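test_that("Volume3D and BinaryMask3D enforce their grid invariants", {
  expect_error(Volume3D(array(0, c(2, 2)), c(1, 1, 1)), "3D")
  expect_error(Volume3D(array(0, c(2, 2, 2)), spacing = c(1, 0, 1)),
               "positive")
  expect_error(BinaryMask3D(array(c(0, 2), c(1, 1, 2))), "exactly")
  v <- Volume3D(array(0, c(3, 4, 5)), spacing = c(0.4, 0.33, 0.33))
  expect_equal(gridDim(v), c(3L, 4L, 5L))
  m <- BinaryMask3D(array(TRUE, c(3, 4, 5)), grid = v)
  expect_true(sameGrid(v, m))
  expect_error(BinaryMask3D(array(TRUE, c(3, 4, 4)), grid = v), "shape")
})

test_that("voxel/world mapping follows the documented axis convention", {
  v <- Volume3D(array(0, c(8, 8, 8)))
  # (k, j, i) = (3, 4, 5) with unit spacing -> world (x, y, z) = (4, 3, 2)
  expect_equal(voxelToWorld(v, c(3, 4, 5)), c(4, 3, 2))
  v2 <- Volume3D(array(0, c(8, 8, 8)), origin = c(10, 0, 0))
  expect_equal(voxelToWorld(v2, c(3, 4, 5)), c(14, 3, 2))
  # inverse composed with forward is the identity on integer indices
  idx <- cbind(k = c(1L, 5L, 8L), j = c(2L, 1L, 8L), i = c(3L, 8L, 1L))
  v3 <- Volume3D(array(0, c(8, 8, 8)), spacing = c(0.4, 0.33, 0.33),
                 origin = c(-4, 2, 7))
  expect_equal(worldToVoxel(v3, voxelToWorld(v3, idx)),
               unname(1 * idx), tolerance = 1e-12)
  expect_error(voxelToWorld(v, c(0, 1, 1)), "bounds")
  expect_error(voxelToWorld(v, c(1, 1, 9)), "bounds")
})

test_that("NIfTI and MetaImage round-trip shape, spacing, origin and data", {
  dat <- array(as.numeric(sample.int(1000, 3 * 4 * 5)), c(3, 4, 5))
  vol <- Volume3D(dat, spacing = c(0.4, 0.33, 0.33), origin = c(5, -2, 1))
  for (ext in c(".nii.gz", ".nii", ".mha", ".mhd")) {
    f <- tempfile(fileext = ext)
    saveVolume(vol, f)
    back <- loadVolume(f)
    expect_equal(gridDim(back), gridDim(vol), info = ext)
    expect_equal(voxelSpacing(back), voxelSpacing(vol), tolerance = 1e-5,
                 info = ext)
    expect_equal(voxelOrigin(back), voxelOrigin(vol), tolerance = 1e-5,
                 info = ext)
    # integer data and an integer element type: bit-for-bit
    expect_identical(volData(back), volData(vol), info = ext)
  }
})

test_that("a 3x3x3 MetaImage of zeros keeps its anisotropic spacing", {
  vol <- Volume3D(array(0, c(3, 3, 3)), spacing = c(0.4, 0.33, 0.33))
  f <- tempfile(fileext = ".mha")
  saveVolume(vol, f)
  expect_equal(voxelSpacing(loadVolume(f)), c(0.4, 0.33, 0.33),
               tolerance = 1e-6)
})

test_that("masks saved as 8-bit volumes keep values {0,1}", {
  m <- BinaryMask3D(randomMask(c(4, 4, 4), 0.5), spacing = c(1, 1, 1))
  f <- tempfile(fileext = ".nii.gz")
  saveVolume(m, f)
  back <- loadVolume(f)
  expect_setequal(unique(as.vector(volData(back))), c(0, 1))
  expect_equal(volData(back) > 0.5, volData(m) == 1)
})

test_that("unreadable or truncated files raise format errors naming the path", {
  expect_error(loadVolume("/nonexistent/vol.nii"), "does not exist")
  f <- tempfile(fileext = ".xyz")
  file.create(f)
  expect_error(loadVolume(f), "unsupported")
  vol <- Volume3D(array(1, c(6, 6, 6)))
  g <- tempfile(fileext = ".mha")
  saveVolume(vol, g)
  raw <- readBin(g, "raw", file.size(g))
  h <- tempfile(fileext = ".mha")
  writeBin(raw[1:(length(raw) - 100)], h)
  expect_error(loadVolume(h), "truncated")
  expect_error(saveVolume(vol, file.path(tempdir(), "nope", "x.nii")),
               "parent directory")
})

test_that("seed sets export and re-import through the CSV contract", {
  v <- Volume3D(array(0, c(6, 6, 6)), spacing = c(0.4, 0.33, 0.33))
  m <- array(FALSE, c(6, 6, 6))
  m[c(8, 44, 100)] <- TRUE
  seeds <- extractSeeds(BinaryMask3D(m, grid = v))
  f <- tempfile(fileext = ".csv")
  writeSeedsCSV(seeds, f)
  expect_identical(readLines(f, n = 1), "k,j,i,x_mm,y_mm,z_mm")
  back <- readSeedsCSV(f, v)
  expect_identical(seedCoords(back), seedCoords(seeds))
  df <- as.data.frame(seeds)
  expect_equal(df$x_mm, (df$i - 1) * 0.33)
  expect_equal(df$z_mm, (df$k - 1) * 0.4)
})
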