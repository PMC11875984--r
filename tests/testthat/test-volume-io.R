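test_that("volume write/read round-trip preserves shape, metadata and intensities", {
  set.seed(11)
  arr <- array(runif(2 * 4 * 8 * 8) * 800, c(2, 4, 8, 8))
  vol <- MultiChannelVolume(arr, c(0.22, 0.22, 1.0), c("DAPI", "CD3"))
  f <- withr::local_tempfile(fileext = ".tif")
  writeVolume(vol, f)
  back <- loadVolume(f)
  expect_identical(dim(back), c(2L, 4L, 8L, 8L))
  expect_identical(voxelSpacing(back), c(0.22, 0.22, 1.0))
  expect_identical(channelNames(back), c("DAPI", "CD3"))
  # intensities agree to 32-bit storage precision
  expect_lt(max(abs(intensities(back) - arr)) / max(arr), 1e-9)
})

test_that("plain TIFF input needs a spacing override and gets default channel names", {
  set.seed(12)
  pages <- lapply(1:4, function(i) matrix(runif(64), 8, 8))
  f <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(pages, f, bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  expect_error(loadVolume(f), "spacing")
  vol <- loadVolume(f, spacingOverride = c(0.5, 0.5, 1))
  expect_identical(channelNames(vol), "C0")
  expect_identical(dim(vol), c(1L, 4L, 8L, 8L))
  # channel-major interpretation of the page stack
  vol2 <- loadVolume(f, spacingOverride = c(0.5, 0.5, 1), nChannels = 2L)
  expect_identical(dim(vol2), c(2L, 2L, 8L, 8L))
  expect_identical(channelNames(vol2), c("C0", "C1"))
})

test_that("volume invariants reject bad input", {
  expect_error(MultiChannelVolume(array(-1, c(1, 2, 4, 4)), c(1, 1, 1)),
               "non-negative")
  expect_error(MultiChannelVolume(array(1, c(1, 2, 4, 4)), c(0, 1, 1)),
               "spacing")
  expect_error(MultiChannelVolume(array(1, c(2, 2, 4, 4)), c(1, 1, 1),
                                  c("A", "A")),
               "unique")
  expect_error(loadVolume(file.path(tempdir(), "nope.tif")), "not found")
})

test_that("cell-center tables parse, convert units and validate", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,x,y,z", "1,10,20,5", "2,2.2,2.2,2.0"), f)
  vox <- loadCenters(f)
  expect_equal(unlist(vox[vox$id == 1, c("x", "y", "z")]),
               c(x = 10, y = 20, z = 5))
  um <- loadCenters(f, coordinateUnit = "micrometer",
                    spacing = c(0.22, 0.22, 1.0))
  expect_equal(unlist(um[um$id == 2, c("x", "y", "z")]),
               c(x = 10, y = 10, z = 2))
  # duplicate ids
  writeLines(c("id,x,y,z", "7,1,1,1", "7,2,2,2"), f)
  expect_error(loadCenters(f), "duplicate")
  # out-of-bounds positions name the offending rows
  writeLines(c("id,x,y,z", "1,5,5,5", "2,99,5,5"), f)
  expect_error(loadCenters(f, dims = c(10, 10, 10)), "rows: 2")
  # round-trip through writeCenters
  df <- data.frame(id = c(3L, 4L), x = c(1.5, 2), y = c(2, 3), z = c(0, 1))
  writeCenters(df, f)
  expect_equal(loadCenters(f), df)
})

test_that("channel thresholds zero sub-threshold voxels and ranges clamp", {
  arr <- array(0, c(1, 2, 2, 3))
  arr[1, 1, 1, ] <- c(1, 5, 9)
  vol <- MultiChannelVolume(arr, c(1, 1, 1), "M")
  thr <- applyChannelConfig(vol, list(M = list(threshold = 4)))
  expect_equal(intensities(thr)[1, 1, 1, ], c(0, 5, 9))
  # threshold 0, no range: identity
  ident <- applyChannelConfig(vol, list(M = list(threshold = 0)))
  expect_identical(intensities(ident), intensities(vol))
  # threshold then clamp
  both <- applyChannelConfig(vol, list(M = list(threshold = 4, range = c(0, 6))))
  expect_equal(intensities(both)[1, 1, 1, ], c(0, 5, 6))
  # input unmodified; idempotent
  expect_equal(intensities(vol)[1, 1, 1, ], c(1, 5, 9))
  cfg <- list(M = list(threshold = 4, range = c(0, 6)))
  expect_identical(intensities(applyChannelConfig(both, cfg)),
                   intensities(both))
  # unknown channel and inconsistent config
  expect_error(applyChannelConfig(vol, list(X = list(threshold = 1))),
               "unknown channel")
  expect_error(applyChannelConfig(vol, list(M = list(threshold = 9,
                                                     range = c(0, 6)))),
               "exceeds")
  # inactive channels are skipped
  off <- applyChannelConfig(vol, list(M = list(threshold = 4, active = FALSE)))
  expect_identical(intensities(off), intensities(vol))
})

test_that("channel config loads from YAML and JSON", {
  fy <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("channels:", "  SOX10:", "    threshold: 12",
               "  CD3D:", "    threshold: 7", "    range: [0, 100]",
               "    active: true"), fy)
  cfg <- loadChannelConfig(fy)
  expect_equal(cfg$SOX10$threshold, 12)
  expect_equal(cfg$CD3D$range, c(0, 100))
  fj <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(channels = list(PD1 = list(threshold = 3))),
                       fj, auto_unbox = TRUE)
  expect_equal(loadChannelConfig(fj)$PD1$threshold, 3)
  expect_true(loadChannelConfig(fj)$PD1$active)
})
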