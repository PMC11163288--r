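test_that("unit conversions make the printed 2D and 3D size filters consistent", {
  # 16 px at 0.0851 um pixels is the 0.116 um^2 area filter ...
  expect_identical(area_to_px(0.116, 0.0851), 16)
  expect_equal(px_to_area(16, 0.0851), 0.116, tolerance = 0.003)
  # ... and with 0.25 um sections the same 0.116 value in um^3 is 64 voxels
  expect_identical(volume_to_vox(0.116, 0.0851, 0.25), 64)
  expect_equal(vox_to_volume(64, 0.0851, 0.25), 0.116, tolerance = 0.003)
})

test_that("pipeline_config defaults carry the standard analysis constants", {
  cfg <- pipeline_config()
  expect_equal(cfg$threshold_k, 2.5)
  expect_equal(cfg$min_area_px, 16L)
  expect_equal(cfg$min_vox, 64L)
  expect_equal(cfg$small_agg_cutoff_um2, 5.0)
  expect_equal(cfg$large_agg_cutoff_um2, 10.0)
  expect_equal(cfg$circularity_min, 0.8)
  expect_equal(cfg$sd_ratio_min, 1.5)
  expect_error(pipeline_config(threshold_k = -1), "positive")
})

test_that("config values are overridable from YAML file and call site", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("threshold_k: 3.0", "min_area_px: 9"), f)
  cfg <- read_config(f)
  expect_equal(cfg$threshold_k, 3.0)
  expect_equal(cfg$min_area_px, 9L)
  expect_equal(cfg$min_vox, 64L)  # untouched default
  cfg2 <- read_config(f, threshold_k = 2.0)
  expect_equal(cfg2$threshold_k, 2.0)
  writeLines("not_a_key: 1", f)
  expect_error(read_config(f), "unknown config key")
})

test_that("image_stack validates geometry, intensities and light schedule", {
  d <- array(1, dim = c(3, 1, 2, 8, 8))
  st <- image_stack(d, 0.1, channel_names = c("a", "b"),
                    light_schedule = list(c(1, 2)))
  expect_s3_class(st, "image_stack")
  expect_equal(n_frames(st), 3L)
  expect_equal(n_channels(st), 2L)
  expect_error(image_stack(-d, 0.1), "nonnegative")
  expect_error(image_stack(d, 0.1, light_schedule = list(c(1, 4))), "within")
  expect_error(image_stack(d, 0.1, light_schedule = list(c(1, 2), c(2, 3))),
               "disjoint")
  expect_error(image_stack(d, 0.1, channel_names = "only-one"), "channel")
  # a bare matrix is promoted to a 1-frame, 1-channel stack
  m <- matrix(runif(36), 6, 6)
  st1 <- image_stack(m, 0.0851)
  expect_equal(dim(st1$data), c(1L, 1L, 1L, 6L, 6L))
  expect_equal(get_frame(st1, 1, 1), m)
})

test_that("stack write/read round-trips data and all metadata", {
  set.seed(11)
  d <- array(runif(2 * 1 * 2 * 12 * 12) * 700, c(2, 1, 2, 12, 12))
  st <- image_stack(d, 0.0851, channel_names = c("p62", "polyQ"),
                    frame_interval_s = 2.5, light_schedule = list(c(1, 1)))
  path <- withr::local_tempfile(fileext = ".tif")
  write_stack(st, path)
  st2 <- read_stack(path)
  expect_equal(st2$data, st$data, tolerance = 1e-6)
  expect_equal(st2$pixel_size_um, 0.0851)
  expect_equal(st2$frame_interval_s, 2.5)
  expect_identical(st2$channel_names, c("p62", "polyQ"))
  expect_equal(st2$light_schedule, list(c(1L, 1L)))
})

test_that("reading without geometry metadata is a configuration error", {
  path <- withr::local_tempfile(fileext = ".tif")
  st <- image_stack(matrix(runif(64), 8, 8), 0.0851)
  write_stack(st, path)
  expect_error(read_stack(path, meta = "does-not-exist.yaml"),
               "pixel_size_um")
  expect_error(read_stack("no-such-file.tif"), "cannot read")
  # sidecar present but lacking the one required field
  bad_meta <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(frame_interval_s = 1), bad_meta)
  expect_error(read_stack(path, meta = bad_meta), "pixel_size_um")
})

test_that("result tables round-trip through CSV with stable columns", {
  rec <- data.frame(object_id = 1L, area_um2 = 0.116,
                    centroid_x_um = 1.23456789012345)
  path <- withr::local_tempfile(fileext = ".csv")
  write_results(rec, path)
  txt <- readLines(path)
  expect_match(txt[1], '"object_id","area_um2","centroid_x_um"', fixed = TRUE)
  expect_match(txt[2], "0.116", fixed = TRUE)
  back <- read_results(path)
  expect_equal(back, rec, tolerance = 1e-12)
  # empty-with-header case
  write_results(rec[0, ], path)
  expect_equal(nrow(read_results(path)), 0L)
  expect_identical(names(read_results(path)), names(rec))
})

test_that("mask images round-trip through 16-bit TIFF", {
  lab <- matrix(sample(0:5, 64, replace = TRUE), 8, 8)
  path <- withr::local_tempfile(fileext = ".tif")
  write_mask(lab, path)
  expect_identical(read_mask(path), matrix(as.integer(lab), 8, 8))
})
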