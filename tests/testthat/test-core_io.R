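test_that("image stacks round-trip through multi-page TIFF bit-exactly", {
  set.seed(11)
  frames <- lapply(1:10, function(i) {
    matrix(round(runif(64 * 64) * 65535) / 65535, 64, 64)
  })
  st <- image_stack(frames, channel = "Cy5", pixel_size = 0.2,
                    frame_interval = 0.2)
  expect_equal(n_frames(st), 10L)
  path <- withr::local_tempfile(fileext = ".tif")
  write_image_stack(st, path)
  rt <- read_image_stack(path, pixel_size = 0.2, frame_interval = 0.2)
  expect_identical(rt$frames, st$frames)
  expect_equal(rt$pixel_size, 0.2)
  expect_equal(rt$frame_interval, 0.2)
})

test_that("channel selection extracts the requested interleaved channel", {
  set.seed(12)
  mk <- function() lapply(1:5, function(i) {
    matrix(round(runif(32 * 32) * 65535) / 65535, 32, 32)
  })
  fitc <- image_stack(mk(), channel = "FITC")
  cy5 <- image_stack(mk(), channel = "Cy5")
  path <- withr::local_tempfile(fileext = ".tif")
  write_image_stack(list(FITC = fitc, Cy5 = cy5), path)
  got <- read_image_stack(path, channel = "Cy5",
                          channels = c("FITC", "Cy5"))
  expect_identical(got$frames, cy5$frames)
  expect_error(read_image_stack(path, channel = "DAPI",
                                channels = c("FITC", "Cy5")),
               "unknown channel")
  both <- read_image_stack(path, channels = c("FITC", "Cy5"))
  expect_named(both, c("FITC", "Cy5"))
  expect_identical(both$FITC$frames, fitc$frames)
})

test_that("a truncated TIFF raises an error rather than a partial stack", {
  set.seed(13)
  st <- image_stack(lapply(1:8, function(i) matrix(runif(32 * 32), 32, 32)))
  path <- withr::local_tempfile(fileext = ".tif")
  write_image_stack(st, path)
  bytes <- readBin(path, "raw", file.size(path))
  bad <- withr::local_tempfile(fileext = ".tif")
  writeBin(bytes[seq_len(length(bytes) %/% 2)], bad)
  expect_error(read_image_stack(bad), "TIFF")
  expect_error(read_image_stack(withr::local_tempfile(fileext = ".tif")),
               "not found")
})

test_that("trace tables round-trip CSV at full precision, including NA gaps", {
  set.seed(14)
  for (rep in 1:5) {
    n <- sample(3:40, 1)
    tt <- trace_table(time_s = cumsum(runif(n)),
                      roi = rnorm(n), absorbance = exp(rnorm(n)))
    tt$roi[sample(n, 1)] <- NA
    path <- withr::local_tempfile(fileext = ".csv")
    write_trace(tt, path)
    rt <- read_trace(path)
    expect_identical(unclass(rt)[1:3], unclass(tt)[1:3])
  }
})

test_that("trace io rejects degenerate tables", {
  empty <- trace_table(time_s = numeric(), v = numeric())
  expect_error(write_trace(empty, tempfile()), "no rows")
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time_s,v", ""), path)
  expect_error(read_trace(path), "no rows")
  writeLines(c("time_s,v", "0,abc"), path)
  expect_error(read_trace(path), "non-numeric")
  expect_error(trace_table(time_s = c(1, 0), v = c(1, 2)), "monotone")
  expect_error(trace_table(time_s = 1:2, v = 1:3), "length")
})

test_that("run configuration validates, hashes stably, and reads YAML/JSON", {
  sp <- data.frame(name = c("E", "R9"), conc_uM = c(5, 100),
                   length = c(66, 9), charged = c(66, 9))
  cfg <- run_config(pixel_size = 0.2, frame_interval = 0.2, species = sp,
                    seed = 7L)
  cfg2 <- run_config(pixel_size = 0.2, frame_interval = 0.2, species = sp,
                     seed = 7L)
  expect_identical(cfg$hash, cfg2$hash)
  expect_false(run_config(pixel_size = 0.3)$hash == cfg$hash)
  expect_error(run_config(pre_bleach_frames = 0), "pre_bleach")
  expect_error(run_config(species = transform(sp, charged = length + 1)),
               "exceed")

  yml <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(pixel_size = 0.5, frame_interval = 2,
                        pre_bleach_frames = 10), yml)
  got <- read_run_config(yml)
  expect_equal(got$pixel_size, 0.5)
  expect_equal(got$pre_bleach_frames, 10L)
  jsn <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(pixel_size = 0.25, seed = 3),
                       jsn, auto_unbox = TRUE)
  expect_equal(read_run_config(jsn)$pixel_size, 0.25)
})
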