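test_that("device specs enforce their invariants", {
  bd <- burst_device()
  expect_equal(samples_per_burst(bd), 82L)
  expect_error(device_spec("bad", "burst", 33.8, 2.43, 20, raw_min = 10,
                           raw_max = 5, axis_map = bd$axis_map),
               "raw_min")
  expect_error(device_spec("bad", "continuous", 1, raw_min = 0, raw_max = 1,
                           axis_map = c(x = "sway", y = "sway", z = "heave")),
               "bijection")
})

test_that("axis remapping permutes values without transforming them", {
  expect_equal(to_semantic_axes(c(10, 20, 30), burst_device()$axis_map),
               c(sway = 20, surge = 30, heave = 10))
  expect_equal(to_semantic_axes(c(10, 20, 30), continuous_device()$axis_map),
               c(sway = 20, surge = 10, heave = 30))
  idm <- c(x = "sway", y = "surge", z = "heave")
  expect_equal(unname(to_semantic_axes(c(7, 8, 9), idm)), c(7, 8, 9))
  # applying the inverse map recovers raw order, for every permutation
  perms <- list(c("sway", "surge", "heave"), c("sway", "heave", "surge"),
                c("surge", "sway", "heave"), c("surge", "heave", "sway"),
                c("heave", "sway", "surge"), c("heave", "surge", "sway"))
  for (p in perms) {
    amap <- stats::setNames(p, c("x", "y", "z"))
    raw <- c(x = 1, y = 2, z = 3)
    sem <- to_semantic_axes(raw, amap)
    back <- vapply(c("x", "y", "z"), function(r) sem[[amap[[r]]]], 0)
    expect_equal(back, raw)
  }
})

test_that("burst CSV dialect round-trips values exactly", {
  spec <- burst_device()
  set.seed(11)
  bursts <- lapply(c(0, 20, 40), function(s) make_burst(start = s))
  path <- withr::local_tempfile(fileext = ".csv")
  write_burst_csv(bursts, path, spec)
  back <- read_burst_csv(path, spec)
  expect_length(back, 3)
  for (i in 1:3) {
    expect_identical(back[[i]]$sway, bursts[[i]]$sway)
    expect_identical(back[[i]]$surge, bursts[[i]]$surge)
    expect_identical(back[[i]]$heave, bursts[[i]]$heave)
    expect_equal(back[[i]]$start_time, bursts[[i]]$start_time)
    expect_equal(back[[i]]$label, "unlabeled")
    expect_length(back[[i]]$sway, 82)
  }
})

test_that("burst CSV parsing rejects bad files with located errors", {
  spec <- burst_device()
  set.seed(12)
  path <- withr::local_tempfile(fileext = ".csv")
  write_burst_csv(list(make_burst()), path, spec)

  lines <- readLines(path)
  over <- sub(",[0-9]+$", ",5000", lines[2])
  writeLines(c(lines[1], over, lines[-(1:2)]), path)
  expect_error(read_burst_csv(path, spec), "5000.*line 2")

  writeLines(c(lines[1], sub(",[0-9]+$", ",oops", lines[2]), lines[-(1:2)]),
             path)
  expect_error(read_burst_csv(path, spec), "malformed row at line 2")

  writeLines(lines[-2], path)  # burst now has 81 samples on one axis
  expect_error(read_burst_csv(path, spec), "expected 82")
})

test_that("continuous CSV preserves gaps and ignores vendor pitch/roll", {
  spec <- continuous_device()
  set.seed(13)
  ts <- c(0:299, 330:629)  # 600 samples with a 30 s transmission gap
  samples <- data.frame(timestamp = ts,
                        x = sample(-100:100, 600, TRUE),
                        y = sample(-100:100, 600, TRUE),
                        z = sample(7000:9000, 600, TRUE))
  stream <- acc_stream("far", spec$name, samples, spec)
  path <- withr::local_tempfile(fileext = ".csv")
  write_continuous_csv(stream, path)
  back <- read_continuous_csv(path, spec)
  expect_equal(nrow(back$samples), 600)
  expect_equal(diff(range(back$samples$timestamp)) + 1, 630)
  expect_identical(back$samples$x, samples$x)

  # vendor pitch/roll columns change nothing
  df <- utils::read.csv(path)
  df$pitch <- 1.23; df$roll <- -0.5
  path2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, path2, row.names = FALSE)
  back2 <- read_continuous_csv(path2, spec)
  expect_identical(back2$samples, back$samples)

  expect_error(acc_stream("far", spec$name,
                          data.frame(timestamp = c(3, 2, 1),
                                     x = 0, y = 0, z = 0), spec),
               "strictly increasing")
  bad <- samples; bad$z[5] <- 40000
  expect_error(acc_stream("far", spec$name, bad, spec), "outside")
})

test_that("ethogram CSV round-trips and rejects overlapping intervals", {
  eth <- data.frame(individual = c("a", "a", "b"),
                    start = c(0, 60, 10), end = c(60, 120, 50),
                    behavior = c("STA", "WAL", "FEG"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_ethogram_csv(eth, path)
  back <- read_ethogram_csv(path)
  expect_equal(back$start, eth$start)
  expect_equal(back$behavior, eth$behavior)
  bad <- eth; bad$start[2] <- 30
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_ethogram_csv(bad, path2)
  expect_error(read_ethogram_csv(path2), "overlapping")
})
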