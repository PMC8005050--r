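test_that("axis moments match hand arithmetic and handle degenerate input", {
  m <- axis_moments(1:5)
  expect_equal(m[["mean"]], 3)
  expect_equal(m[["sd"]], sqrt(2.5))
  expect_equal(m[["icv"]], 3 / sqrt(2.5))
  expect_equal(m[["skewness"]], 0)  # symmetric sequence

  cc <- axis_moments(rep(7, 10))
  expect_equal(cc[["mean"]], 7)
  expect_equal(cc[["sd"]], 0)
  expect_equal(cc[["icv"]], 1e9)
  expect_equal(axis_moments(rep(-7, 10))[["icv"]], -1e9)
  expect_equal(cc[["kurtosis"]], 0)

  expect_error(axis_moments(1:4), "at least 5")
})

test_that("moment estimators agree with e1071 type-1 estimators", {
  set.seed(51)
  for (i in 1:20) {
    x <- rnorm(82, sd = runif(1, 0.1, 50))
    m <- axis_moments(x)
    expect_equal(m[["skewness"]], e1071::skewness(x, type = 1),
                 tolerance = 1e-12)
    expect_equal(m[["kurtosis"]], e1071::kurtosis(x, type = 1),
                 tolerance = 1e-12)
  }
})

test_that("weighted mean frequency recovers tones and degenerates sanely", {
  fs <- 33.8; n <- 82
  # bin-centered tone: no leakage, wm is (nearly) the tone frequency
  f_bin <- 10 * fs / n
  x <- sin(2 * pi * f_bin * (0:(n - 1)) / fs)
  expect_equal(weighted_mean_frequency(x, fs), f_bin, tolerance = 1e-6)
  # off-bin tone at 4 Hz: within one bin width despite rectangular leakage
  y <- sin(2 * pi * 4 * (0:(n - 1)) / fs)
  expect_lt(abs(weighted_mean_frequency(y, fs) - 4), fs / n)
  # constant input: all-zero spectrum -> sentinel
  expect_equal(weighted_mean_frequency(rep(3, n), fs), 0)
  # white noise: flat expected spectrum -> wm near the mid-band bin mean
  set.seed(52)
  wm <- replicate(200, weighted_mean_frequency(rnorm(n), fs))
  mid <- mean((1:floor(n / 2)) * fs / n)
  expect_lt(abs(mean(wm) - mid), 0.5)
})

test_that("combined q/pitch/roll follow the static-gravity convention", {
  n <- 82
  f <- combined_features(rep(0, n), rep(0, n), rep(1, n))
  expect_equal(unname(f), c(1, 0, 0))
  f2 <- combined_features(rep(0, n), rep(-1, n), rep(0, n))
  expect_equal(f2[["pitch"]], pi / 2)
  # q is the mean per-sample norm (independent loop oracle)
  set.seed(53)
  sw <- rnorm(n); su <- rnorm(n); he <- rnorm(n)
  q_oracle <- 0
  for (i in 1:n) q_oracle <- q_oracle + sqrt(sw[i]^2 + su[i]^2 + he[i]^2) / n
  expect_equal(combined_features(sw, su, he)[["q"]], q_oracle,
               tolerance = 1e-12)
})

test_that("q dominates the norm of the per-axis means (Jensen)", {
  set.seed(54)
  for (i in 1:50) {
    b <- make_burst()
    f <- feature_vector(b, burst_device())
    expect_gte(f[["q"]] + 1e-9,
               sqrt(sum((c(mean(b$sway), mean(b$surge), mean(b$heave)) -
                           2048)^2)))
  }
})

test_that("feature vectors carry exactly the named 21 or 18 predictors", {
  set.seed(55)
  fb <- feature_vector(make_burst(), burst_device())
  expect_length(fb, 21)
  expect_true(all(c("wm_sway", "wm_surge", "wm_heave") %in% names(fb)))
  section <- acc_burst("x", "continuous_logger", 0, rnorm(40), rnorm(40),
                       rnorm(40), label = "DRI")
  fc <- feature_vector(section, continuous_device())
  expect_length(fc, 18)
  expect_false(any(grepl("^wm_", names(fc))))
  expect_equal(setdiff(names(fb), names(fc)),
               c("wm_sway", "wm_surge", "wm_heave"))
})

test_that("sample order affects only the spectral features", {
  set.seed(56)
  b <- make_burst()
  perm <- sample(82)  # one permutation applied to all axes keeps the triples
  p <- acc_burst(b$individual, b$device, b$start_time,
                 b$sway[perm], b$surge[perm], b$heave[perm], b$label)
  f1 <- feature_vector(b, burst_device())
  f2 <- feature_vector(p, burst_device())
  order_free <- setdiff(names(f1), c("wm_sway", "wm_surge", "wm_heave"))
  expect_equal(f1[order_free], f2[order_free], tolerance = 1e-12)
  expect_false(isTRUE(all.equal(f1[["wm_sway"]], f2[["wm_sway"]],
                                tolerance = 1e-6)))
})

test_that("features shift and scale the way their definitions demand", {
  set.seed(57)
  spec <- burst_device()
  for (i in 1:25) {
    b <- make_burst()
    f <- feature_vector(b, spec)
    shift <- 137.5
    bs <- acc_burst(b$individual, b$device, b$start_time, b$sway + shift,
                    b$surge + shift, b$heave + shift, b$label)
    fs_ <- feature_vector(bs, spec)
    inv <- grep("^(sd|skew|kurt|wm)_", names(f), value = TRUE)
    expect_equal(fs_[inv], f[inv], tolerance = 1e-9)
    expect_equal(fs_[["mn_sway"]], f[["mn_sway"]] + shift, tolerance = 1e-9)
    expect_equal(fs_[["icv_sway"]], (f[["mn_sway"]] + shift) / f[["sd_sway"]],
                 tolerance = 1e-9)

    cmul <- 3.25
    bc <- acc_burst(b$individual, b$device, b$start_time, b$sway * cmul,
                    b$surge * cmul, b$heave * cmul, b$label)
    spec0 <- spec; spec0$zero_offset <- 0
    f0 <- feature_vector(b, spec0)
    fcv <- feature_vector(bc, spec0)
    scale_inv <- grep("^(icv|skew|kurt|wm)_", names(f0), value = TRUE)
    expect_equal(fcv[c(scale_inv, "pitch", "roll")],
                 f0[c(scale_inv, "pitch", "roll")], tolerance = 1e-9)
    expect_equal(fcv[["q"]], f0[["q"]] * cmul, tolerance = 1e-9)
    expect_equal(fcv[["sd_surge"]], f0[["sd_surge"]] * cmul, tolerance = 1e-9)
  }
})

test_that("short continuous sections are discarded before feature extraction", {
  set.seed(58)
  good <- acc_burst("x", "continuous_logger", 0, rnorm(10), rnorm(10),
                    rnorm(10), label = "STA")
  short <- acc_burst("x", "continuous_logger", 20, rnorm(3), rnorm(3),
                     rnorm(3), label = "STA")
  expect_message(ft <- feature_table(list(good, short), continuous_device()),
                 "discarded")
  expect_equal(nrow(ft), 1)
  expect_error(suppressMessages(feature_table(list(short),
                                              continuous_device())),
               "no bursts")
})
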