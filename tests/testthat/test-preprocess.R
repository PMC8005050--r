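eth_one <- function(behaviors, bounds, individual = "x") {
  data.frame(individual = individual,
             start = bounds[-length(bounds)], end = bounds[-1],
             behavior = behaviors, stringsAsFactors = FALSE)
}

test_that("bursts are labeled by half-open interval containment", {
  spec <- burst_device()
  eth <- eth_one(c("STA", "WAL"), c(0, 60, 120))
  set.seed(21)
  inside <- make_burst(start = 10)          # [10, 12.43) inside STA
  spanning <- make_burst(start = 58.5)      # crosses the STA -> WAL boundary
  after <- make_burst(start = 130)          # beyond the last interval
  labs <- vapply(label_bursts(list(inside, spanning, after), eth, spec),
                 `[[`, "", "label")
  expect_equal(labs, c("STA", "mixed", "unlabeled"))
  # partially observed bursts are unlabeled even if they also span behaviors
  straddling <- make_burst(start = 119)
  expect_equal(label_bursts(list(straddling), eth, spec)[[1]]$label,
               "unlabeled")
})

test_that("labeling is exhaustive and exclusive and matches a brute-force oracle", {
  cfg <- tiny_scenario("solo", seed = 31, session_length = 3000)
  truth <- generate_truth(cfg)
  spec <- burst_device()
  bursts <- render_device(truth, "solo", spec)
  labeled <- label_bursts(bursts, truth$ethogram, spec)
  labs <- vapply(labeled, `[[`, "", "label")
  codes <- names(cfg$signatures)
  expect_true(all(labs %in% c(codes, "mixed", "unlabeled")))

  # oracle: direct containment scan over ground-truth intervals
  eth <- truth$ethogram
  oracle <- vapply(bursts, function(b) {
    t0 <- b$start_time
    t1 <- b$start_time + 81 / spec$sample_rate
    hit <- eth$start <= t0 & t1 < eth$end
    if (any(hit)) eth$behavior[which(hit)[1]]
    else if (t1 >= cfg$session_length) "unlabeled" else "mixed"
  }, "")
  expect_equal(labs, oracle)
})

test_that("continuous segmentation splits on behavior changes and gaps", {
  spec <- continuous_device()
  mk_stream <- function(ts) acc_stream("x", spec$name,
    data.frame(timestamp = ts, x = 0, y = 0, z = 8192), spec)

  eth <- eth_one("DRI", c(0, 90))
  one <- segment_continuous(mk_stream(0:89), eth, spec)
  expect_length(one, 1)
  expect_equal(length(one[[1]]$sway), 90)
  expect_equal(one[[1]]$label, "DRI")

  # a 10 s transmission gap splits the section in two
  two <- segment_continuous(mk_stream(c(0:39, 50:89)), eth, spec)
  expect_length(two, 2)
  expect_equal(sum(vapply(two, function(b) length(b$sway), 0L)), 80)
  expect_true(all(vapply(two, `[[`, "", "label") == "DRI"))

  # degenerate: alternating 1 s behaviors give length-1 sections
  eth2 <- eth_one(rep(c("STA", "WAL"), 5), 0:10)
  ones <- segment_continuous(mk_stream(0:9), eth2, spec)
  expect_length(ones, 10)
  expect_true(all(vapply(ones, function(b) length(b$sway), 0L) == 1L))

  # axis remapping: continuous raw z carries heave
  expect_true(all(one[[1]]$heave == 8192))
  expect_true(all(one[[1]]$sway == 0))
})

test_that("segmentation partitions the labeled, non-dropped samples", {
  cfg <- tiny_scenario("solo", seed = 32, session_length = 2000,
                       dropout_rate = 0.05)
  truth <- generate_truth(cfg)
  spec <- continuous_device()
  stream <- render_device(truth, "solo", spec)
  sections <- segment_continuous(stream, truth$ethogram, spec)
  # every retained sample is inside an interval, so all samples are covered
  eth <- truth$ethogram
  ts <- stream$samples$timestamp
  covered <- vapply(ts, function(t) any(eth$start <= t & t < eth$end), TRUE)
  expect_equal(sum(vapply(sections, function(b) length(b$sway), 0L)),
               sum(covered))
})

test_that("filter_pure retains exactly the pure-labeled bursts", {
  set.seed(22)
  bursts <- c(lapply(1:10, function(i) make_burst(label = "STA")),
              lapply(1:4, function(i) make_burst(label = "mixed")),
              lapply(1:2, function(i) make_burst(label = "unlabeled")))
  ds <- filter_pure(bursts)
  expect_length(ds$bursts, 10)
  expect_warning(empty <- filter_pure(lapply(1:3, function(i)
    make_burst(label = "mixed"))), "no pure")
  expect_length(empty$bursts, 0)
})

test_that("balanced subsampling equalizes counts and drops rare categories", {
  set.seed(23)
  ds <- make_dataset(c(STA = 120, WAL = 45, DRI = 12))
  sub <- balanced_subsample(ds, 30, seed = 9)
  tab <- table(vapply(sub$bursts, `[[`, "", "label"))
  expect_equal(as.vector(tab[c("STA", "WAL")]), c(30, 30))
  expect_false("DRI" %in% names(tab))
  expect_equal(sub$dropped, "x/DRI")
  expect_true(all(table(vapply(sub$bursts, `[[`, "", "label")) == 30))

  # 8 categories, all sufficient -> 240 bursts
  ds8 <- make_dataset(stats::setNames(rep(35, 8), paste0("B", 1:8)))
  expect_length(balanced_subsample(ds8, 30, seed = 1)$bursts, 240)

  # determinism under the seed
  s1 <- balanced_subsample(ds, 30, seed = 77)
  s2 <- balanced_subsample(ds, 30, seed = 77)
  expect_identical(vapply(s1$bursts, `[[`, 0, "start_time"),
                   vapply(s2$bursts, `[[`, 0, "start_time"))
})
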