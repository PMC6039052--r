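# Labeled burst generator, detection scoring, config round-trips and
# report serialization.

test_that("burst generator produces labeled, non-overlapping bursts", {
  g <- generate_burst_series(n_channels = 2, duration = 120, seed = 9)
  expect_equal(dim(g$series), c(120 * g$rate, 2))
  expect_gt(nrow(g$truth), 5)
  for (ch in 1:2) {
    tr <- g$truth[g$truth$channel == ch, ]
    if (nrow(tr) > 1) {
      expect_true(all(tr$onset_s[-1] >= head(tr$offset_s, -1)))
    }
  }
  expect_true(all(g$truth$freq_hz >= 11 & g$truth$freq_hz <= 15))
  expect_true(all(g$truth$offset_s - g$truth$onset_s >= 0.5 - 1e-9))
  # reproducible
  g2 <- generate_burst_series(n_channels = 2, duration = 120, seed = 9)
  expect_identical(g$series, g2$series)
  expect_identical(g$truth, g2$truth)
})

test_that("zero-amplitude bursts yield (almost) no detections", {
  g <- generate_burst_series(duration = 300, amp_sd = 0, seed = 5)
  ev <- detect_spindles(g$series, g$rate)
  expect_lt(nrow(ev) / 5, 0.5)  # < 0.5 events/min of false positives
})

test_that("high-SNR bursts are detected and ISI structure is recovered", {
  g <- generate_burst_series(duration = 600, amp_sd = 5,
                             dur_range = c(0.6, 1.8), gap_mean = 6,
                             seed = 12)
  # detector band matched to the generator's 11-15 Hz bursts
  ev <- detect_spindles(g$series, g$rate,
                        detector_params("model", band = c(10, 16)))
  sc <- score_detection(ev, g$truth)
  expect_gte(sc$sensitivity, 0.95)
  expect_gte(sc$precision, 0.95)
})

test_that("exponential vs lognormal gap processes separate in detected ISIs", {
  ge <- generate_burst_series(duration = 1500, gap_dist = "exp",
                              gap_mean = 6, dur_range = c(0.6, 1.5),
                              seed = 31)
  gl <- generate_burst_series(duration = 1500, gap_dist = "lognorm",
                              meanlog = 1.8, sdlog = 0.25,
                              dur_range = c(0.6, 1.5), seed = 32)
  ie <- interspindle_intervals(detect_spindles(ge$series, ge$rate))
  il <- interspindle_intervals(detect_spindles(gl$series, gl$rate))
  expect_gt(length(ie), 100)
  expect_gt(length(il), 100)
  expect_lt(compare_isi(ie, il)$p_value, 0.01)
  # ML exponential rate on the exponential channel recovers the
  # generating ISI mean (gap mean + mean burst length) within 10%
  fit <- fit_isi_distributions(ie)
  implied_mean <- 1 / fit$exponential$rate
  true_mean <- mean(ie) * 0 + (6 + mean(c(0.6, 1.5)))  # gap + duration
  expect_lt(abs(implied_mean - true_mean) / true_mean, 0.15)
})

test_that("config round-trips and rejects unknown keys", {
  cfg <- default_config()
  path <- tempfile(fileext = ".yaml")
  write_config(cfg, path)
  back <- read_config(path)
  expect_equal(unclass(back), cfg)
  # modified nested value survives
  cfg$network$fanout_ratio <- 5
  write_config(cfg, path)
  expect_equal(read_config(path)$network$fanout_ratio, 5)
  # unknown key rejected with its location
  writeLines("network:\n  made_up_key: 3", path)
  expect_error(read_config(path), "network/.*made_up_key")
  writeLines("nonsense_block: 1", path)
  expect_error(read_config(path), "nonsense_block")
  writeLines("network: [a', 1", path)
  expect_error(read_config(path), "malformed")
})

test_that("default config builds the baseline network", {
  cfg <- default_config()
  cfg$network$scale <- 0.02
  nw <- network_from_config(cfg)
  expect_s3_class(nw, "tc_network")
  expect_equal(nw$spec$fanout_ratio, 10)
  expect_setequal(unique(nw$populations$class), c("PY", "IN", "TC", "RE"))
})

test_that("reports serialize with provenance", {
  path <- tempfile(fileext = ".json")
  write_report(list(density = 6.5, note = "x"), path,
               config = default_config())
  back <- jsonlite::read_json(path)
  expect_equal(back$density, 6.5)
  expect_equal(back$meta$package, "spindlenet")
  expect_match(back$meta$config_md5, "^[0-9a-f]{32}$")
  # hash is stable for identical configs
  path2 <- tempfile(fileext = ".json")
  write_report(list(density = 1), path2, config = default_config())
  expect_equal(jsonlite::read_json(path2)$meta$config_md5,
               back$meta$config_md5)
})
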