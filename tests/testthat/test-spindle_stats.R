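# Spindle ensemble statistics.

mk_events <- function(onsets, durs = 1, channel = 1) {
  channel <- rep(channel, length.out = length(onsets))
  durs <- rep(durs, length.out = length(onsets))
  data.frame(channel = channel, onset_s = onsets,
             offset_s = onsets + durs,
             center_s = onsets + durs / 2, duration_s = durs,
             peak_freq_hz = rep(13, length(onsets)))
}

test_that("spindle density is count per minute, additive over records", {
  expect_equal(spindle_density(mk_events(numeric(0)), 60,
                               channels = 1)$density_per_min, 0)
  ev <- mk_events(seq(5, 115, 10))  # 12 events in 120 s
  expect_equal(spindle_density(ev, 120)$density_per_min, 6)
  # concatenating two equal-duration records averages densities
  ev2 <- mk_events(seq(5, 55, 10))  # 6 events in 60 s
  both <- rbind(ev2, mk_events(seq(65, 115, 25)))  # + 3 events
  d1 <- spindle_density(ev2, 60)$density_per_min
  d2 <- spindle_density(mk_events(seq(5, 55, 25)), 60)$density_per_min
  expect_equal(spindle_density(both, 120)$density_per_min, (d1 + d2) / 2)
})

test_that("lognormal ML fit recovers generating parameters", {
  set.seed(21)
  x <- rlnorm(1000, meanlog = 1, sdlog = 0.5)
  fit <- fit_isi_distributions(x)
  expect_true(fit$fitted)
  expect_lt(abs(fit$lognormal$meanlog - 1), 3 * fit$lognormal$se[1])
  expect_lt(abs(fit$lognormal$sdlog - 0.5), 3 * fit$lognormal$se[2])
  # exponential rate on exponential data
  y <- rexp(1000, rate = 0.25)
  fe <- fit_isi_distributions(y)
  expect_lt(abs(fe$exponential$rate - 0.25), 3 * fe$exponential$se)
  # long-tailed data flagged non-normal
  expect_lt(fit_isi_distributions(rlnorm(500, 0, 1))$lilliefors$p_value,
            0.01)
  expect_false(fit_isi_distributions(rexp(10))$fitted)
})

test_that("Lilliefors type-I error is calibrated on Gaussian data", {
  set.seed(31)
  rej <- vapply(1:200, function(i) {
    fit_isi_distributions(rnorm(1000, 10, 1))$lilliefors$p_value < 0.05
  }, logical(1))
  expect_lte(mean(rej), 0.10)  # ~5% nominal
})

test_that("KS comparison: identical samples give statistic 0", {
  x <- rexp(100)
  expect_equal(compare_isi(x, x)$statistic, 0)
  set.seed(5)
  r <- compare_isi(rlnorm(800, 1, 0.6), rexp(800, 1 / exp(1.2)))
  expect_lt(r$p_value, 0.01)
})

test_that("spatial correlation behaves on constructed channels", {
  set.seed(41)
  rate <- 200
  n <- 60 * rate
  ev <- mk_events(seq(5, 50, 5), durs = 2)
  ev_all <- do.call(rbind, lapply(1:4, function(ch) {
    transform(ev, channel = ch)
  }))
  # independent noise: mean correlation ~ 0
  noise <- matrix(rnorm(n * 4), n, 4)
  sc0 <- spatial_correlation(noise, rate, ev_all)
  expect_lt(abs(sc0$mean), 3 / sqrt(sum(ev$duration_s) * rate / 10))
  # common 13 Hz source + noise: correlation falls as noise grows
  tt <- (seq_len(n) - 1) / rate
  src <- sin(2 * pi * 13 * tt)
  mk <- function(sigma) src + sigma * rnorm(n)
  for (sigma in c(0.5, 2)) {
    ch <- cbind(mk(sigma), mk(sigma), mk(sigma), mk(sigma))
    sc <- spatial_correlation(ch, rate, ev_all)
    expect_gt(sc$mean, 0)
    if (sigma == 0.5) high <- sc$mean else expect_lt(sc$mean, high)
  }
  # self-correlation is 1 by construction of the estimator
  two <- cbind(src, src)
  expect_equal(spatial_correlation(two, rate, ev_all[ev_all$channel
                                                     %in% 1:2, ])$mean, 1)
  expect_warning(
    sc_na <- spatial_correlation(noise, rate, mk_events(numeric(0))),
    "no spindle epochs"
  )
  expect_true(is.na(sc_na$mean))
})

test_that("co-occurrence probabilities reproduce the asymmetry logic", {
  a <- mk_events(seq(0, 90, 10))            # 10 events
  b <- a[1:5, ]                             # exact sub-list
  r <- cooccurrence_probability(a, b)
  expect_equal(r$p_b_given_a, 0.5)
  expect_equal(r$p_a_given_b, 1.0)
  ident <- cooccurrence_probability(a, a)
  expect_equal(ident$p_b_given_a, 1)
  expect_equal(ident$p_a_given_b, 1)
  far <- cooccurrence_probability(a, mk_events(seq(500, 590, 10)))
  expect_equal(far$p_b_given_a, 0)
  expect_equal(far$p_a_given_b, 0)
})

test_that("onset delays pair nearest onsets with the window and sign", {
  core <- mk_events(1.0)
  mat <- mk_events(1.3)
  d <- onset_delays(core, mat)
  expect_equal(d$delays_ms, -300)  # negative: core precedes
  expect_length(onset_delays(mk_events(1), mk_events(5))$delays_ms, 0)
  # constructed pairing: each matrix event used at most once
  core2 <- mk_events(c(1, 1.2, 10))
  mat2 <- mk_events(c(1.1, 10.5))
  d2 <- onset_delays(core2, mat2)
  expect_equal(sort(d2$delays_ms), c(-500, -100))
  expect_equal(d2$mean_ms, -300)
})

test_that("spike phases lock to construction and histograms normalize", {
  rate <- 200
  dur <- 60
  tt <- (seq_len(dur * rate) - 1) / rate
  lfp <- cos(2 * pi * 10 * tt)
  ev <- do.call(rbind, lapply(seq(2, 54, 4), function(o) mk_events(o, 2)))
  # spikes at the cosine peaks of one neuron -> phase ~ 0
  peak_t <- seq(4, 50, 0.1)
  peak_t <- peak_t[abs((peak_t * 10) %% 1) < 1e-9]
  spikes <- data.frame(index = 1, time = peak_t * 1000)
  ph <- spike_phase_distribution(spikes, lfp, rate, ev, n_bins = 20)
  expect_equal(sum(ph$pooled$probability), 1)
  expect_lt(abs(mean(ph$phases)), 0.35)  # peak maps to phase 0
  # uniform random spikes -> flat histogram (chi-square, 200 reps)
  set.seed(61)
  rejections <- vapply(1:200, function(i) {
    st <- runif(400, 2, 56) * 1000
    sp <- data.frame(index = rep(1:4, each = 100), time = st)
    h <- spike_phase_distribution(sp, rnorm(length(tt)), rate, ev,
                                  n_bins = 10)
    counts <- h$pooled$probability * length(h$phases)
    suppressWarnings(chisq.test(counts)$p.value) < 0.05
  }, logical(1))
  expect_lt(mean(rejections), 0.12)
  # neurons with too few in-spindle spikes are excluded
  few <- data.frame(index = c(rep(1, 50), 2), time = c(runif(50, 2, 56),
                                                       10) * 1000)
  r <- spike_phase_distribution(few, lfp, rate, ev)
  expect_equal(r$n_neurons, 1)
  expect_true("2" %in% r$excluded_neurons)
})

test_that("phase comparison runs in both pooled and per-neuron modes", {
  rate <- 200
  tt <- (seq_len(40 * rate) - 1) / rate
  lfp <- cos(2 * pi * 10 * tt)
  ev <- do.call(rbind, lapply(seq(2, 34, 4), function(o) mk_events(o, 2)))
  set.seed(71)
  sp1 <- data.frame(index = rep(1:5, each = 60),
                    time = runif(300, 2, 36) * 1000)
  sp2 <- data.frame(index = rep(1:5, each = 60),
                    time = runif(300, 2, 36) * 1000)
  p1 <- spike_phase_distribution(sp1, lfp, rate, ev)
  p2 <- spike_phase_distribution(sp2, lfp, rate, ev)
  pooled <- compare_spike_phases(p1, p2, "pooled")
  expect_true(pooled$statistic >= 0 && pooled$statistic <= 1)
  per <- compare_spike_phases(p1, p2, "neurons")
  expect_true(is.finite(per$p_value))
})

test_that("network events merge overlapping channels into one event", {
  ev <- rbind(mk_events(c(1, 20), durs = 1, channel = 1),
              mk_events(c(1.4, 30), durs = 1, channel = 2),
              mk_events(c(1.8), durs = 1, channel = 3))
  ne <- network_events(ev)
  expect_equal(nrow(ne), 3)           # {1..2.8}, {20..21}, {30..31}
  expect_equal(ne$n_channels, c(3L, 1L, 1L))
  expect_equal(ne$onset_s[1], 1)
  expect_equal(ne$offset_s[1], 2.8)
  expect_equal(nrow(network_events(mk_events(numeric(0)))), 0)
})
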