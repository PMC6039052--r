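# Receptor kinetics, depression, NMDA gate, GABA-B cascade, minis.

test_that("synaptic current follows g * D * O * gate * (V - E)", {
  kin <- receptor_kinetics("AMPA")
  st <- list(O = 0.5, D = 1)
  expect_equal(synaptic_current(0.15, st, V_post = 0, kin), 0)
  expect_equal(synaptic_current(0.15, list(O = 0, D = 1), -70, kin), 0)
  # direct arithmetic: 0.15 * 1 * 0.5 * (-70 - 0) = -5.25
  expect_equal(synaptic_current(0.15, st, -70, kin), -5.25)
  # reversal potential zeroes the current for any receptor
  kg <- receptor_kinetics("GABA_A", target_class = "TC")
  expect_equal(kg$E_syn, -80)
  expect_equal(synaptic_current(1, st, -80, kg), 0)
  expect_error(synaptic_current(-1, st, 0, kin), "g_max")
})

test_that("depression follows the printed update and recovers", {
  # immediately after a spike from full resources: 1 * (1 - U)
  expect_equal(depression_update(1, 0, 0), 0.8)
  # hand-evaluated: D_i = 0.8, dt = tau -> 1 - (1 - 0.64) e^-1
  expect_equal(depression_update(0.8, 0, 500),
               1 - (1 - 0.8 * 0.8) * exp(-1), tolerance = 1e-12)
  # full recovery in the long run
  expect_equal(depression_update(0.3, 0, 1e6), 1)
  expect_error(depression_update(1, 100, 50), "t_i")
})

test_that("periodic driving converges to the closed-form fixed point", {
  for (delta in c(50, 200, 1000)) {
    D <- 1
    t <- 0
    for (i in 1:200) {
      D <- depression_update(D, t, t + delta)
      t <- t + delta
    }
    expect_equal(D, depression_fixed_point(delta), tolerance = 1e-6)
  }
})

test_that("depression stays in [0,1] under random spike trains", {
  set.seed(11)
  for (rep in 1:20) {
    times <- cumsum(rexp(200, 1 / 100))
    D <- 1
    t_prev <- -Inf
    for (t in times) {
      D <- depression_update(D, max(t_prev, t - 1e7), t)
      t_prev <- t
      expect_gte(D, 0)
      expect_lte(D, 1)
    }
  }
})

test_that("NMDA gate is a sigmoid centered at -25 mV", {
  expect_equal(nmda_voltage_gate(-25), 0.5)
  expect_equal(nmda_voltage_gate(-12.5), 1 / (1 + exp(-1)))
  expect_equal(nmda_voltage_gate(1e4), 1)
  expect_equal(nmda_voltage_gate(-1e4), 0)
  v <- seq(-90, 20, 5)
  expect_true(all(diff(nmda_voltage_gate(v)) > 0))
})

test_that("GABA-B cascade is slow and sums over spike trains", {
  quiet <- gabab_update(events = numeric(), t_end = 500)
  expect_true(all(quiet$factor == 0))
  one <- gabab_update(events = 0, t_end = 800)
  t_pk_b <- one$time[which.max(one$factor)]
  # GABA-A comparison: same spike through the first-order scheme
  ka <- receptor_kinetics("GABA_A")
  o <- 0
  oa <- numeric(8000)
  for (i in seq_along(oa)) {
    t <- (i - 1) * 0.1
    Tm <- if (t < ka$T_dur) ka$T_amp else 0
    o <- o + 0.1 * (ka$alpha * Tm * (1 - o) - ka$beta * o)
    oa[i] <- o
  }
  t_pk_a <- (which.max(oa) - 1) * 0.1
  expect_gte(t_pk_b - t_pk_a, 50)  # conductance peak delayed >= 50 ms
  train <- gabab_update(events = seq(0, 500, 100), t_end = 800)
  expect_gt(max(train$factor), max(one$factor))  # temporal summation
})

test_that("mini rate matches the printed formula", {
  expect_equal(mini_rate(0, 0), 0)
  expect_equal(mini_rate(1e7, 0), 1 / 250, tolerance = 1e-9)
  expect_equal(mini_rate(400, 0), (2 / (1 + exp(-1)) - 1) / 250)
  expect_error(mini_rate(-1, 0), "t0")
})

test_that("mini sampler matches its rate integral and is reproducible", {
  expect_identical(sample_mini_times(0, 5000, seed = 42),
                   sample_mini_times(0, 5000, seed = 42))
  # tiny horizon right after a spike: rate ~ 0
  expect_length(sample_mini_times(0, 5, seed = 1), 0)
  # empirical mean count vs numeric integral of the rate
  horizon <- 4000
  expected <- integrate(function(t) mini_rate(t, 0), 0, horizon)$value
  counts <- vapply(1:300, function(s) {
    length(sample_mini_times(0, horizon, seed = s))
  }, numeric(1))
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 3 * se + 1e-9)
})

test_that("mini sampler passes a time-rescaling check", {
  # transformed interarrival times Lambda(t_i) - Lambda(t_{i-1}) of an
  # inhomogeneous Poisson process are unit-rate exponential
  Lambda <- function(t) {
    vapply(t, function(ti) {
      integrate(function(u) mini_rate(u, 0), 0, ti)$value
    }, numeric(1))
  }
  pooled <- unlist(lapply(1:100, function(s) {
    tt <- sample_mini_times(0, 3000, seed = 1000 + s)
    if (length(tt) < 2) return(numeric())
    diff(Lambda(tt))
  }))
  ks <- suppressWarnings(ks.test(pooled, "pexp", 1))
  expect_gt(ks$p.value, 0.01)
})
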