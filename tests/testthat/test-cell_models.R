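# Single-cell dynamics of the four cell classes.

test_that("leak-only cells rest exactly at E_leak", {
  p <- thalamic_cell_params("TC", g_KL = 0, g_Na = 0, g_K = 0,
                            g_T = 0, g_h = 0)
  st <- setNames(c(p$E_leak, rep(0, 9)), thalamic_state_names)
  st["ca"] <- p$ca_inf
  d <- thalamic_derivatives(st, p)
  expect_equal(unname(d["V"]), 0)
  rest <- resting_state(p)
  expect_equal(unname(rest["V"]), p$E_leak, tolerance = 1e-3)
})

test_that("I_KL vanishes at its reversal potential", {
  p <- thalamic_cell_params("TC", g_leak = 0, g_Na = 0, g_K = 0,
                            g_T = 0, g_h = 0)
  st <- setNames(c(-95, rep(0, 9)), thalamic_state_names)
  st["ca"] <- p$ca_inf
  d <- thalamic_derivatives(st, p)
  expect_equal(unname(d["V"]), 0)  # only I_KL is left and E_KL = -95
})

test_that("derivatives reject non-finite state with a named diagnostic", {
  p <- thalamic_cell_params("TC")
  st <- setNames(c(-65, 0.1, 0.9, 0.1, 0.1, 0.5, 2.4e-4, 0, 0, 0),
                 thalamic_state_names)
  st["h_na"] <- NaN
  expect_error(thalamic_derivatives(st, p), "h_na")
  st["h_na"] <- 2
  expect_error(thalamic_derivatives(st, p), "h_na")
})

test_that("TC cells fire a rebound burst on release from hyperpolarization", {
  p <- thalamic_cell_params("TC")
  rest <- resting_state(p)
  r <- integrate_cell(p, duration = 2000, record_dt = 0.5, init = rest,
                      stim = list(t_on = 500, t_off = 1200, amp = -1.5))
  sp <- extract_spikes(r$V, dt = 0.5)
  rebound <- sp[sp > 1200 & sp < 1450]
  expect_gte(length(rebound), 2)
  # no spikes during the hyperpolarizing step itself
  expect_length(sp[sp > 600 & sp <= 1200], 0)
})

test_that("thalamic resting states are stable, deterministic and in range", {
  for (cls in c("TC", "RE")) {
    p <- thalamic_cell_params(cls)
    a <- resting_state(p)
    b <- resting_state(p)
    expect_identical(a, b)
    expect_gte(unname(a["V"]), -110)
    expect_lte(unname(a["V"]), -40)
    gates <- a[setdiff(names(a), c("V", "ca"))]
    expect_true(all(gates >= 0 & gates <= 1))
  }
})

test_that("cortical axial current balances across compartments", {
  p <- cortical_cell_params("PY")
  st <- setNames(c(-60, -70, rep(0.1, 9), 2.4e-4), cortical_state_names)
  res <- cortical_derivatives(st, p)
  s_d <- p$S_soma * p$R
  expect_equal(res$axial[["dend"]] * s_d,
               -res$axial[["soma"]] * p$S_soma, tolerance = 1e-12)
  # equal potentials: no axial current
  st2 <- st; st2["v_s"] <- -60
  res2 <- cortical_derivatives(st2, p)
  expect_equal(unname(res2$axial), c(0, 0))
  # coupling conductance is 1/r = 0.1 uS
  expect_equal(1e-3 / p$r_axial, 1e-4)
})

test_that("PY is regular spiking with adaptation, IN fast spiking", {
  ppy <- cortical_cell_params("PY")
  rpy <- resting_state(ppy)
  r <- integrate_cell(ppy, duration = 2500, record_dt = 0.5, init = rpy,
                      stim = list(t_on = 500, t_off = 2300, amp = 1.2))
  spy <- extract_spikes(r$V, dt = 0.5)
  spy <- spy[spy > 500 & spy < 2300]
  expect_gte(length(spy), 5)
  # slow, adapting discharge: the Ca-activated AHP stretches intervals
  # after the initial response, so the first interval is the shortest
  # and the sustained rate stays well below the fast-spiking regime
  expect_lt(diff(spy)[1], median(diff(spy)))
  expect_lt(length(spy) / 1.8, 25)  # sustained rate < 25 Hz
  pin <- cortical_cell_params("IN")
  expect_equal(pin$g_Nap_s, 0)  # no persistent Na+ in interneurons
  rin <- resting_state(pin)
  r2 <- integrate_cell(pin, duration = 2500, record_dt = 0.5, init = rin,
                       stim = list(t_on = 500, t_off = 2300, amp = 1.2))
  sin_ <- extract_spikes(r2$V, dt = 0.5)
  sin_ <- sin_[sin_ > 500 & sin_ < 2300]
  # fast spiking: higher sustained rate, near-constant intervals
  expect_gt(length(sin_), length(spy))
  cv <- sd(diff(sin_)) / mean(diff(sin_))
  expect_lt(cv, 0.3)
})

test_that("gating variables stay in [0,1] from random initial conditions", {
  set.seed(91)
  for (i in 1:25) {
    cls <- sample(c("TC", "RE", "PY", "IN"), 1)
    cortical <- cls %in% c("PY", "IN")
    p <- if (cortical) cortical_cell_params(cls) else
      thalamic_cell_params(cls)
    nm <- if (cortical) cortical_state_names else thalamic_state_names
    nv <- if (cortical) 2 else 1
    st <- setNames(runif(length(nm)), nm)
    st[seq_len(nv)] <- runif(nv, -90, -50)
    st["ca"] <- runif(1, 1e-4, 1e-3)
    r <- integrate_cell(p, duration = 1500, record_dt = 10, init = st)
    gates <- r$state[setdiff(nm, c("V", "v_d", "v_s", "ca"))]
    expect_true(all(gates >= -1e-9 & gates <= 1 + 1e-9), info = cls)
    expect_gte(r$state[["ca"]], 0)
    v <- if (cortical) r$state[["v_s"]] else r$state[["V"]]
    expect_true(v > -120 && v < 60, info = cls)
  }
})

test_that("halving dt changes a 1 s voltage trace by < 1 mV RMS", {
  for (cls in c("TC", "PY")) {
    p <- if (cls == "PY") cortical_cell_params(cls) else
      thalamic_cell_params(cls)
    rest <- resting_state(p)
    tr <- lapply(c(0.025, 0.0125), function(dt) {
      # subthreshold probe: spike-time micro-shifts would otherwise
      # dominate the RMS without reflecting integration error
      integrate_cell(p, duration = 1000, dt = dt, record_dt = 1,
                     init = rest,
                     stim = list(t_on = 200, t_off = 1000, amp = -0.3))$V
    })
    rms <- sqrt(mean((tr[[1]] - tr[[2]])^2))
    expect_lt(rms, 1)
  }
})

test_that("spike extraction finds constructed crossings", {
  expect_length(extract_spikes(rep(-65, 100), dt = 1), 0)
  v <- rep(-70, 1000)
  for (t0 in c(100, 400, 900)) v[t0:(t0 + 2)] <- c(0, 20, -10)
  expect_equal(extract_spikes(v, dt = 1), c(100, 400, 900))
  # refractory filtering
  v2 <- rep(-70, 100)
  v2[c(10, 11)] <- 10; v2[12] <- -30; v2[13] <- 10
  expect_length(extract_spikes(v2, dt = 1, refractory = 5), 1)
  # doubling the sampling rate moves times < 1 sample period
  tt <- seq(0, 200, 0.5)
  vv <- -65 + 80 * exp(-((tt - 100)^2) / 2)
  t1 <- extract_spikes(vv[seq(1, length(vv), 2)], dt = 1)
  t2 <- extract_spikes(vv, dt = 0.5)
  expect_lt(abs(t1 - t2), 1)
})
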