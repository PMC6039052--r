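# Receptor kinetics, short-term depression, NMDA voltage gate, GABA-B
# G-protein cascade, and the Poisson miniature-PSP process.

#' Receptor kinetic constants
#'
#' First-order transmitter-pulse kinetics for AMPA, NMDA and GABA-A
#' (open fraction `O` obeys `dO/dt = alpha T (1 - O) - beta O` with a
#' square transmitter pulse of `T_amp` mM for `T_dur` ms per presynaptic
#' event), and the rate constants of the GABA-B receptor / G-protein
#' cascade.  Constants are the standard set of this model family; the
#' source model defers them to its antecedents, so they are exposed here
#' for audit and override.  Reversal potentials: AMPA/NMDA 0 mV; GABA-A
#' -70 mV onto cortical cells and RE, -80 mV onto TC; GABA-B -95 mV.
#'
#' @param receptor one of `"AMPA"`, `"NMDA"`, `"GABA_A"`, `"GABA_B"`.
#' @param target_class optional postsynaptic class (`"TC"` switches the
#'   GABA-A reversal to -80 mV).
#' @param ... named overrides.
#' @return Named list with `receptor`, `alpha`, `beta` (1/ms; GABA-B
#'   instead carries `K1..K4`, `Kd`, `n_G`), `T_amp`, `T_dur`, `E_syn`.
#' @export
#' @examples
#' receptor_kinetics("GABA_A", target_class = "TC")$E_syn
receptor_kinetics <- function(receptor = c("AMPA", "NMDA", "GABA_A",
                                           "GABA_B"),
                              target_class = NULL, ...) {
  receptor <- match.arg(receptor)
  k <- switch(receptor,
    AMPA = list(receptor = "AMPA", alpha = 1.1, beta = 0.19,
                T_amp = 0.5, T_dur = 0.3, E_syn = 0),
    NMDA = list(receptor = "NMDA", alpha = 0.072, beta = 0.0066,
                T_amp = 0.5, T_dur = 0.3, E_syn = 0),
    GABA_A = list(receptor = "GABA_A", alpha = 5, beta = 0.18,
                  T_amp = 0.5, T_dur = 0.3, E_syn = -70),
    GABA_B = list(receptor = "GABA_B",
                  K1 = 0.09,   # receptor activation, 1/(mM ms)
                  K2 = 0.0012, # receptor deactivation, 1/ms
                  K3 = 0.18,   # G-protein production, 1/ms
                  K4 = 0.034,  # G-protein decay, 1/ms
                  Kd = 100, n_G = 4,
                  T_amp = 0.5, T_dur = 0.3, E_syn = -95)
  )
  if (receptor == "GABA_A" && identical(target_class, "TC")) {
    k$E_syn <- -80
  }
  override_params(k, list(...))
}

#' Postsynaptic current through one synapse
#'
#' `I_syn = g_max * D * O * gate * (V_post - E_syn)` (outward positive):
#' maximal conductance scaled by the depression variable `D`, the open
#' fraction `O`, the NMDA voltage gate (1 for other receptors) and the
#' driving force.
#'
#' @param g_max maximal conductance (>= 0).
#' @param state list with `O` (open fraction) and `D` (depression
#'   variable), both in `[0, 1]`.
#' @param V_post postsynaptic potential (mV).
#' @param kin a [receptor_kinetics()] list (supplies `E_syn`).
#' @param nmda_gate voltage-gate factor in `(0, 1]`; see
#'   [nmda_voltage_gate()].
#' @return Current (same conductance units times mV).
#' @export
synaptic_current <- function(g_max, state, V_post, kin, nmda_gate = 1) {
  stopifnot(g_max >= 0)
  g_max * state$D * state$O * nmda_gate * (V_post - kin$E_syn)
}

#' Short-term depression update
#'
#' Available synaptic resources immediately before an event at time `t`,
#' given availability `D_i` used at the previous event at `t_i`:
#' `D = 1 - (1 - D_i (1 - U)) exp(-(t - t_i) / tau)`.  `U` is the
#' fraction of resources consumed per action potential and `tau` the
#' recovery time constant.  Applied at each presynaptic event of
#' depressing (intracortical excitatory) connections.
#'
#' @param D_i availability used at the previous event, in `[0, 1]`.
#' @param t_i time of the previous event (ms).
#' @param t current event time (ms), `t >= t_i`.
#' @param U use fraction per event (default 0.2).
#' @param tau recovery time constant in ms (default 500).
#' @return Updated `D` in `[0, 1]`.
#' @export
#' @examples
#' depression_update(1, 0, 0)        # 0.8 immediately after a spike
#' depression_update(0.8, 0, 500)    # partial recovery after one tau
depression_update <- function(D_i, t_i, t, U = 0.2, tau = 500) {
  if (any(t < t_i)) stop("event time t must be >= previous time t_i")
  stopifnot(all(D_i >= 0 & D_i <= 1))
  1 - (1 - D_i * (1 - U)) * exp(-(t - t_i) / tau)
}

#' Steady-state depression under periodic driving
#'
#' Closed-form fixed point of [depression_update()] under spikes at a
#' fixed interval `delta`:
#' `D* = (1 - exp(-delta/tau)) / (1 - (1 - U) exp(-delta/tau))`.
#'
#' @param delta inter-spike interval (ms).
#' @inheritParams depression_update
#' @return The fixed-point availability.
#' @export
depression_fixed_point <- function(delta, U = 0.2, tau = 500) {
  e <- exp(-delta / tau)
  (1 - e) / (1 - (1 - U) * e)
}

#' NMDA voltage gate
#'
#' Sigmoid relief of the Mg2+ block with depolarization:
#' `1 / (1 + exp(-(V_post - V_th) / delta))` with `V_th = -25` mV and
#' `delta = 12.5` mV, equal to 0.5 at -25 mV.
#'
#' @param V_post postsynaptic potential (mV).
#' @param V_th half-activation voltage (mV).
#' @param delta slope (mV).
#' @return Gate factor in `(0, 1)`.
#' @export
nmda_voltage_gate <- function(V_post, V_th = -25, delta = 12.5) {
  1 / (1 + exp(-(V_post - V_th) / delta))
}

#' GABA-B receptor / G-protein cascade
#'
#' Integrates the second-messenger scheme: transmitter pulses activate
#' the receptor fraction `R` (`dR/dt = K1 T (1 - R) - K2 R`), activated
#' receptor drives G-protein `G` (`dG/dt = K3 R - K4 G`), and the K+
#' channel opens as `G^n / (G^n + Kd)`.  The cascade makes GABA-B slow
#' (conductance peak >= 50 ms after a spike, decay over hundreds of ms)
#' and strongly favours presynaptic bursts over single spikes.
#'
#' @param state list with `R` and `G` (both >= 0); use `NULL` for a
#'   naive synapse.
#' @param events presynaptic event times (ms), sorted.
#' @param t_end integrate from 0 to `t_end` ms.
#' @param dt integration step (ms).
#' @param kin a [receptor_kinetics]`("GABA_B")` list.
#' @return List with `time`, `factor` (conductance factor trace in
#'   `[0, 1]`), and final `state`.
#' @export
gabab_update <- function(state = NULL, events = numeric(), t_end,
                         dt = 0.1, kin = receptor_kinetics("GABA_B")) {
  if (is.null(state)) state <- list(R = 0, G = 0)
  stopifnot(state$R >= 0, state$G >= 0, t_end > 0)
  times <- seq(0, t_end, by = dt)
  Rv <- Gv <- numeric(length(times))
  R <- state$R; G <- state$G
  for (i in seq_along(times)) {
    t <- times[i]
    Tm <- if (length(events)) {
      d <- t - events
      as.numeric(any(d >= 0 & d < kin$T_dur)) * kin$T_amp
    } else 0
    R <- R + dt * (kin$K1 * Tm * (1 - R) - kin$K2 * R)
    G <- G + dt * (kin$K3 * R - kin$K4 * G)
    Rv[i] <- R; Gv[i] <- G
  }
  gn <- Gv^kin$n_G
  list(time = times, factor = gn / (gn + kin$Kd),
       state = list(R = R, G = G))
}

#' Miniature-PSP rate
#'
#' Time-dependent mean rate of the Poisson miniature-PSP process:
#' `mu(t) = (2 / (1 + exp(-(t - t0)/400)) - 1) / 250` events per ms,
#' where `t0` is the time of the last presynaptic spike.  The rate is 0
#' immediately after a presynaptic spike and recovers to the asymptote
#' `1/250` per ms (4 events/s) over roughly a second.
#'
#' @param t current time (ms), `t >= t0`.
#' @param t0 time of the last presynaptic spike (ms).
#' @return Rate in events/ms, in `[0, 1/250]`.
#' @export
mini_rate <- function(t, t0) {
  if (any(t < t0)) stop("t must be >= t0")
  (2 / (1 + exp(-(t - t0) / 400)) - 1) / 250
}

#' Sample miniature-PSP event times
#'
#' Draws an inhomogeneous Poisson sample with rate [mini_rate()] over
#' `[t0, t0 + horizon)` by thinning against the constant bound `1/250`
#' per ms.  Reproducible given `seed`.
#'
#' @param t0 time of the last presynaptic spike (ms).
#' @param horizon sampling horizon (ms), > 0.
#' @param seed optional integer seed (R RNG state is restored on exit).
#' @return Strictly increasing numeric vector of event times (ms).
#' @export
sample_mini_times <- function(t0, horizon, seed = NULL) {
  stopifnot(horizon > 0)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  mu_max <- 1 / 250
  t <- t0
  out <- numeric()
  repeat {
    t <- t + rexp(1, mu_max)
    if (t >= t0 + horizon) break
    if (runif(1) < mini_rate(t, t0) / mu_max) out <- c(out, t)
  }
  out
}
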