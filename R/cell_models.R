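# Single-compartment thalamic (TC, RE) and two-compartment cortical
# (PY, IN) Hodgkin-Huxley cell models.  Units throughout: mV, ms,
# mS/cm2, uA/cm2, uF/cm2, mM.  Rate functions live in src/kinetics.h;
# see the methods vignette for the full set with provenance notes.

#' Thalamic cell parameters
#'
#' Default membrane parameters for one-compartment thalamocortical relay
#' (TC) and thalamic reticular (RE) neurons.  Both carry fast Na+ and K+
#' spike currents, the low-threshold Ca2+ current I_T, and a K+ leak
#' `I_KL = g_KL (V - E_KL)` with `E_KL = -95` mV; TC cells additionally
#' carry the hyperpolarization-activated cation current I_h whose open
#' fraction is up-regulated by intracellular Ca2+ (the mechanism behind
#' spindle waxing and waning).
#'
#' Defaults: `Cm = 1` uF/cm2; TC `g_leak = 0.01`, `E_leak = -70`,
#' `g_KL = 0.03`, `g_Na = 90`, `g_K = 10`, `g_T = 2.2`, `g_h = 0.017`
#' mS/cm2, area `2.9e-4` cm2 (TC Ca2+ clearance is fast, `tau_ca = 20`
#' ms, so the Ca2+-gated I_h up-regulation integrates over a spindle
#' epoch rather than single bursts); RE `g_leak = 0.05`, `E_leak = -77`,
#' `g_Na = 100`, `g_K = 10`, `g_T = 2.3` mS/cm2, area `1.43e-4` cm2.
#' The source tables give the RE leak both as 0.05 and 0.005 mS/cm2;
#' the default is 0.05, which lets RE cells repolarize fast enough to
#' recover their T current between spindle cycles (0.005 produces a
#' one-shot oscillation).  The RE K+ leak conductance is not printed
#' and defaults to `0.005` mS/cm2.  `vtraub` positions the fast Na+/K+
#' threshold (about `vtraub + 13` mV): -60 for TC, -63 for RE, so
#' reticular bursts require coincident input rather than single EPSPs.
#'
#' @param cell_class `"TC"` or `"RE"`.
#' @param ... named overrides of any default parameter.
#' @return A named list of class `thalamic_cell_params`.
#' @export
#' @examples
#' p <- thalamic_cell_params("TC")
#' p$g_T
thalamic_cell_params <- function(cell_class = c("TC", "RE"), ...) {
  cell_class <- match.arg(cell_class)
  p <- if (cell_class == "TC") {
    list(
      cell_class = "TC", Cm = 1, area = 2.9e-4,
      g_leak = 0.01, E_leak = -70, g_KL = 0.03, E_KL = -95,
      g_Na = 90, E_Na = 50, g_K = 10, E_K = -95,
      g_T = 2.2, g_h = 0.017, E_h = -40,
      tau_ca = 20, ca_inf = 2.4e-4, vtraub = -60, ih_cac = 0.002
    )
  } else {
    list(
      cell_class = "RE", Cm = 1, area = 1.43e-4,
      g_leak = 0.05, E_leak = -77, g_KL = 0.005, E_KL = -95,
      g_Na = 100, E_Na = 50, g_K = 10, E_K = -95,
      g_T = 2.3, g_h = 0, E_h = -40,
      tau_ca = 165, ca_inf = 2.4e-4, vtraub = -63
    )
  }
  override_params(p, list(...))
}

#' Cortical cell parameters
#'
#' Default parameters for the two-compartment (axosomatic + dendritic)
#' cortical pyramidal (PY, regular spiking, dendrite/soma area ratio
#' `R = 165`) and interneuron (IN, fast spiking, `R = 50`) models.  The
#' axosomatic compartment is treated as having negligible capacitance so
#' its voltage is the instantaneous equilibrium of its very large spike
#' conductances (`g_Na = 3000`, `g_K = 200` mS/cm2) with the axial
#' current; the two compartments are coupled through an axial resistance of
#' 10 MOhm (coupling conductance 0.1 uS).  The dendrite carries the leak,
#' K+ leak, persistent Na+ (PY only), high-threshold Ca2+, Ca2+-activated
#' K+ and slow non-inactivating K+ currents plus all synaptic input.
#'
#' @param cell_class `"PY"` or `"IN"`.
#' @param ... named overrides of any default parameter.
#' @return A named list of class `cortical_cell_params`.
#' @export
#' @examples
#' cortical_cell_params("IN")$g_Nap_s  # interneurons carry no I_Na(p)
cortical_cell_params <- function(cell_class = c("PY", "IN"), ...) {
  cell_class <- match.arg(cell_class)
  py <- cell_class == "PY"
  p <- list(
    cell_class = cell_class,
    R = if (py) 165 else 50,
    r_axial = 10,            # MOhm between compartments
    S_soma = 1.0e-6,         # cm2; S_dend = S_soma * R
    # axosomatic compartment (zero capacitance, algebraic voltage)
    g_Na_s = 3000, g_K_s = 200, g_Nap_s = if (py) 0.07 else 0,
    # dendritic compartment
    Cm_d = 0.75, g_L = 0.033,
    E_leak = if (py) -68 else -75,
    g_KL = 0.0025, E_KL = -95,
    g_Na_d = 1.5, g_Nap_d = if (py) 0.07 else 0,
    g_HVA = 0.01, g_KCa = 0.3, g_Km = 0.01,
    E_Na = 50, E_K = -95,
    tau_ca = 165, ca_inf = 2.4e-4
  )
  override_params(p, list(...))
}

override_params <- function(p, dots) {
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad)) {
      stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    }
    p[names(dots)] <- dots
  }
  p
}

# state-vector slot order shared with the compiled core
thalamic_state_names <- c(
  "V", "m_na", "h_na", "n_k", "m_t", "h_t", "ca", "o1_h", "p1_h", "o2_h"
)

cortical_state_names <- c(
  "v_d", "v_s", "m_na_d", "h_na_d", "m_na_s", "h_na_s", "n_k_s",
  "n_km", "n_kca", "m_hva", "h_hva", "ca"
)

check_state <- function(state, names_expected) {
  if (is.null(names(state))) {
    if (length(state) != length(names_expected)) {
      stop("state must have ", length(names_expected), " elements")
    }
    names(state) <- names_expected
  }
  miss <- setdiff(names_expected, names(state))
  if (length(miss)) stop("state missing: ", paste(miss, collapse = ", "))
  bad <- names(state)[!is.finite(state[names_expected])]
  if (length(bad)) {
    stop("non-finite state variable(s): ", paste(bad, collapse = ", "))
  }
  gates <- setdiff(names_expected, c("V", "v_d", "v_s", "ca"))
  out <- state[gates][state[gates] < -1e-9 | state[gates] > 1 + 1e-9]
  if (length(out)) {
    stop("gating variable(s) outside [0,1]: ",
         paste(names(out), collapse = ", "))
  }
  if (state["ca"] < 0) stop("negative calcium concentration")
  state[names_expected]
}

#' Thalamic membrane derivatives
#'
#' Time derivatives of the one-compartment TC/RE state under
#' `Cm dV/dt = -g_leak (V - E_leak) - I_int - I_syn`, where `I_int` sums
#' the fast Na+ and K+ spike currents, the low-threshold Ca2+ current
#' I_T, the K+ leak I_KL and (TC only) I_h.  `I_syn` is a current
#' density in uA/cm2, positive outward.
#'
#' @param state named numeric vector with elements
#'   `V, m_na, h_na, n_k, m_t, h_t, ca, o1_h, p1_h, o2_h`.
#' @param params a [thalamic_cell_params()] list.
#' @param I_syn synaptic current density (uA/cm2, outward positive).
#' @return Named numeric vector of `d(state)/dt` (per ms).
#' @export
thalamic_derivatives <- function(state, params, I_syn = 0) {
  state <- check_state(state, thalamic_state_names)
  d <- thal_deriv_cpp(as.numeric(state), params, I_syn)
  setNames(d, thalamic_state_names)
}

#' Cortical membrane derivatives
#'
#' Time derivatives of the dendritic states of the two-compartment PY/IN
#' model, with the axosomatic voltage reported at its instantaneous
#' algebraic equilibrium (the axosomatic compartment has negligible
#' capacitance; its very fast spike conductances equilibrate with the
#' axial current within a time step).  Returned axial current densities
#' satisfy `I_axial_dend * S_dend = -I_axial_soma * S_soma` (equal total
#' current, opposite sign after area scaling).
#'
#' @param state named numeric vector with elements
#'   `v_d, v_s, m_na_d, h_na_d, m_na_s, h_na_s, n_k_s, n_km, n_kca,
#'   m_hva, h_hva, ca`.
#' @param params a [cortical_cell_params()] list.
#' @param I_syn synaptic current density onto the dendrite
#'   (uA/cm2, outward positive).
#' @return List with `derivs` (named vector, `v_s` slot holds the change
#'   toward its equilibrium), `v_s_star` (equilibrium axosomatic
#'   voltage given the current state), and `axial` (current densities
#'   `c(dend=, soma=)` evaluated at the supplied voltages).
#' @export
cortical_derivatives <- function(state, params, I_syn = 0) {
  state <- check_state(state, cortical_state_names)
  res <- cort_deriv_cpp(as.numeric(state), params, I_syn)
  list(
    derivs = setNames(res$derivs, cortical_state_names),
    v_s_star = res$v_s_star,
    axial = c(dend = res$ax_dend, soma = res$ax_soma)
  )
}

#' Resting state of a single cell
#'
#' Finds the cell's stable rest by relaxation: the model is integrated
#' for `duration` ms with zero synaptic input and the final state is
#' returned.  The call is deterministic.
#'
#' @param params a [thalamic_cell_params()] or [cortical_cell_params()]
#'   list.
#' @param duration relaxation time in ms (default 5000).
#' @param dt integration step (ms).
#' @return Named state vector at rest.
#' @export
#' @examples
#' resting_state(thalamic_cell_params("RE"))[["V"]]
resting_state <- function(params, duration = 5000, dt = 0.025) {
  r <- integrate_cell(params, duration = duration, dt = dt,
                      record_dt = duration)
  v <- if (is_cortical(params)) r$state[["v_s"]] else r$state[["V"]]
  if (!is.finite(v) || v < -110 || v > -40) {
    stop("no resting fixed point found in [-110, -40] mV (V = ",
         signif(v, 4), " mV); check parameters")
  }
  r$state
}

is_cortical <- function(params) {
  params$cell_class %in% c("PY", "IN")
}

#' Integrate a single cell
#'
#' Fixed-step integration of one isolated TC, RE, PY or IN cell with an
#' optional square current injection.  For cortical cells the injection
#' is delivered to the dendrite and the recorded voltage is axosomatic.
#'
#' @param params cell parameter list.
#' @param duration total simulated time (ms).
#' @param dt time step (ms).
#' @param stim optional list or data.frame with `t_on`, `t_off`, `amp`
#'   (uA/cm2; negative = hyperpolarizing) rows.
#' @param record_dt sampling interval of the returned voltage trace (ms).
#' @param init optional initial state vector (defaults to a standard
#'   hyperpolarized initialization).
#' @return List with `time` (ms), `V` (mV; axosomatic for cortical
#'   cells), `V_dend` (cortical only) and `state` (final state vector).
#' @export
integrate_cell <- function(params, duration, dt = 0.025, stim = NULL,
                           record_dt = 1, init = NULL) {
  stopifnot(duration > 0, dt > 0)
  if (is.null(stim)) {
    stim <- list(t_on = numeric(), t_off = numeric(), amp = numeric())
  }
  cortical <- is_cortical(params)
  nm <- if (cortical) cortical_state_names else thalamic_state_names
  if (!is.null(init)) init <- as.numeric(check_state(init, nm))
  res <- single_cell_cpp(
    type = cell_type_code(params$cell_class), params = params,
    dt = dt, duration = duration,
    stim_on = as.numeric(stim$t_on), stim_off = as.numeric(stim$t_off),
    stim_amp = as.numeric(stim$amp),
    record_dt = record_dt, init = init
  )
  out <- list(time = res$time, V = res$V,
              state = setNames(res$state, nm))
  if (cortical) out$V_dend <- res$V_dend
  out
}

cell_type_code <- function(cell_class) {
  match(cell_class, c("TC", "RE", "PY", "IN")) - 1L
}

#' Extract spike times from a voltage trace
#'
#' Spikes are upward crossings of `threshold` (default -20 mV) with a
#' refractory gap: crossings closer than `refractory` ms to the previous
#' accepted spike are ignored.  Robust to subthreshold oscillations.
#'
#' @param v numeric voltage trace, uniformly sampled.
#' @param dt sample interval in ms (or use `rate` in Hz).
#' @param threshold crossing threshold (mV).
#' @param refractory minimum separation between spikes (ms).
#' @param rate sampling rate in Hz; overrides `dt` when given.
#' @return Numeric vector of spike times in ms.
#' @export
extract_spikes <- function(v, dt = 1, threshold = -20, refractory = 2,
                           rate = NULL) {
  if (!is.null(rate)) dt <- 1000 / rate
  n <- length(v)
  if (n < 2) return(numeric())
  up <- which(v[-1] >= threshold & v[-n] < threshold)
  if (!length(up)) return(numeric())
  times <- (up + 1) * dt  # sample j sits at time j * dt
  keep <- logical(length(times))
  last <- -Inf
  for (i in seq_along(times)) {
    if (times[i] - last >= refractory) {
      keep[i] <- TRUE
      last <- times[i]
    }
  }
  times[keep]
}
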