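# Time-stepped integration of the full network: R-side configuration,
# initial-condition handling and result assembly around the compiled
# core (src/netsim.cpp).

#' Simulation configuration
#'
#' @param duration simulated time in seconds.
#' @param dt integration step in ms (default 0.025; chosen for the
#'   stiff axosomatic kinetics, see the methods vignette).
#' @param transient_discard initial span (s) excluded from downstream
#'   statistics (the simulator records it; analysis functions drop it).
#' @param seed integer seed governing both the initial-voltage jitter
#'   and the miniature-PSP streams.
#' @param lfp_rate sampling rate (Hz) of recorded synaptic-current
#'   series (bin-averaged before storage).
#' @param n_groups number of non-overlapping, contiguous LFP groups
#'   per recorded cortical layer (default 10).
#' @param record_layers PY populations whose dendritic synaptic
#'   currents are recorded (defaults to all PY populations present).
#' @param record_cells also keep per-cell current series (memory-heavy;
#'   only sensible for small networks).
#' @param record_v optional data.frame(`pop`, `index`) of cells whose
#'   somatic voltage traces to record at `lfp_rate`.
#' @param mini_scale amplitude of a miniature PSP as a fraction of the
#'   evoked per-synapse conductance of the same synapse.
#' @param v_jitter half-width (mV) of the uniform initial-voltage
#'   jitter that breaks spatial symmetry.
#' @param stim optional data.frame(`pop`, `index`, `t_on`, `t_off`,
#'   `amp`) of square current injections (ms, uA/cm2; cortical cells
#'   receive it dendritically).
#' @param cell_params optional named list of per-class parameter
#'   overrides, e.g. `list(RE = thalamic_cell_params("RE", g_KL = 0.01))`.
#' @param syn_kinetics optional named list of per-receptor
#'   [receptor_kinetics()] overrides, e.g.
#'   `list(GABA_A = receptor_kinetics("GABA_A", beta = 0.1))`.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(duration, dt = 0.025, transient_discard = 5,
                       seed = 1L, lfp_rate = 1000, n_groups = 10,
                       record_layers = NULL, record_cells = FALSE,
                       record_v = NULL, mini_scale = 0.15,
                       v_jitter = 2, stim = NULL, cell_params = list(),
                       syn_kinetics = list()) {
  stopifnot(duration > 0, dt > 0, duration > transient_discard ||
              transient_discard == 0 || duration * 1 > 0)
  if (duration <= transient_discard) {
    stop("duration must exceed transient_discard")
  }
  structure(
    list(duration = duration, dt = dt,
         transient_discard = transient_discard, seed = as.integer(seed),
         lfp_rate = lfp_rate, n_groups = n_groups,
         record_layers = record_layers, record_cells = record_cells,
         record_v = record_v, mini_scale = mini_scale,
         v_jitter = v_jitter, stim = stim, cell_params = cell_params,
         syn_kinetics = syn_kinetics),
    class = "sim_config"
  )
}

default_cell_params <- function(overrides = list()) {
  p <- list(TC = thalamic_cell_params("TC"),
            RE = thalamic_cell_params("RE"),
            PY = cortical_cell_params("PY"),
            IN = cortical_cell_params("IN"))
  for (nm in names(overrides)) p[[nm]] <- overrides[[nm]]
  p
}

#' Run a network simulation
#'
#' Integrates every cell and synapse of a built network with a fixed
#' step.  Each cell starts from its class resting state (found by
#' relaxation) plus a small seeded voltage jitter; miniature-PSP event
#' streams are drawn per synapse from a generator seeded by
#' `config$seed`, so an identical seed and configuration reproduces the
#' spike raster exactly.  Integration aborts with a diagnostic naming
#' the cell and time if any membrane potential leaves +/-150 mV.
#'
#' @param network a [build_network()] result.
#' @param config a [sim_config()].
#' @return List of class `sim_result`: `spikes` (data.frame `pop`,
#'   `index`, `time` in ms), `lfp` (named list of time x group matrices
#'   of mean dendritic synaptic current, outward positive), `lfp_rate`,
#'   `groups` (group membership bounds), optional `cell_currents` and
#'   `v_traces`, `config`, `duration` (s) and `elapsed` (s).
#' @export
run_simulation <- function(network, config) {
  stopifnot(inherits(network, "tc_network"), inherits(config, "sim_config"))
  t0 <- proc.time()[["elapsed"]]
  pops <- network$populations
  params <- default_cell_params(config$cell_params)

  record_layers <- config$record_layers
  if (is.null(record_layers)) {
    record_layers <- pops$name[pops$class == "PY"]
  }
  stopifnot(all(record_layers %in% pops$name))

  # initial conditions: class rest + seeded uniform V jitter
  init <- resting_states_cached(params, config$dt)
  set.seed(config$seed)
  init_mats <- lapply(seq_len(nrow(pops)), function(i) {
    cls <- pops$class[i]
    st <- init[[cls]]
    m <- matrix(st, nrow = length(st), ncol = pops$size[i])
    jit <- runif(pops$size[i], -config$v_jitter, config$v_jitter)
    m[1, ] <- m[1, ] + jit  # V or v_d is slot 1
    if (cls %in% c("PY", "IN")) m[2, ] <- m[2, ] + jit
    m
  })

  pop_index <- setNames(seq_len(nrow(pops)) - 1L, pops$name)
  e <- network$edges
  offs <- setNames(pops$offset, pops$name)
  src_gid <- offs[e$source] + e$source_idx - 1L
  tgt_gid <- offs[e$target] + e$target_idx - 1L
  rec_code <- match(e$receptor, c("AMPA", "NMDA", "GABA_A", "GABA_B")) - 1L

  stim <- config$stim
  if (is.null(stim)) {
    stim <- data.frame(pop = character(), index = integer(),
                       t_on = numeric(), t_off = numeric(),
                       amp = numeric())
  }
  stim_gid <- if (nrow(stim)) offs[stim$pop] + stim$index - 1L else integer()

  rv <- config$record_v
  record_v_gid <- if (is.null(rv)) integer() else offs[rv$pop] + rv$index - 1L

  sk <- config$syn_kinetics
  ka <- if (!is.null(sk$AMPA)) sk$AMPA else receptor_kinetics("AMPA")
  kn <- if (!is.null(sk$NMDA)) sk$NMDA else receptor_kinetics("NMDA")
  kg <- if (!is.null(sk$GABA_A)) sk$GABA_A else receptor_kinetics("GABA_A")
  kb <- if (!is.null(sk$GABA_B)) sk$GABA_B else receptor_kinetics("GABA_B")
  syn_const <- c(
    ampa_alpha = ka$alpha, ampa_beta = ka$beta,
    nmda_alpha = kn$alpha, nmda_beta = kn$beta,
    gabaa_alpha = kg$alpha, gabaa_beta = kg$beta,
    K1 = kb$K1, K2 = kb$K2, K3 = kb$K3, K4 = kb$K4, Kd = kb$Kd,
    T_amp = ka$T_amp, T_dur = ka$T_dur,
    nmda_vth = -25, nmda_delta = 12.5
  )

  res <- run_network_cpp(
    pop_class = cell_type_code(pops$class), pop_size = pops$size,
    params = params[pops$class],
    init = init_mats,
    src = as.integer(src_gid), tgt = as.integer(tgt_gid),
    rec = as.integer(rec_code),
    w = e$weight_density, depressing = e$depressing, mini = e$mini,
    syn_const = syn_const,
    depress_U = 0.2, depress_tau = 500,
    dt = config$dt, duration_ms = config$duration * 1000,
    lfp_dt = 1000 / config$lfp_rate, seed = config$seed,
    mini_scale = config$mini_scale,
    record_pops = as.integer(pop_index[record_layers]),
    n_groups = as.integer(config$n_groups),
    record_cells = isTRUE(config$record_cells),
    record_v = as.integer(record_v_gid),
    stim_gid = as.integer(stim_gid), stim_on = as.numeric(stim$t_on),
    stim_off = as.numeric(stim$t_off), stim_amp = as.numeric(stim$amp)
  )

  gid <- res$spike_id
  pop_of <- findInterval(gid, pops$offset)
  spikes <- data.frame(
    pop = pops$name[pop_of],
    index = gid - pops$offset[pop_of] + 1L,
    time = res$spike_t
  )
  lfp <- res$lfp
  names(lfp) <- record_layers
  groups <- lapply(setNames(record_layers, record_layers), function(nm) {
    n <- pops$size[pops$name == nm]
    gs <- n %/% config$n_groups
    data.frame(group = seq_len(config$n_groups),
               from = (seq_len(config$n_groups) - 1L) * gs + 1L,
               to = seq_len(config$n_groups) * gs)
  })
  out <- list(spikes = spikes, lfp = lfp, lfp_rate = config$lfp_rate,
              groups = groups, populations = pops, config = config,
              duration = config$duration,
              elapsed = proc.time()[["elapsed"]] - t0)
  if (isTRUE(config$record_cells)) {
    out$cell_currents <- res$cell_currents
    names(out$cell_currents) <- record_layers
  }
  if (length(record_v_gid)) {
    out$v_traces <- res$v_traces
    names(out$v_traces) <- paste0(rv$pop, "_", rv$index)
  }
  class(out) <- "sim_result"
  out
}

#' @export
print.sim_result <- function(x, ...) {
  cat("sim_result:", x$duration, "s,", nrow(x$spikes), "spikes,",
      length(x$lfp), "recorded layer(s); elapsed",
      round(x$elapsed, 1), "s\n")
  invisible(x)
}

# resting states are deterministic per (class, params, dt); cache them
.rest_cache <- new.env(parent = emptyenv())

resting_states_cached <- function(params, dt) {
  out <- list()
  for (cls in unique(names(params))) {
    key <- paste0(cls, "|", dt, "|",
                  paste(unlist(params[[cls]]), collapse = ","))
    if (is.null(.rest_cache[[key]])) {
      .rest_cache[[key]] <- resting_state(params[[cls]], dt = dt)
    }
    out[[cls]] <- .rest_cache[[key]]
  }
  out
}

#' Mean firing rate of a population
#'
#' @param sim a [run_simulation()] result.
#' @param pop population name (prefix match allowed, e.g. `"PY"`).
#' @param from,to analysis window in seconds (defaults to the
#'   post-transient span).
#' @return Mean rate in Hz per cell.
#' @export
population_rate <- function(sim, pop, from = NULL, to = NULL) {
  if (is.null(from)) from <- sim$config$transient_discard
  if (is.null(to)) to <- sim$duration
  stopifnot(to > from)
  sel_pop <- startsWith(sim$populations$name, pop)
  if (!any(sel_pop)) stop("no population matches '", pop, "'")
  n_cells <- sum(sim$populations$size[sel_pop])
  sel <- startsWith(sim$spikes$pop, pop) &
    sim$spikes$time >= from * 1000 & sim$spikes$time < to * 1000
  sum(sel) / n_cells / (to - from)
}
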