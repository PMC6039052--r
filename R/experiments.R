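# Drivers for the standard computational experiments: baseline
# analysis, fanout-ratio sweep, interlaminar-strength sweeps, and the
# reduced one-layer model.

#' Analyze a simulation into a spindle statistics report
#'
#' Band-passes the recorded LFP of the core (L3/4) and matrix (L5)
#' layers, detects spindles per LFP group, and assembles the standard
#' statistics: per-channel density, pooled inter-spindle intervals and
#' distribution fits, durations, spatial correlation, core/matrix
#' co-occurrence, and onset delays.  The configured transient is
#' discarded before analysis.
#'
#' @param sim a [run_simulation()] result with `PY_L34` and `PY_L5`
#'   recorded (or a single layer for one-layer networks).
#' @param params a [detector_params()] list.
#' @param core_layer,matrix_layer population names backing the two
#'   systems' LFP.
#' @return List of class `stats_report`.
#' @export
analyze_simulation <- function(sim, params = detector_params("model"),
                               core_layer = "PY_L34",
                               matrix_layer = "PY_L5") {
  rate <- sim$lfp_rate
  cut <- round(sim$config$transient_discard * rate)
  analyzed <- sim$duration - sim$config$transient_discard
  trim <- function(m) m[(cut + 1):nrow(m), , drop = FALSE]

  one_layer <- !(matrix_layer %in% names(sim$lfp))
  layers <- c(core = core_layer,
              if (!one_layer) c(matrix = matrix_layer))
  sys <- lapply(layers, function(nm) {
    raw <- trim(sim$lfp[[nm]])
    fb <- bandpass(raw, rate, params$band[1], params$band[2])
    ev <- detect_spindles(fb, rate, params)
    isi <- interspindle_intervals(ev, params$isi_exclusion)
    list(
      layer = nm, events = ev, lfp_band = fb,
      density = spindle_density(ev, analyzed,
                                channels = seq_len(ncol(fb))),
      isi = isi, isi_fit = fit_isi_distributions(isi),
      duration = ev$duration_s,
      spatial = spatial_correlation(fb, rate, ev)
    )
  })
  report <- list(
    analyzed_s = analyzed,
    core = sys$core,
    matrix = if (!one_layer) sys$matrix,
    mean_density = vapply(sys, function(s) {
      mean(s$density$density_per_min)
    }, numeric(1))
  )
  if (!one_layer) {
    report$cooccurrence <- cooccurrence_probability(sys$core$events,
                                                    sys$matrix$events)
    report$delays <- onset_delays(sys$core$events, sys$matrix$events)
    report$isi_ks <- if (length(sys$core$isi) && length(sys$matrix$isi)) {
      compare_isi(sys$core$isi, sys$matrix$isi)
    }
  }
  class(report) <- "stats_report"
  report
}

#' @export
print.stats_report <- function(x, ...) {
  cat("stats_report over", round(x$analyzed_s, 1), "s\n")
  cat("  core:  ", nrow(x$core$events), "events,",
      round(x$mean_density[["core"]], 2), "per min\n")
  if (!is.null(x$matrix)) {
    cat("  matrix:", nrow(x$matrix$events), "events,",
        round(x$mean_density[["matrix"]], 2), "per min\n")
    cat("  P(core | matrix) =",
        round(x$cooccurrence$p_a_given_b, 3),
        "; P(matrix | core) =",
        round(x$cooccurrence$p_b_given_a, 3), "\n")
    cat("  mean onset delay:", round(x$delays$mean_ms, 1), "ms\n")
  }
  invisible(x)
}

run_condition <- function(spec_args, duration, seeds, sim_args = list(),
                          params = detector_params("model")) {
  lapply(seeds, function(s) {
    nw <- build_network(do.call(network_spec, spec_args))
    cfg <- do.call(sim_config, c(list(duration = duration, seed = s),
                                 sim_args))
    analyze_simulation(run_simulation(nw, cfg), params = params)
  })
}

summarize_reports <- function(reports) {
  g <- function(f) vapply(reports, f, numeric(1))
  data.frame(
    core_density = mean(g(function(r) r$mean_density[["core"]])),
    matrix_density = if (!is.null(reports[[1]]$matrix)) {
      mean(g(function(r) r$mean_density[["matrix"]]))
    } else NA_real_,
    p_core_given_matrix = if (!is.null(reports[[1]]$matrix)) {
      mean(g(function(r) r$cooccurrence$p_a_given_b), na.rm = TRUE)
    } else NA_real_,
    p_matrix_given_core = if (!is.null(reports[[1]]$matrix)) {
      mean(g(function(r) r$cooccurrence$p_b_given_a), na.rm = TRUE)
    } else NA_real_,
    mean_delay_ms = if (!is.null(reports[[1]]$matrix)) {
      mean(g(function(r) {
        d <- r$delays$mean_ms
        if (is.null(d) || !length(d)) NA_real_ else d
      }), na.rm = TRUE)
    } else NA_real_,
    core_spatial = mean(g(function(r) r$core$spatial$mean), na.rm = TRUE),
    matrix_spatial = if (!is.null(reports[[1]]$matrix)) {
      mean(g(function(r) r$matrix$spatial$mean), na.rm = TRUE)
    } else NA_real_
  )
}

#' Fanout-ratio sweep
#'
#' Rebuilds and simulates the network across matrix/core fanout
#' ratios.  The core radii stay at (10, 2) while the matrix radii are
#' (10, 2) x ratio, i.e. ratios 1..15 correspond to the radius
#' quadruples 10/2/10/2 through 10/2/150/30.
#'
#' @param ratios fanout ratios (default the printed set).
#' @param scale network-size multiplier for desk runs.
#' @param duration simulated seconds per run.
#' @param seeds one run per seed per ratio.
#' @param spec_args,sim_args extra arguments for [network_spec()] and
#'   [sim_config()].
#' @return List with `summary` (one row per ratio) and `reports`.
#' @export
fanout_sweep <- function(ratios = c(1, 2.5, 5, 7.5, 10, 12.5, 15),
                         scale = 0.2, duration = 120, seeds = 1:5,
                         spec_args = list(), sim_args = list()) {
  stopifnot(length(ratios) >= 1, all(ratios >= 1))
  reports <- lapply(ratios, function(rt) {
    run_condition(c(list(scale = scale, fanout_ratio = rt), spec_args),
                  duration, seeds, sim_args)
  })
  names(reports) <- paste0("ratio_", ratios)
  summary <- do.call(rbind, lapply(reports, summarize_reports))
  summary <- cbind(data.frame(ratio = ratios), summary)
  rownames(summary) <- NULL
  list(summary = summary, reports = reports)
}

#' Interlaminar-strength sweep
#'
#' Scales only the AMPA + NMDA totals of one interlaminar projection
#' (L3/4 to L5, or L5 to L3/4); 100% is the baseline, which equals
#' half the intralaminar strength.
#'
#' @param direction `"l34_l5"` or `"l5_l34"`.
#' @param strengths percentages of the baseline (0 disconnects).
#' @inheritParams fanout_sweep
#' @return List with `summary` (one row per strength) and `reports`.
#' @export
interlaminar_sweep <- function(direction = c("l34_l5", "l5_l34"),
                               strengths = c(0, 50, 100, 140, 150),
                               scale = 0.2, duration = 120, seeds = 1:5,
                               spec_args = list(), sim_args = list()) {
  direction <- match.arg(direction)
  stopifnot(all(strengths >= 0))
  arg <- if (direction == "l34_l5") "interlaminar_l34_l5" else
    "interlaminar_l5_l34"
  reports <- lapply(strengths, function(pc) {
    sa <- c(list(scale = scale), spec_args)
    sa[[arg]] <- pc / 100
    run_condition(sa, duration, seeds, sim_args)
  })
  names(reports) <- paste0("strength_", strengths)
  summary <- do.call(rbind, lapply(reports, summarize_reports))
  summary <- cbind(data.frame(direction = direction,
                              strength_pct = strengths), summary)
  rownames(summary) <- NULL
  list(summary = summary, reports = reports)
}

#' Reduced one-layer model
#'
#' One cortical layer reciprocally coupled to one thalamic system, with
#' per-synapse weights fixed (no input-count normalization), used to
#' separate the effects of thalamocortical/corticothalamic strength
#' from fanout.
#'
#' @param vary `"tc_strength"`, `"ct_strength"`, `"tc_fanout"` or
#'   `"ct_fanout"`.
#' @param values multipliers (strength) or radii in full-scale source
#'   units (fanout).
#' @inheritParams fanout_sweep
#' @return List with `summary` (density, duration, mean cross-group
#'   correlation per value) and `reports`.
#' @export
one_layer_model <- function(vary = c("tc_strength", "ct_strength",
                                     "tc_fanout", "ct_fanout"),
                            values, scale = 0.2, duration = 120,
                            seeds = 1:5, spec_args = list(),
                            sim_args = list()) {
  vary <- match.arg(vary)
  reports <- lapply(values, function(v) {
    sa <- c(list(scale = scale, variant = "onelayer",
                 normalize = FALSE), spec_args)
    sa[[sub("_(strength|fanout)", "", vary) |>
          paste0(if (grepl("strength", vary)) "_strength"
                 else "_radius")]] <- v
    lapply(seeds, function(s) {
      nw <- build_network(do.call(network_spec, sa))
      cfg <- do.call(sim_config, c(list(duration = duration, seed = s),
                                   sim_args))
      analyze_simulation(run_simulation(nw, cfg),
                         core_layer = "PY_L1",
                         matrix_layer = "PY_L1_none")
    })
  })
  names(reports) <- paste0(vary, "_", values)
  summary <- do.call(rbind, lapply(reports, function(rs) {
    data.frame(
      density = mean(vapply(rs, function(r) {
        r$mean_density[["core"]]
      }, numeric(1))),
      duration = mean(vapply(rs, function(r) {
        if (length(r$core$duration)) mean(r$core$duration) else NA_real_
      }, numeric(1)), na.rm = TRUE),
      synchrony = mean(vapply(rs, function(r) {
        s <- r$core$spatial$mean
        if (is.null(s)) NA_real_ else s
      }, numeric(1)), na.rm = TRUE)
    )
  }))
  summary <- cbind(data.frame(vary = vary, value = values), summary)
  rownames(summary) <- NULL
  list(summary = summary, reports = reports)
}
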