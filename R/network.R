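# Network geometry: three cortical layers (L3/4, L5, L6) of PY + IN
# cells plus two separated thalamic systems (core, matrix) of TC + RE
# cells on a 1D axis, with fanout radii and input-count weight
# normalization.

#' Construct a network specification
#'
#' Describes the baseline architecture: 1000 PY per cortical layer
#' (L3/4, L5, L6), interneurons per layer (default 200), and 200 TC +
#' 200 RE per thalamic system.  The core thalamus projects focally to
#' L3/4 (radius 10 thalamic units) with corticothalamic return from L6
#' (radius 2 cortical units); the matrix thalamus projects diffusely to
#' the dendrites of L5 cells with reciprocal L5 return, both radii
#' scaled by `fanout_ratio` (baseline 10, i.e. radii 100/20).  The two
#' thalamic systems share no synapses.  Intracortical and intrathalamic
#' radii are not printed in the source tables; defaults (PY-PY 5,
#' PY-IN 1, IN-PY 5, interlaminar 5, intrathalamic 4) are local
#' footprints standard for this model family and are exposed here.
#'
#' `scale` shrinks every population (and the thalamocortical /
#' corticothalamic / intrathalamic radii with them, preserving the
#' fraction of the axis each projection covers) for desk-scale runs;
#' intracortical radii are absolute local footprints and do not shrink.
#'
#' @param scale population-size multiplier (1 = full size).
#' @param fanout_ratio matrix/core thalamocortical radius ratio
#'   (baseline 10; 1 makes the two systems geometrically identical).
#' @param in_per_layer interneurons per cortical layer.  The source
#'   description's total of 400 interneurons is arithmetically
#'   inconsistent with three layers; the default keeps the 1:5 IN:PY
#'   ratio per layer (200 at full scale).
#' @param interlaminar_nmda `"half"` (default: half the intralaminar
#'   NMDA total, 0.03) or `"printed"` (0.75, the value printed in the
#'   source table, 12.5x the intralaminar value).
#' @param interlaminar_l34_l5,interlaminar_l5_l34 strength multipliers
#'   for the two interlaminar projections (1 = baseline = half the
#'   intralaminar strength).
#' @param syn_unit_scale global calibration factor mapping printed
#'   total conductances (uS per connection type) to conductance
#'   densities on the target compartment; see the methods vignette.
#' @param variant `"full"` (three layers, two systems) or `"onelayer"`
#'   (one cortical layer + one thalamic system, used for reduced-model
#'   sweeps).
#' @param normalize divide each connection's total conductance by the
#'   per-target input count (the baseline rule); `FALSE` fixes the
#'   per-synapse weight at the baseline interior value independent of
#'   fanout (reduced-model mode).
#' @param tc_radius,ct_radius,tc_strength,ct_strength one-layer variant
#'   only: thalamocortical / corticothalamic radii (full-scale source
#'   units) and strength multipliers.
#' @param ... radius overrides: `py_py_radius`, `py_in_radius`,
#'   `in_py_radius`, `interlaminar_radius`, `intrathalamic_radius`,
#'   `core_tc_radius`, `core_ct_radius`.
#' @return A list of class `network_spec` with `populations` and
#'   `rules` data frames.
#' @export
#' @examples
#' spec <- network_spec(scale = 0.1)
#' subset(spec$rules, source == "TC_matrix")
network_spec <- function(scale = 1, fanout_ratio = 10,
                         in_per_layer = 200,
                         interlaminar_nmda = c("half", "printed"),
                         interlaminar_l34_l5 = 1,
                         interlaminar_l5_l34 = 1,
                         syn_unit_scale = 2,
                         variant = c("full", "onelayer"),
                         normalize = TRUE,
                         tc_radius = 10, ct_radius = 2,
                         tc_strength = 1, ct_strength = 1, ...) {
  variant <- match.arg(variant)
  interlaminar_nmda <- match.arg(interlaminar_nmda)
  stopifnot(scale > 0, fanout_ratio >= 1)
  r <- modifyList(
    list(py_py_radius = 5, py_in_radius = 1, in_py_radius = 5,
         interlaminar_radius = 5, intrathalamic_radius = 4,
         core_tc_radius = 10, core_ct_radius = 2),
    list(...)
  )
  sz <- function(n) max(2L, as.integer(round(n * scale)))
  thal_r <- function(x) max(1, x * scale)  # radii scale with the axis
  # corticothalamic radii stay absolute: the per-target input count of
  # a cortex->thalamus rule is 2r+1 independent of network size, and
  # that count (5 core vs 41 matrix at ratio 10) carries the
  # ignition-threshold asymmetry between the systems.  Scaling it down
  # would floor both systems to the same handful of inputs.
  ct_r <- identity
  g_il_nmda <- if (interlaminar_nmda == "half") 0.03 else 0.75

  if (variant == "full") {
    populations <- data.frame(
      name = c("PY_L34", "PY_L5", "PY_L6",
               "IN_L34", "IN_L5", "IN_L6",
               "TC_core", "RE_core", "TC_matrix", "RE_matrix"),
      class = c("PY", "PY", "PY", "IN", "IN", "IN",
                "TC", "RE", "TC", "RE"),
      size = c(rep(sz(1000), 3), rep(sz(in_per_layer), 3), rep(sz(200), 4)),
      stringsAsFactors = FALSE
    )
    layers <- c("L34", "L5", "L6")
    rules <- do.call(rbind, c(
      lapply(layers, function(L) cortical_layer_rules(L, r)),
      list(
        # interlaminar: AMPA at half the intralaminar total (0.3)
        rule_rows("PY_L34", "PY_L5", c("AMPA", "NMDA"),
                  c(0.3, g_il_nmda) * interlaminar_l34_l5,
                  r$interlaminar_radius, depressing = TRUE, mini = TRUE),
        rule_rows("PY_L5", "PY_L34", c("AMPA", "NMDA"),
                  c(0.3, g_il_nmda) * interlaminar_l5_l34,
                  r$interlaminar_radius, depressing = TRUE, mini = TRUE),
        thalamic_loop_rules("core", "L34", "L6",
                            tc_r = thal_r(r$core_tc_radius),
                            ct_r = ct_r(r$core_ct_radius)),
        thalamic_loop_rules("matrix", "L5", "L5",
                            tc_r = thal_r(r$core_tc_radius * fanout_ratio),
                            ct_r = ct_r(r$core_ct_radius * fanout_ratio)),
        intrathalamic_rules("core", thal_r(r$intrathalamic_radius)),
        intrathalamic_rules("matrix", thal_r(r$intrathalamic_radius))
      )
    ))
  } else {
    populations <- data.frame(
      name = c("PY_L1", "IN_L1", "TC_core", "RE_core"),
      class = c("PY", "IN", "TC", "RE"),
      size = c(sz(1000), sz(in_per_layer), sz(200), sz(200)),
      stringsAsFactors = FALSE
    )
    rules <- rbind(
      cortical_layer_rules("L1", r),
      rule_rows("TC_core", "PY_L1", "AMPA", 0.15 * tc_strength,
                thal_r(tc_radius)),
      rule_rows("TC_core", "IN_L1", "AMPA", 0.1 * tc_strength,
                thal_r(tc_radius)),
      rule_rows("PY_L1", "TC_core", "AMPA", 0.05 * ct_strength,
                ct_r(ct_radius)),
      rule_rows("PY_L1", "RE_core", "AMPA", 0.15 * ct_strength,
                ct_r(ct_radius)),
      intrathalamic_rules("core", thal_r(r$intrathalamic_radius))
    )
  }
  rownames(rules) <- NULL
  # reference radius anchors per-synapse weights when normalization is
  # off: the baseline (unswept) geometry of the same connection
  rules$ref_radius <- rules$radius
  if (variant == "onelayer") {
    tc_rules <- rules$source == "TC_core" & rules$target != "RE_core"
    ct_rules <- rules$source == "PY_L1" &
      rules$target %in% c("TC_core", "RE_core")
    rules$ref_radius[tc_rules] <- thal_r(10)
    rules$ref_radius[ct_rules] <- 2
  }
  structure(
    list(populations = populations, rules = rules,
         fanout_ratio = fanout_ratio, scale = scale,
         syn_unit_scale = syn_unit_scale, normalize = normalize,
         variant = variant),
    class = "network_spec"
  )
}

#' Isolated thalamic circuit specification
#'
#' A reduced network of `n` TC and `n` RE cells with the reciprocal
#' TC-RE loop (AMPA to RE; GABA-A + GABA-B back to TC) and RE-RE
#' inhibition, but no cortex: the classic minimal spindle oscillator.
#'
#' @param n cells per population.
#' @param radius intrathalamic fanout radius (source index units).
#' @param syn_unit_scale as in [network_spec()].
#' @return A `network_spec`.
#' @export
thalamic_pair_spec <- function(n = 1, radius = 1, syn_unit_scale = 2) {
  populations <- data.frame(
    name = c("TC_core", "RE_core"), class = c("TC", "RE"),
    size = c(n, n), stringsAsFactors = FALSE
  )
  structure(
    list(populations = populations,
         rules = intrathalamic_rules("core", radius),
         fanout_ratio = 1, scale = n / 200,
         syn_unit_scale = syn_unit_scale, normalize = TRUE,
         variant = "thalamic"),
    class = "network_spec"
  )
}

rule_rows <- function(source, target, receptor, g_total, radius,
                      depressing = FALSE, mini = FALSE) {
  data.frame(source = source, target = target, receptor = receptor,
             g_total = g_total, radius = radius,
             depressing = depressing, mini = mini,
             stringsAsFactors = FALSE)
}

cortical_layer_rules <- function(L, r) {
  py <- paste0("PY_", L); inn <- paste0("IN_", L)
  rbind(
    rule_rows(py, py, c("AMPA", "NMDA"), c(0.6, 0.06), r$py_py_radius,
              depressing = TRUE, mini = TRUE),
    rule_rows(py, inn, c("AMPA", "NMDA"), c(0.2, 0.08), r$py_in_radius,
              depressing = TRUE, mini = TRUE),
    rule_rows(inn, py, "GABA_A", 0.15, r$in_py_radius, mini = TRUE)
  )
}

thalamic_loop_rules <- function(system, cortex_in, cortex_out, tc_r,
                                ct_r) {
  tc <- paste0("TC_", system); re <- paste0("RE_", system)
  rbind(
    rule_rows(tc, paste0("PY_", cortex_in), "AMPA", 0.15, tc_r),
    rule_rows(tc, paste0("IN_", cortex_in), "AMPA", 0.1, tc_r),
    rule_rows(paste0("PY_", cortex_out), tc, "AMPA", 0.05, ct_r),
    rule_rows(paste0("PY_", cortex_out), re, "AMPA", 0.15, ct_r)
  )
}

intrathalamic_rules <- function(system, radius) {
  tc <- paste0("TC_", system); re <- paste0("RE_", system)
  rbind(
    rule_rows(tc, re, "AMPA", 0.06, radius),
    rule_rows(re, tc, "GABA_A", 0.06, radius),
    rule_rows(re, tc, "GABA_B", 0.0025, radius),
    rule_rows(re, re, "GABA_A", 0.1, radius)
  )
}

#' Fanout targets of one source cell
#'
#' Both populations are mapped onto a common normalized axis (cell `i`
#' of `N` sits at `(i - 0.5) / N`); the targets of source `i` are all
#' cells whose position lies within `radius / source_size` of the
#' source's position.  Boundaries truncate (no wraparound), so edge
#' cells have fewer targets than interior cells.  A source whose radius
#' falls below the target-grid spacing would otherwise project nowhere;
#' in that case the single nearest target is used.
#'
#' @param source_index 1-based index of the source cell.
#' @param source_size,target_size population sizes.
#' @param radius fanout radius in source index units (may be
#'   fractional).
#' @param exclude_self drop the identical index (within-population
#'   rules).
#' @return Integer vector of 1-based target indices.
#' @export
#' @examples
#' length(fanout_targets(100, 200, 1000, radius = 10))  # 101
fanout_targets <- function(source_index, source_size, target_size,
                           radius, exclude_self = FALSE) {
  stopifnot(source_index >= 1, source_index <= source_size, radius >= 0)
  x <- (source_index - 0.5) / source_size
  rho <- radius / source_size + 1e-9
  lo <- max(1, ceiling((x - rho) * target_size + 0.5 - 1e-9))
  hi <- min(target_size, floor((x + rho) * target_size + 0.5 + 1e-9))
  j <- if (hi >= lo) seq.int(lo, hi) else integer()
  if (!length(j)) {
    # nearest target cell; exact ties resolve to the lower index
    j <- max(1L, min(target_size, ceiling(x * target_size - 1e-9)))
  }
  if (exclude_self) j <- j[j != source_index]
  as.integer(j)
}

#' Per-synapse weight from a connection total
#'
#' The strength of an individual synapse is the total synaptic strength
#' of the connection divided by the number of inputs of that type the
#' postsynaptic neuron receives, so broader fanouts yield weaker
#' individual synapses (matrix weaker than core at baseline).
#'
#' @param g_total total connection conductance.
#' @param n_inputs number of convergent inputs (>= 1).
#' @return Per-synapse conductance.
#' @export
normalize_weight <- function(g_total, n_inputs) {
  if (any(n_inputs < 1)) {
    stop("n_inputs must be >= 1; a neuron with no inputs has no ",
         "defined per-synapse weight")
  }
  g_total / n_inputs
}

compartment_area <- function(class) {
  # area (cm2) of the compartment synapses land on
  c(TC = 2.9e-4, RE = 1.43e-4,
    PY = 1.0e-6 * 165, IN = 1.0e-6 * 50)[class]
}

#' Build the connectivity tables of a network
#'
#' Realizes a [network_spec()] as an explicit edge list: for every rule
#' and source cell, targets are enumerated by [fanout_targets()], and
#' per-synapse weights follow [normalize_weight()] with per-target
#' input counts (or, with `normalize = FALSE`, stay fixed at the
#' interior count of the same geometry so weight is independent of
#' fanout).  Construction is a pure function of the spec.  Any rule
#' that would couple the two thalamic systems directly is rejected:
#' spindle propagation between core and matrix is deliberately
#' restricted to the cortex.
#'
#' @param spec a [network_spec()].
#' @return A list of class `tc_network` with `populations` (including
#'   0-based global id offsets), `edges` (source/target population and
#'   index, receptor, per-synapse weight in uS and as conductance
#'   density on the target compartment, depression and mini flags) and
#'   the echoed `spec`.
#' @export
build_network <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  pops <- spec$populations
  pops$offset <- cumsum(c(0L, head(pops$size, -1L)))
  rules <- spec$rules
  thal <- c("TC", "RE")
  sysname <- function(nm) sub("^(TC|RE)_", "", nm)
  pclass <- setNames(pops$class, pops$name)
  for (k in seq_len(nrow(rules))) {
    s <- rules$source[k]; t <- rules$target[k]
    if (pclass[s] %in% thal && pclass[t] %in% thal &&
        sysname(s) != sysname(t)) {
      stop("cross-system thalamic connection requested (", s, " -> ",
           t, "); core and matrix thalamus must stay separate")
    }
  }
  psize <- setNames(pops$size, pops$name)
  edge_list <- vector("list", nrow(rules))
  for (k in seq_len(nrow(rules))) {
    src <- rules$source[k]; tgt <- rules$target[k]
    ns <- psize[[src]]; nt <- psize[[tgt]]
    self <- src == tgt
    tl <- lapply(seq_len(ns), fanout_targets, source_size = ns,
                 target_size = nt, radius = rules$radius[k],
                 exclude_self = self)
    len <- lengths(tl)
    si <- rep.int(seq_len(ns), len)
    ti <- unlist(tl, use.names = FALSE)
    if (!length(ti)) next  # e.g. self-only rule in a 1-cell population
    n_in <- tabulate(ti, nbins = nt)
    if (spec$normalize) {
      w <- normalize_weight(rules$g_total[k], n_in[ti])
    } else {
      # per-synapse weight pinned to the interior input count of the
      # reference (baseline) geometry, independent of the swept fanout
      rr <- if (is.null(rules$ref_radius)) rules$radius[k] else
        rules$ref_radius[k]
      ref <- lapply(seq_len(ns), fanout_targets, source_size = ns,
                    target_size = nt, radius = rr,
                    exclude_self = self)
      w <- rules$g_total[k] /
        max(tabulate(unlist(ref, use.names = FALSE), nbins = nt))
    }
    edge_list[[k]] <- data.frame(
      source = src, source_idx = si, target = tgt, target_idx = ti,
      receptor = rules$receptor[k], weight = w,
      n_inputs = n_in[ti],
      depressing = rules$depressing[k], mini = rules$mini[k],
      rule = k, stringsAsFactors = FALSE
    )
  }
  edges <- do.call(rbind, edge_list)
  rownames(edges) <- NULL
  # conductance density on the target compartment (mS/cm2)
  area <- compartment_area(pclass[edges$target])
  edges$weight_density <- edges$weight * 1e-3 / area * spec$syn_unit_scale
  structure(list(populations = pops, edges = edges, spec = spec),
            class = "tc_network")
}

#' @export
print.tc_network <- function(x, ...) {
  cat("thalamocortical network:",
      sum(x$populations$size), "cells,",
      nrow(x$edges), "synapses\n")
  cat("populations:\n")
  print(x$populations[, c("name", "class", "size")], row.names = FALSE)
  invisible(x)
}

#' Export connectivity as an edge-list table
#'
#' @param network a [build_network()] result.
#' @param path optional CSV path; when given the table is written there.
#' @return The edge-list data frame, invisibly when written to file.
#' @export
export_edges <- function(network, path = NULL) {
  stopifnot(inherits(network, "tc_network"))
  tab <- network$edges[, c("source", "source_idx", "target",
                           "target_idx", "receptor", "weight")]
  if (!is.null(path)) {
    write.csv(tab, path, row.names = FALSE)
    return(invisible(tab))
  }
  tab
}
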