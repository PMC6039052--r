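# Config round-tripping, report serialization, and the labeled
# synthetic burst generator used to validate detection and statistics
# without running the network.

#' Generate labeled spindle-like burst series
#'
#' Emulates spindle-band field potentials: background 1/f-like noise
#' with Hann-windowed sinusoidal bursts (frequency uniform in 11-15 Hz,
#' duration uniform in 0.5-3 s by default) whose inter-burst gaps are
#' drawn from an exponential or lognormal process.  Burst amplitude is
#' expressed in SD units of the background.  The ground-truth table
#' makes the series usable for sensitivity/precision calibration.
#'
#' @param n_channels number of independent channels.
#' @param duration series length (s).
#' @param rate sampling rate (Hz).
#' @param gap_dist `"exp"` or `"lognorm"` inter-burst gap process
#'   (offset-to-onset, s).
#' @param gap_mean mean gap (s) for `"exp"`; for `"lognorm"` the
#'   `meanlog`/`sdlog` pair is used instead.
#' @param meanlog,sdlog lognormal gap parameters.
#' @param amp_sd burst amplitude in background-SD units.
#' @param min_gap minimum inter-burst gap (s); gaps below it are
#'   redrawn as `min_gap` (spindles recur every 5-15 s, so abutting
#'   bursts would be unphysiological and would defeat event labeling).
#' @param freq_range,dur_range burst frequency (Hz) and duration (s)
#'   ranges.
#' @param seed integer seed.
#' @return List with `series` (time x channel matrix), `rate`, and
#'   `truth` (data.frame `channel`, `onset_s`, `offset_s`, `freq_hz`,
#'   `amp_sd`); bursts are non-overlapping within a channel.
#' @export
generate_burst_series <- function(n_channels = 1, duration = 300,
                                  rate = 200,
                                  gap_dist = c("exp", "lognorm"),
                                  gap_mean = 8, meanlog = 1.8,
                                  sdlog = 0.6, amp_sd = 5,
                                  min_gap = 2,
                                  freq_range = c(11, 15),
                                  dur_range = c(0.5, 3), seed = 1) {
  gap_dist <- match.arg(gap_dist)
  stopifnot(duration > 0, rate > 2 * freq_range[2])
  set.seed(seed)
  n <- round(duration * rate)
  tt <- (seq_len(n) - 1) / rate
  series <- matrix(0, n, n_channels)
  truth <- list()
  for (ch in seq_len(n_channels)) {
    bg <- one_over_f_noise(n, rate)
    s0 <- sd(bg)
    t <- 2  # settle margin before the first burst
    rows <- list()
    repeat {
      gap <- if (gap_dist == "exp") rexp(1, 1 / gap_mean) else
        rlnorm(1, meanlog, sdlog)
      gap <- max(gap, min_gap)
      on <- t + gap
      dur <- runif(1, dur_range[1], dur_range[2])
      off <- on + dur
      if (off > duration - 1) break
      f <- runif(1, freq_range[1], freq_range[2])
      i0 <- round(on * rate) + 1
      i1 <- round(off * rate)
      m <- i1 - i0 + 1
      # tapered-cosine (Tukey) envelope: waxing-waning edges with a
      # flat core, so the nominal amplitude holds over most of the
      # burst rather than only at its midpoint
      u <- seq(0, 1, length.out = m)
      taper <- 0.3
      env <- rep(1, m)
      lo <- u < taper / 2
      hi <- u > 1 - taper / 2
      env[lo] <- 0.5 * (1 + cos(pi * (2 * u[lo] / taper - 1)))
      env[hi] <- 0.5 * (1 + cos(pi * (2 * (1 - u[hi]) / taper - 1)))
      ph <- runif(1, 0, 2 * pi)
      bg[i0:i1] <- bg[i0:i1] +
        amp_sd * s0 * env * sin(2 * pi * f * tt[i0:i1] + ph)
      rows[[length(rows) + 1]] <-
        data.frame(channel = ch, onset_s = on, offset_s = off,
                   freq_hz = f, amp_sd = amp_sd)
      t <- off
    }
    series[, ch] <- bg
    truth[[ch]] <- if (length(rows)) do.call(rbind, rows) else NULL
  }
  truth <- do.call(rbind, truth)
  if (is.null(truth)) {
    truth <- data.frame(channel = integer(), onset_s = numeric(),
                        offset_s = numeric(), freq_hz = numeric(),
                        amp_sd = numeric())
  }
  list(series = series, rate = rate, truth = truth)
}

one_over_f_noise <- function(n, rate, exponent = 1) {
  # shape white Gaussian noise to a 1/f^exponent amplitude spectrum
  w <- rnorm(n)
  sp <- fft(w)
  f <- c(1, seq_len(n - 1))  # avoid dividing DC by zero
  f <- pmin(f, n - f + 1)    # two-sided frequency index
  sp <- sp / (f^(exponent / 2))
  x <- Re(fft(sp, inverse = TRUE)) / n
  as.numeric(scale(x))
}

#' Score detections against ground truth
#'
#' A truth burst is hit when a detected event on the same channel
#' overlaps it; a detected event is a true positive when it overlaps a
#' truth burst.  Sensitivity = hit bursts / bursts; precision = true
#' positive events / events.
#'
#' @param events [detect_spindles()] table.
#' @param truth ground-truth table from [generate_burst_series()].
#' @return List with `sensitivity`, `precision`, `n_truth`, `n_events`.
#' @export
score_detection <- function(events, truth) {
  hit <- vapply(seq_len(nrow(truth)), function(i) {
    sel <- events$channel == truth$channel[i]
    any(events$onset_s[sel] < truth$offset_s[i] &
          events$offset_s[sel] > truth$onset_s[i])
  }, logical(1))
  tp <- vapply(seq_len(nrow(events)), function(i) {
    sel <- truth$channel == events$channel[i]
    any(truth$onset_s[sel] < events$offset_s[i] &
          truth$offset_s[sel] > events$onset_s[i])
  }, logical(1))
  list(sensitivity = if (nrow(truth)) mean(hit) else NA_real_,
       precision = if (nrow(events)) mean(tp) else NA_real_,
       n_truth = nrow(truth), n_events = nrow(events))
}

#' Default configuration
#'
#' The full declarative configuration of a baseline run: network
#' geometry, simulation, and detector blocks.  [read_config()] checks
#' unknown keys against this template.
#'
#' @return Nested named list.
#' @export
default_config <- function() {
  list(
    network = list(scale = 1, fanout_ratio = 10, in_per_layer = 200,
                   interlaminar_nmda = "half",
                   interlaminar_l34_l5 = 1, interlaminar_l5_l34 = 1,
                   syn_unit_scale = 2, normalize = TRUE,
                   variant = "full"),
    simulation = list(duration = 60, dt = 0.025, transient_discard = 5,
                      seed = 1, lfp_rate = 1000, n_groups = 10,
                      mini_scale = 0.15, v_jitter = 2),
    detector = list(mode = "model")
  )
}

#' Read a configuration file
#'
#' YAML configuration with the blocks of [default_config()]; missing
#' keys take defaults, unknown keys are rejected with their location.
#'
#' @param path YAML file path.
#' @return Nested named list of class `spindlenet_config`.
#' @export
read_config <- function(path) {
  cfg <- tryCatch(yaml::read_yaml(path), error = function(e) {
    stop("malformed config '", path, "': ", conditionMessage(e))
  })
  if (is.null(cfg)) cfg <- list()
  defaults <- default_config()
  check_keys <- function(x, ref, where) {
    bad <- setdiff(names(x), names(ref))
    if (length(bad)) {
      stop("unknown config key(s) at ", where, ": ",
           paste(bad, collapse = ", "))
    }
    for (nm in names(x)) {
      if (is.list(ref[[nm]]) && !is.null(names(ref[[nm]]))) {
        check_keys(x[[nm]], ref[[nm]], paste0(where, nm, "/"))
      }
    }
  }
  check_keys(cfg, defaults, "/")
  out <- modifyList(defaults, cfg)
  class(out) <- "spindlenet_config"
  out
}

#' Write a configuration file
#'
#' @param config nested list (e.g. from [default_config()]).
#' @param path YAML output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Build the network described by a configuration
#'
#' @param config a [read_config()] / [default_config()] list.
#' @return A [build_network()] result.
#' @export
network_from_config <- function(config) {
  nw <- config$network
  build_network(network_spec(
    scale = nw$scale, fanout_ratio = nw$fanout_ratio,
    in_per_layer = nw$in_per_layer,
    interlaminar_nmda = nw$interlaminar_nmda,
    interlaminar_l34_l5 = nw$interlaminar_l34_l5,
    interlaminar_l5_l34 = nw$interlaminar_l5_l34,
    syn_unit_scale = nw$syn_unit_scale, normalize = nw$normalize,
    variant = nw$variant
  ))
}

#' Write an analysis report
#'
#' Serializes a (nested) list of results to JSON together with
#' provenance: package version, timestamp, and an MD5 hash of the
#' generating configuration.
#'
#' @param report named list of results.
#' @param path output JSON path.
#' @param config optional configuration list hashed into the report.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, config = NULL) {
  meta <- list(
    package = "spindlenet",
    version = as.character(utils::packageVersion("spindlenet")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  if (!is.null(config)) {
    tf <- tempfile(fileext = ".yaml")
    on.exit(unlink(tf))
    write_config(config, tf)
    meta$config_md5 <- unname(tools::md5sum(tf))
    meta$config <- config
  }
  jsonlite::write_json(c(list(meta = meta), report), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
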