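# Spindle ensemble statistics: density, ISI distribution fits, spatial
# correlation, co-occurrence, onset delays, spike-phase histograms.

#' Spindle density
#'
#' Number of spindles per minute of analyzed time, per channel.
#'
#' @param events a [detect_spindles()] table.
#' @param duration_s analyzed duration in seconds.
#' @param channels optional full channel set (channels with zero events
#'   are reported as 0 rather than dropped).
#' @return data.frame with `channel` and `density_per_min`.
#' @export
spindle_density <- function(events, duration_s, channels = NULL) {
  stopifnot(duration_s > 0)
  if (is.null(channels)) channels <- unique(events$channel)
  n <- vapply(channels, function(ch) sum(events$channel == ch),
              numeric(1))
  data.frame(channel = channels,
             density_per_min = unname(n) / duration_s * 60)
}

#' Merge per-channel events into distinct network events
#'
#' Events whose spans overlap across any channels of the same system
#' are one underlying network event; a global spindle visible on all
#' channels contributes one row here but one event per channel in the
#' per-channel tables.  Distinct-event counts are therefore the
#' multiplicity-free measure of how often the system spindles, which
#' matters when comparing conditions that change spindle spatial
#' extent.
#'
#' @param events a [detect_spindles()] table.
#' @return data.frame with `onset_s`, `offset_s`, `n_channels` (number
#'   of channels participating in each merged event), ordered by onset.
#' @export
network_events <- function(events) {
  if (!nrow(events)) {
    return(data.frame(onset_s = numeric(), offset_s = numeric(),
                      n_channels = integer()))
  }
  o <- order(events$onset_s)
  on <- events$onset_s[o]; off <- events$offset_s[o]
  ch <- events$channel[o]
  grp <- integer(length(on))
  grp[1] <- 1
  reach <- off[1]
  for (i in seq_along(on)[-1]) {
    if (on[i] <= reach) grp[i] <- grp[i - 1]
    else grp[i] <- grp[i - 1] + 1L
    reach <- max(reach, off[i])
    if (grp[i] != grp[i - 1]) reach <- off[i]
  }
  data.frame(
    onset_s = as.numeric(tapply(on, grp, min)),
    offset_s = as.numeric(tapply(off, grp, max)),
    n_channels = as.integer(tapply(ch, grp, function(x) {
      length(unique(x))
    }))
  )
}

#' Fit inter-spindle interval distributions
#'
#' Maximum-likelihood lognormal and exponential fits, a
#' Lilliefors-type normality test, and summary moments.  Long-tailed,
#' non-normal ISI distributions are the signature of a stochastic
#' (Poisson-like) rather than periodic spindle generator.
#'
#' @param intervals numeric vector of ISIs (s); at least 20 for fits.
#' @return List with `n`, `lognormal` (meanlog, sdlog and SEs),
#'   `exponential` (rate and SE), `lilliefors` (statistic and p for
#'   normality of the raw intervals), `mean`, `median`.  When `n < 20`
#'   the fits are `NULL` and `fitted` is `FALSE`.
#' @export
fit_isi_distributions <- function(intervals) {
  intervals <- intervals[is.finite(intervals) & intervals > 0]
  n <- length(intervals)
  out <- list(n = n, fitted = FALSE, lognormal = NULL,
              exponential = NULL, lilliefors = NULL,
              mean = mean(intervals), median = median(intervals))
  if (n < 20) return(out)
  ln <- MASS::fitdistr(intervals, "lognormal")
  ex <- MASS::fitdistr(intervals, "exponential")
  lt <- nortest::lillie.test(intervals)
  out$fitted <- TRUE
  out$lognormal <- list(meanlog = unname(ln$estimate["meanlog"]),
                        sdlog = unname(ln$estimate["sdlog"]),
                        se = unname(ln$sd), loglik = ln$loglik)
  out$exponential <- list(rate = unname(ex$estimate["rate"]),
                          se = unname(ex$sd), loglik = ex$loglik)
  out$lilliefors <- list(statistic = unname(lt$statistic),
                         p_value = lt$p.value)
  out
}

#' Two-sample Kolmogorov-Smirnov comparison of interval sets
#'
#' @param a,b numeric interval vectors.
#' @return List with `statistic` and `p_value`.
#' @export
compare_isi <- function(a, b) {
  k <- suppressWarnings(ks.test(a, b))
  list(statistic = unname(k$statistic), p_value = k$p.value)
}

event_mask <- function(events, n, rate, channels = NULL) {
  m <- logical(n)
  if (!is.null(channels)) events <- events[events$channel %in% channels, ]
  if (nrow(events)) {
    for (i in seq_len(nrow(events))) {
      a <- max(1L, floor(events$onset_s[i] * rate) + 1L)
      b <- min(n, ceiling(events$offset_s[i] * rate))
      if (b >= a) m[a:b] <- TRUE
    }
  }
  m
}

#' Spatial correlation of LFP channels versus distance
#'
#' Pearson correlation of band-passed LFP between channel pairs,
#' restricted to spindle epochs (the union of both channels' detected
#' event spans), averaged within inter-group distance bins.  Channel
#' distance is the difference of group indices (one unit = one LFP
#' group along the network axis).
#'
#' @param lfp time x channel matrix of band-passed LFP.
#' @param rate sampling rate (Hz).
#' @param events a [detect_spindles()] table whose `channel` values are
#'   the column indices of `lfp` (or `channel_names`).
#' @param channel_names channel labels matching `events$channel`
#'   (default column indices).
#' @return List with `by_distance` (data.frame `distance`,
#'   `mean_correlation`, `n_pairs`) and `mean` (grand mean over all
#'   pairs).  `NA` with a warning when no spindle epochs exist.
#' @export
spatial_correlation <- function(lfp, rate, events,
                                channel_names = NULL) {
  lfp <- as.matrix(lfp)
  nc <- ncol(lfp)
  stopifnot(nc >= 2)
  if (is.null(channel_names)) channel_names <- seq_len(nc)
  n <- nrow(lfp)
  masks <- lapply(channel_names, function(ch) {
    event_mask(events, n, rate, channels = ch)
  })
  pr <- expand.grid(i = seq_len(nc), j = seq_len(nc))
  pr <- pr[pr$i < pr$j, ]
  cors <- dist <- rep(NA_real_, nrow(pr))
  for (k in seq_len(nrow(pr))) {
    i <- pr$i[k]; j <- pr$j[k]
    m <- masks[[i]] | masks[[j]]
    if (sum(m) > rate) {  # at least 1 s of spindle epoch
      cors[k] <- cor(lfp[m, i], lfp[m, j])
      dist[k] <- abs(j - i)
    }
  }
  ok <- is.finite(cors)
  if (!any(ok)) {
    warning("no spindle epochs; spatial correlation undefined")
    return(list(by_distance = data.frame(distance = numeric(),
                                         mean_correlation = numeric(),
                                         n_pairs = integer()),
                mean = NA_real_))
  }
  bd <- aggregate(cors[ok], by = list(distance = dist[ok]),
                  FUN = mean)
  names(bd)[2] <- "mean_correlation"
  bd$n_pairs <- as.integer(table(dist[ok])[as.character(bd$distance)])
  list(by_distance = bd, mean = mean(cors[ok]))
}

#' Probability of spindle co-occurrence
#'
#' `P(B spindling | A spindling)`: the fraction of A events whose time
#' span intersects at least one B event (on any B channel), and the
#' reverse.  Also reports, for each A event, how many distinct A
#' channels carry a temporally overlapping event, split by whether a B
#' event co-occurs (channel-recruitment statistic).
#'
#' @param events_a,events_b [detect_spindles()] tables on a common
#'   clock.
#' @return List with `p_b_given_a`, `p_a_given_b`, `n_a`, `n_b`, and
#'   `recruitment` (mean simultaneous A channels during A events with /
#'   without a co-occurring B event).
#' @export
cooccurrence_probability <- function(events_a, events_b) {
  overlaps <- function(on, off, tab) {
    if (!nrow(tab)) return(rep(FALSE, length(on)))
    vapply(seq_along(on), function(i) {
      any(tab$onset_s < off[i] & tab$offset_s > on[i])
    }, logical(1))
  }
  a_hit <- overlaps(events_a$onset_s, events_a$offset_s, events_b)
  b_hit <- overlaps(events_b$onset_s, events_b$offset_s, events_a)
  n_ch <- vapply(seq_len(nrow(events_a)), function(i) {
    sel <- events_a$onset_s < events_a$offset_s[i] &
      events_a$offset_s > events_a$onset_s[i]
    length(unique(events_a$channel[sel]))
  }, numeric(1))
  list(
    p_b_given_a = if (nrow(events_a)) mean(a_hit) else NA_real_,
    p_a_given_b = if (nrow(events_b)) mean(b_hit) else NA_real_,
    n_a = nrow(events_a), n_b = nrow(events_b),
    recruitment = list(
      with_b = if (any(a_hit)) mean(n_ch[a_hit]) else NA_real_,
      without_b = if (any(!a_hit)) mean(n_ch[!a_hit]) else NA_real_
    )
  )
}

#' Onset delays between co-occurring core and matrix spindles
#'
#' Each core event is paired with the nearest-onset unused matrix
#' event within `window` ms; the delay is
#' `onset_core - onset_matrix`, so negative values mean the core
#' preceded the matrix.
#'
#' @param events_core,events_matrix [detect_spindles()] tables on a
#'   common clock.
#' @param window pairing window in ms (default 2500).
#' @return List with `delays_ms` (one per matched pair) and `mean_ms`.
#' @export
onset_delays <- function(events_core, events_matrix, window = 2500) {
  stopifnot(window > 0)
  co <- sort(events_core$onset_s) * 1000
  mo <- sort(events_matrix$onset_s) * 1000
  used <- rep(FALSE, length(mo))
  delays <- numeric()
  for (t in co) {
    d <- abs(mo - t)
    d[used] <- Inf
    j <- which.min(d)
    if (length(j) && is.finite(d[j]) && d[j] <= window) {
      delays <- c(delays, t - mo[j])
      used[j] <- TRUE
    }
  }
  list(delays_ms = delays,
       mean_ms = if (length(delays)) mean(delays) else NA_real_)
}

#' Spike phase during spindles
#'
#' Instantaneous phase is the angle of the analytic signal of the
#' band-passed LFP, so a band-limited peak maps to phase 0 and a trough
#' to +/-pi (convention recorded in the output).  Spikes outside
#' detected spindle epochs are discarded; neurons with fewer than
#' `min_spikes` in-spindle spikes are excluded and reported.
#'
#' @param spikes data.frame with `index` (neuron) and `time` (ms).
#' @param lfp single-channel LFP vector (unfiltered; filtered
#'   internally with `band`).
#' @param rate LFP sampling rate (Hz).
#' @param events [detect_spindles()] events for this channel.
#' @param band band edges (Hz) for the phase-defining filter.
#' @param n_bins histogram bins over `(-pi, pi]` (default 100).
#' @param min_spikes per-neuron inclusion threshold.
#' @return List with `histogram` (data.frame `phase`, `probability`;
#'   mean of per-neuron normalized histograms), `pooled` (normalized
#'   histogram of all retained spikes), `phases` (per-spike phases),
#'   `n_neurons`, `excluded_neurons`, and `convention`.
#' @export
spike_phase_distribution <- function(spikes, lfp, rate, events,
                                     band = c(6, 15), n_bins = 100,
                                     min_spikes = 10) {
  fb <- bandpass(lfp, rate, band[1], band[2])
  phase <- Arg(analytic_signal(fb))
  n <- length(lfp)
  mask <- event_mask(events, n, rate)
  idx <- pmin(pmax(round(spikes$time / 1000 * rate), 1), n)
  keep <- mask[idx]
  spk <- data.frame(index = spikes$index[keep], phase = phase[idx[keep]])
  counts <- table(spk$index)
  good <- names(counts)[counts >= min_spikes]
  excluded <- setdiff(unique(as.character(spikes$index)), good)
  spk <- spk[as.character(spk$index) %in% good, ]
  breaks <- seq(-pi, pi, length.out = n_bins + 1)
  histo <- function(ph) {
    h <- hist(ph, breaks = breaks, plot = FALSE)$counts
    if (sum(h) > 0) h / sum(h) else h
  }
  per_neuron <- if (nrow(spk)) {
    t(vapply(split(spk$phase, spk$index), histo, numeric(n_bins)))
  } else {
    matrix(numeric(), ncol = n_bins)
  }
  centers <- (breaks[-1] + breaks[-(n_bins + 1)]) / 2
  list(
    histogram = data.frame(
      phase = centers,
      probability = if (nrow(per_neuron)) colMeans(per_neuron)
                    else rep(NA_real_, n_bins)
    ),
    pooled = data.frame(phase = centers, probability = histo(spk$phase)),
    phases = setNames(spk$phase, as.character(spk$index)),
    n_neurons = length(good),
    excluded_neurons = excluded,
    convention = "peak of band-passed LFP = phase 0 (trough = +/-pi)"
  )
}

#' Compare spike-phase distributions between two systems
#'
#' Two-sample Kolmogorov-Smirnov test on spike phases, either pooling
#' all spikes or comparing per-neuron circular mean phases.
#'
#' @param phase_a,phase_b results of [spike_phase_distribution()].
#' @param mode `"pooled"` (all spikes) or `"neurons"`.
#' @return List with `statistic` and `p_value`.
#' @export
compare_spike_phases <- function(phase_a, phase_b,
                                 mode = c("pooled", "neurons")) {
  mode <- match.arg(mode)
  if (mode == "pooled") {
    compare_isi(as.numeric(phase_a$phases), as.numeric(phase_b$phases))
  } else {
    compare_isi(per_neuron_means(phase_a), per_neuron_means(phase_b))
  }
}

per_neuron_means <- function(p) {
  # circular mean phase per neuron (spike phases carry neuron ids)
  vapply(split(as.numeric(p$phases), names(p$phases)),
         function(x) Arg(mean(exp(1i * x))), numeric(1))
}
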