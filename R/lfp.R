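# Estimated LFP: group means of dendritic synaptic currents, plus
# zero-phase spindle-band filtering.

#' Estimate LFP from per-cell dendritic synaptic currents
#'
#' The estimated LFP of a cortical layer is the arithmetic mean of the
#' dendritic synaptic currents over every group of `group_size`
#' contiguous neurons (10 groups of 100 cells per 1000-cell layer at
#' full scale).  Currents are outward-positive, so net inward synaptic
#' current deflects the estimate negative.  A trailing partial group is
#' dropped with a warning.
#'
#' @param currents numeric matrix, time x cells (cells in spatial
#'   order).
#' @param group_size cells per group (default 100).
#' @param rate sampling rate in Hz (carried through as metadata).
#' @return List of class `lfp_series`: `series` (time x group matrix),
#'   `rate`, and `groups` (membership bounds).
#' @export
estimate_lfp <- function(currents, group_size = 100, rate = 1000) {
  currents <- as.matrix(currents)
  n <- ncol(currents)
  stopifnot(group_size >= 1, n >= group_size)
  n_groups <- n %/% group_size
  if (n_groups * group_size < n) {
    warning("dropping trailing partial group of ",
            n - n_groups * group_size, " cells")
  }
  series <- vapply(seq_len(n_groups), function(g) {
    cols <- ((g - 1) * group_size + 1):(g * group_size)
    rowMeans(currents[, cols, drop = FALSE])
  }, numeric(nrow(currents)))
  structure(
    list(series = series, rate = rate,
         groups = data.frame(group = seq_len(n_groups),
                             from = (seq_len(n_groups) - 1) * group_size + 1,
                             to = seq_len(n_groups) * group_size)),
    class = "lfp_series"
  )
}

#' Zero-phase band-pass filter
#'
#' Forward-backward (zero-phase) 4th-order Butterworth band-pass,
#' applied column-wise to matrices.  Zero phase matters downstream: a
#' causal filter would bias spindle onset-delay statistics.
#'
#' @param x numeric vector or time x channel matrix.
#' @param rate sampling rate (Hz); must exceed `2 * high`.
#' @param low,high band edges in Hz (default 6-15, the spindle band
#'   used on model LFP).
#' @return Filtered data with the shape of `x`.
#' @export
bandpass <- function(x, rate, low = 6, high = 15) {
  stopifnot(low > 0, high > low)
  if (rate <= 2 * high) {
    stop("sampling rate ", rate, " Hz too low for a ", high,
         " Hz band edge")
  }
  bf <- signal::butter(2, c(low, high) / (rate / 2), type = "pass")
  filt1 <- function(v) {
    y <- signal::filtfilt(bf, v - mean(v))
    if (!all(is.finite(y))) stop("band-pass filter diverged")
    y
  }
  if (is.matrix(x)) apply(x, 2, filt1) else filt1(as.numeric(x))
}

# analytic signal via the frequency-domain Hilbert construction:
# doubles positive frequencies, zeroes negative ones
analytic_signal <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  fft(fft(x) * h, inverse = TRUE) / n
}
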