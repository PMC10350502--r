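#' Detect intensity spikes in a trajectory
#'
#' A spike is a local maximum of the sampled intensity exceeding
#' `threshold`, with consecutive peaks at least `min_separation` apart (the
#' earlier peak is kept on a violation). The quiet-state intensity is of
#' order `beta` (1e-4 to 1e-2) while excitable pulses reach intensities of
#' order 1--100, so the default unit threshold separates the two regimes by
#' orders of magnitude; `min_separation = 50` is well below the refractory
#' gap between genuine pulses.
#'
#' @param traj a `laser_trajectory` from [integrate_laser()].
#' @param threshold intensity a peak must exceed to count as a spike.
#' @param min_separation minimum time between retained peaks.
#' @param reference_time stimulus-onset time used later for latency.
#' @return An object of class `spike_train` with `peak_times`,
#'   `peak_intensities`, `threshold_used` and `reference_time`. An empty
#'   train is a valid result.
#' @export
detect_spikes <- function(traj, threshold = 1, min_separation = 50,
                          reference_time = 0) {
  stopifnot(inherits(traj, "laser_trajectory"))
  I <- traj$I
  t <- traj$times
  n <- length(I)
  peaks_t <- numeric(0)
  peaks_I <- numeric(0)
  if (n >= 3) {
    mid <- 2:(n - 1)
    is_peak <- I[mid] > I[mid - 1] & I[mid] >= I[mid + 1] & I[mid] > threshold
    cand <- mid[is_peak]
    for (j in cand) {
      if (!length(peaks_t) || t[j] - peaks_t[length(peaks_t)] >= min_separation) {
        peaks_t <- c(peaks_t, t[j])
        peaks_I <- c(peaks_I, I[j])
      }
    }
  }
  structure(list(peak_times = peaks_t, peak_intensities = peaks_I,
                 threshold_used = threshold, min_separation = min_separation,
                 reference_time = reference_time),
            class = "spike_train")
}

#' Latency of the first spike
#'
#' The spike latency `tau_l` is the interval between the presentation of the
#' stimulus (the spike train's `reference_time`, by convention the onset of
#' bit 0 of the pump program) and the first emitted pulse. It diverges to
#' infinity as the stimulus approaches the excitable threshold from above,
#' and is `Inf` when no spike occurred.
#'
#' @param spikes a `spike_train` from [detect_spikes()].
#' @return A single number, possibly `Inf`.
#' @export
first_spike_latency <- function(spikes) {
  stopifnot(inherits(spikes, "spike_train"))
  if (!length(spikes$peak_times)) return(Inf)
  spikes$peak_times[1] - spikes$reference_time
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %d spike(s), threshold %g\n",
              length(x$peak_times), x$threshold_used))
  if (length(x$peak_times)) {
    cat("  peak times:", paste(signif(x$peak_times, 6), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
as.data.frame.spike_train <- function(x, ...) {
  data.frame(peak_time = x$peak_times, peak_I = x$peak_intensities)
}
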