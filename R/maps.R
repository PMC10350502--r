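#' Minimum number of consecutive "1" bits needed to elicit a spike
#'
#' Temporal summation lets several sub-threshold pump pulses add up: with
#' the bit time chosen slightly below the relative refractory time, a neuron
#' at tuning `(mu0, c)` fires only once a sufficiently long contiguous run
#' of "1" bits has arrived. This function finds the smallest such run
#' length. Runs are embedded left-aligned in a `frame`-bit sequence
#' ("11100", "11110", ...) to match the 5-pixel receptive fields.
#'
#' A value of `0` means the unperturbed neuron spikes by itself
#' (self-pulsing regime); `NA` means even a full frame of ones stays silent.
#'
#' @param mu0 base pump value.
#' @param c pump amplitude for "1" bits.
#' @param tau_b,tau_p bit and pulse durations.
#' @param params a [laser_params()] object.
#' @param max_run largest run length tried (defaults to the frame width).
#' @param frame length of the bit frame the run is embedded in.
#' @param t_pad post-stimulus padding.
#' @param zero_horizon horizon used for the zero-input (self-pulsing) check.
#' @return Integer in `0..max_run`, or `NA_integer_`.
#' @examples
#' \donttest{
#' min_run_to_spike(mu0 = 1.25, c = 6)  # 3
#' }
#' @export
min_run_to_spike <- function(mu0, c, tau_b = 50, tau_p = 30,
                             params = laser_params(), max_run = 5,
                             frame = 5, t_pad = 3000, zero_horizon = 5000) {
  stopifnot(max_run <= frame)
  if (spikes_unperturbed(mu0, params, horizon = zero_horizon)) return(0L)
  for (k in seq_len(max_run)) {
    bits <- c(rep(1L, k), rep(0L, frame - k))
    if (is.finite(pattern_latency(bits, mu0, c, tau_b, tau_p, t_pad, params))) {
      return(k)
    }
  }
  NA_integer_
}

# does the neuron spike at constant pump mu0 with no input bits?
spikes_unperturbed <- function(mu0, params = laser_params(), horizon = 5000,
                               init = NULL) {
  prog <- pump_program(rep(0L, 1), mu0 = mu0, c = 0, tau_b = 1, tau_p = 1,
                       t_pad = horizon - 1)
  init <- init %||% tryCatch(steady_state(params, mu0), error = function(e) NULL)
  if (is.null(init)) return(TRUE)  # no quiet state: pulsing is inevitable
  traj <- integrate_laser(params, prog, init = init)
  length(detect_spikes(traj)$peak_times) > 0
}

#' Can a neuron tell two bit patterns apart?
#'
#' `TRUE` when the neuron at tuning `(mu0, c)` emits at least one spike for
#' `fire_pattern` and stays silent for `reject_pattern`. This is the
#' building block for sequence-selective features such as separating
#' "10111" from its mirror "11101": summation is a time-dependent process,
#' so a leading pulse can prime the gain enough that the trailing run
#' crosses threshold, while the mirrored sequence does not.
#'
#' @param fire_pattern,reject_pattern bit patterns of equal length.
#' @inheritParams min_run_to_spike
#' @return Logical.
#' @export
pattern_discriminates <- function(mu0, c, fire_pattern, reject_pattern,
                                  tau_b = 50, tau_p = 30,
                                  params = laser_params(), t_pad = 3000) {
  fp <- parse_bits(fire_pattern)
  rp <- parse_bits(reject_pattern)
  if (length(fp) != length(rp)) {
    stop("patterns must have the same length", call. = FALSE)
  }
  is.finite(pattern_latency(fp, mu0, c, tau_b, tau_p, t_pad, params)) &&
    !is.finite(pattern_latency(rp, mu0, c, tau_b, tau_p, t_pad, params))
}

#' Spike-latency difference between 3-run and 4-run inputs
#'
#' Simulates the neuron for left-aligned runs of three ("11100") and four
#' ("11110") ones, both referenced to the same stimulus onset, and returns
#' the latencies `tau3`, `tau4` and their difference
#' `delta = tau3 - tau4`. Near the excitable threshold the latency diverges,
#' so the difference can span orders of magnitude; a difference larger than
#' the bit time is what makes spike-time stamp coding possible. Infinities
#' propagate when one input fails to spike.
#'
#' @inheritParams min_run_to_spike
#' @param frame frame width the runs are embedded in.
#' @return An object of class `latency_result` with `tau3`, `tau4`, `delta`.
#' @export
latency_difference <- function(mu0, c, tau_b = 50, tau_p = 30,
                               params = laser_params(), frame = 5,
                               t_pad = 3000) {
  tau3 <- pattern_latency(c(rep(1L, 3), rep(0L, frame - 3)), mu0, c,
                          tau_b, tau_p, t_pad, params)
  tau4 <- pattern_latency(c(rep(1L, 4), rep(0L, frame - 4)), mu0, c,
                          tau_b, tau_p, t_pad, params)
  structure(list(tau3 = tau3, tau4 = tau4, delta = tau3 - tau4),
            class = "latency_result")
}

#' @export
print.latency_result <- function(x, ...) {
  cat(sprintf("<latency_result> tau3 = %g, tau4 = %g, delta = %g\n",
              x$tau3, x$tau4, x$delta))
  invisible(x)
}

#' Onset of the self-pulsing regime
#'
#' Locates, by bisection, the smallest base pump at which the neuron spikes
#' with zero input bits. Each candidate pump is integrated over `horizon`
#' time units starting from the quiet steady state of the bracket's low end,
#' and the predicate is "at least one spike within the horizon". Near the
#' onset the inter-spike period diverges, so the located boundary depends
#' weakly on the horizon; the default (5000 units) is large against the bit
#' time scale and the result is stable to doubling it at the default
#' resolution.
#'
#' @param lo,hi bracket: `lo` must be quiet and `hi` self-pulsing.
#' @param resolution bisection stops when the bracket is this narrow.
#' @param horizon integration horizon per candidate.
#' @param params a [laser_params()] object.
#' @return The onset pump value `mu0*`.
#' @export
self_pulsing_onset <- function(lo = 2.0, hi = 3.2, resolution = 0.01,
                               horizon = 5000, params = laser_params()) {
  stopifnot(lo < hi, resolution > 0)
  init <- tryCatch(steady_state(params, lo), error = function(e) NULL)
  if (is.null(init)) {
    stop("invalid bracket: low end already spikes", call. = FALSE)
  }
  pred <- function(mu0) spikes_unperturbed(mu0, params, horizon, init = init)
  if (pred(lo)) stop("invalid bracket: low end already spikes", call. = FALSE)
  if (!pred(hi)) stop("invalid bracket: high end does not spike", call. = FALSE)
  while (hi - lo > resolution) {
    mid <- (lo + hi) / 2
    if (pred(mid)) hi <- mid else lo <- mid
  }
  hi
}

#' Parameter sweep over (mu0, c)
#'
#' Evaluates one of the excitability measures on a rectangular grid:
#' `"minrun"` ([min_run_to_spike()]), `"discriminate"`
#' ([pattern_discriminates()], requires `fire_pattern`/`reject_pattern`) or
#' `"latency"` ([latency_difference()], value is `log10(delta)` for finite
#' positive differences and `NA` otherwise, with `tau3`, `tau4`, `delta`
#' kept alongside).
#'
#' @param kind which measure to map.
#' @param mu0_grid,c_grid axis values.
#' @param tau_b,tau_p fixed timing parameters, recorded in the result.
#' @param params a [laser_params()] object.
#' @param fire_pattern,reject_pattern patterns for `kind = "discriminate"`.
#' @param ... passed to the per-cell operation.
#' @return A long-format data frame (`mu0`, `c`, `value`, ...) of class
#'   `parameter_map`, cells ordered mu0-major, with the fixed parameters in
#'   attributes.
#' @export
excitability_sweep <- function(kind = c("minrun", "discriminate", "latency"),
                               mu0_grid, c_grid, tau_b = 50, tau_p = 30,
                               params = laser_params(),
                               fire_pattern = "10111",
                               reject_pattern = "11101", ...) {
  kind <- match.arg(kind)
  grid <- expand.grid(c = c_grid, mu0 = mu0_grid)[, c("mu0", "c")]
  cell <- switch(kind,
    minrun = function(m, cc) {
      v <- min_run_to_spike(m, cc, tau_b, tau_p, params, ...)
      data.frame(value = as.numeric(v))
    },
    discriminate = function(m, cc) {
      data.frame(value = as.numeric(pattern_discriminates(
        m, cc, fire_pattern, reject_pattern, tau_b, tau_p, params, ...)))
    },
    latency = function(m, cc) {
      lr <- latency_difference(m, cc, tau_b, tau_p, params, ...)
      data.frame(value = if (is.finite(lr$delta) && lr$delta > 0)
                   log10(lr$delta) else NA_real_,
                 tau3 = lr$tau3, tau4 = lr$tau4, delta = lr$delta)
    })
  rows <- mapply(cell, grid$mu0, grid$c, SIMPLIFY = FALSE)
  out <- cbind(grid, do.call(rbind, rows))
  attr(out, "kind") <- kind
  attr(out, "fixed") <- list(tau_b = tau_b, tau_p = tau_p)
  class(out) <- c("parameter_map", "data.frame")
  out
}

#' Write a parameter map as CSV plus a JSON sidecar
#'
#' @param map a `parameter_map` from [excitability_sweep()].
#' @param file CSV path; the sidecar is written next to it as
#'   `<file>.json`.
#' @export
write_parameter_map <- function(map, file) {
  utils::write.csv(as.data.frame(map), file, row.names = FALSE)
  side <- list(kind = attr(map, "kind"), fixed = attr(map, "fixed"))
  jsonlite::write_json(side, paste0(file, ".json"), auto_unbox = TRUE)
  invisible(file)
}
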