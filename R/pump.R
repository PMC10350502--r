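#' Pump program: a bit sequence encoded as a pump waveform
#'
#' Encodes an ordered binary sequence into the time-varying pump
#' \deqn{\mu_1(t) = \mu_0 + \sum_i c\, p_i\, \Pi_{\tau_p}(t - i\tau_b - \tau_d)}
#' where \eqn{\Pi_{\tau_p}} is a boxcar of duration `tau_p`. Bit `i`
#' (0-based) occupies the half-open interval
#' `[i*tau_b + tau_d, i*tau_b + tau_d + tau_p)`, so abutting pulses with
#' `tau_p == tau_b` concatenate without double counting. In the short-pulse
#' limit the physically relevant drive is the pulse energy `tau_p * c`.
#'
#' @param bits binary sequence: a string like `"00111"` or a 0/1 vector.
#' @param mu0 base pump value.
#' @param c pump amplitude added while a "1" bit's pulse is on.
#' @param tau_b bit duration (time allotted per pixel).
#' @param tau_p pulse duration within each bit; must satisfy `tau_p <= tau_b`.
#' @param tau_d onset delay of the whole sequence.
#' @param t_pad padding after the last bit before the program ends; the
#'   post-stimulus window in which late spikes are still observed.
#' @return An object of class `pump_program`.
#' @examples
#' pr <- pump_program("00111", mu0 = 1.25, c = 6)
#' pump_level(pr, c(0, 100, 120, 130, 149, 150))
#' @export
pump_program <- function(bits, mu0, c, tau_b = 50, tau_p = 30, tau_d = 0,
                         t_pad = 3000) {
  bits <- parse_bits(bits)
  if (!length(bits)) stop("bits must be non-empty", call. = FALSE)
  if (tau_p > tau_b) stop("tau_p must not exceed tau_b", call. = FALSE)
  if (c < 0) stop("pump amplitude c must be non-negative", call. = FALSE)
  if (tau_d < 0) stop("tau_d must be non-negative", call. = FALSE)
  stopifnot(is.finite(mu0), is.finite(c), tau_b > 0, tau_p > 0, t_pad >= 0)
  structure(list(bits = bits, mu0 = mu0, c = c, tau_b = tau_b, tau_p = tau_p,
                 tau_d = tau_d, t_pad = t_pad),
            class = "pump_program")
}

parse_bits <- function(bits) {
  if (is.character(bits)) {
    stopifnot(length(bits) == 1)
    bits <- as.integer(strsplit(bits, "")[[1]])
  }
  bits <- as.integer(bits)
  if (anyNA(bits) || !all(bits %in% c(0L, 1L))) {
    stop("bits must be 0/1", call. = FALSE)
  }
  bits
}

#' Evaluate a pump program
#'
#' @param prog a [pump_program()].
#' @param t time(s) at which to evaluate `mu_1(t)`; vectorised.
#' @return Numeric vector of pump values.
#' @export
pump_level <- function(prog, t) {
  stopifnot(inherits(prog, "pump_program"))
  on <- rep(FALSE, length(t))
  idx <- which(prog$bits == 1L) - 1L
  for (i in idx) {
    t0 <- i * prog$tau_b + prog$tau_d
    on <- on | (t >= t0 & t < t0 + prog$tau_p)
  }
  prog$mu0 + prog$c * as.numeric(on)
}

#' @rdname pump_level
#' @export
pump_end <- function(prog) {
  prog$tau_d + length(prog$bits) * prog$tau_b + prog$t_pad
}

# times at which mu_1 switches level, within [0, pump_end]
pump_breakpoints <- function(prog) {
  idx <- which(prog$bits == 1L) - 1L
  br <- c(0, pump_end(prog))
  for (i in idx) {
    t0 <- i * prog$tau_b + prog$tau_d
    br <- c(br, t0, t0 + prog$tau_p)
  }
  br <- sort(unique(br))
  br[br >= 0 & br <= pump_end(prog)]
}

#' Tabulate a pump waveform
#'
#' @param prog a [pump_program()].
#' @param dt sampling step.
#' @return A data frame with columns `t` and `mu1`, suitable for CSV export.
#' @export
pump_table <- function(prog, dt = 1) {
  t <- seq(0, pump_end(prog), by = dt)
  data.frame(t = t, mu1 = pump_level(prog, t))
}

#' @export
print.pump_program <- function(x, ...) {
  cat(sprintf("<pump_program> bits %s, mu0 = %g, c = %g\n",
              paste(x$bits, collapse = ""), x$mu0, x$c))
  cat(sprintf("  tau_b = %g, tau_p = %g, tau_d = %g, pad = %g (ends at %g)\n",
              x$tau_b, x$tau_p, x$tau_d, x$t_pad, pump_end(x)))
  invisible(x)
}
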