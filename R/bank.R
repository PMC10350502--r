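#' A tuned feature-detector neuron
#'
#' A detector is one microlaser neuron assigned to one receptive field and
#' tuned, through its base pump `mu0` and pulse amplitude `c`, to respond to
#' a target bit pattern: a run of three ("111") or four ("1111") consecutive
#' ones, or the sequence-selective "10111" (fires on "10111" but not on the
#' mirrored "11101").
#'
#' @param field receptive-field name, e.g. `"H1"` or `"V4"`.
#' @param intent the pattern the tuning is meant to detect.
#' @param mu0,c neuron tuning.
#' @param tau_b,tau_p bit and pulse durations.
#' @return An object of class `detector_spec`.
#' @seealso [default_event_bank()], [validate_detector()]
#' @export
detector_spec <- function(field, intent = c("111", "1111", "10111"),
                          mu0, c, tau_b = 50, tau_p = 30) {
  intent <- match.arg(intent)
  stopifnot(field %in% all_field_names())
  structure(list(field = field, intent = intent, mu0 = mu0, c = c,
                 tau_b = tau_b, tau_p = tau_p),
            class = "detector_spec")
}

#' @export
print.detector_spec <- function(x, ...) {
  cat(sprintf("<detector_spec> %s ~ \"%s\" at (mu0 = %g, c = %g)\n",
              x$field, x$intent, x$mu0, x$c))
  invisible(x)
}

#' Check that a detector's tuning realizes its intent
#'
#' Verifies the tuning against the excitability maps: a "111" detector must
#' have minimum run length 3, a "1111" detector 4, and a "10111" detector
#' must fire on "10111" while rejecting "11101".
#'
#' @param spec a [detector_spec()].
#' @param params a [laser_params()] object.
#' @return Logical.
#' @export
validate_detector <- function(spec, params = laser_params()) {
  mr <- function() min_run_to_spike(spec$mu0, spec$c, spec$tau_b, spec$tau_p,
                                    params)
  switch(spec$intent,
    "111"  = identical(mr(), 3L),
    "1111" = identical(mr(), 4L),
    "10111" = pattern_discriminates(spec$mu0, spec$c, "10111", "11101",
                                    spec$tau_b, spec$tau_p, params))
}

#' The default 10-neuron event-coding bank
#'
#' The bank pairs receptive fields with tuned detectors: `H1, H3, H5, V2,
#' V4` look for "111", `V2, V3, V4` for "1111", and `V2` and `V4` for the
#' sequence-selective "10111" that separates the mirror digits 2 and 5
#' (`sym_units` can restrict this to a single unit). Detector amplitudes
#' are taken from the package's own excitability maps so that every tuning
#' realizes its intent: at `mu0 = 1.25` the run-3 firing boundary sits at
#' `c = 5.39`, the run-4 boundary at 4.46, and the "10111" priming boundary
#' at 4.63, giving `c = 6` for "111" detectors (printed map region), a pure
#' run-4 window at `c = 4.55` and a "10111"-selective window at `c = 5`.
#'
#' @param sym_units which "10111" units to include: both (default), or a
#'   single one.
#' @return List of ten (or nine) [detector_spec()]s.
#' @export
default_event_bank <- function(sym_units = c("both", "V2", "V4")) {
  sym_units <- match.arg(sym_units)
  b <- list()
  for (f in c("H1", "H3", "H5", "V2", "V4")) {
    b[[length(b) + 1]] <- detector_spec(f, "111", mu0 = 1.25, c = 6)
  }
  for (f in c("V2", "V3", "V4")) {
    b[[length(b) + 1]] <- detector_spec(f, "1111", mu0 = 1.25, c = 4.55)
  }
  sym <- if (sym_units == "both") c("V2", "V4") else sym_units
  for (f in sym) {
    b[[length(b) + 1]] <- detector_spec(f, "10111", mu0 = 1.25, c = 5)
  }
  names(b) <- vapply(b, function(u) paste0(u$field, "_", u$intent), "")
  b
}

#' Default tunings of the temporal coding schemes
#'
#' The spike-time scheme runs its seven field neurons near the excitable
#' threshold, where the latency difference between 3-run and 4-run inputs
#' exceeds the bit time (`delta ~ 230 > tau_b = 50` at the default tuning),
#' so a spike's timing identifies both the run length and its position. The
#' rank scheme runs slightly further from threshold so that runs of three,
#' four and five all fire with distinct latencies, and relies only on the
#' order of arrival, with per-field onset delays breaking degeneracies.
#'
#' @return A list with `fields`, `mu0`, `c`, `tau_b`, `tau_p` (and, for the
#'   rank scheme, the per-field `delays`).
#' @export
spiketime_tuning <- function() {
  list(fields = c("V2", "V3", "V4", "H1", "H3", "H4", "H5"),
       mu0 = 2.65, c = 0.355, tau_b = 50, tau_p = 30)
}

#' @rdname spiketime_tuning
#' @export
rank_tuning <- function() {
  list(fields = c("V2", "V3", "V4", "H1", "H3", "H4", "H5"),
       mu0 = 2.6, c = 0.7, tau_b = 50, tau_p = 30,
       delays = c(V2 = 24, V3 = 47, V4 = 20, H1 = 60, H3 = 91, H4 = 9,
                  H5 = 67))
}
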