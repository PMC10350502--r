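#' Build a codebook for one coding scheme over a digit font
#'
#' Simulates every digit of `font` through the chosen scheme and stores the
#' resulting code per digit:
#'
#' * `"event"`: one spike/no-spike bit per detector of `bank`, in bank
#'   order. Time plays no role.
#' * `"spiketime"`: a temporal position stamp per receptive field. All
#'   first-spike latencies observed over the font at the scheme tuning are
#'   clustered (a gap larger than `slot_gap` starts a new cluster) and the
#'   stamp is the cluster rank, fastest = 1; silent fields stamp 0. The
#'   cluster boundaries are stored in the codebook so that later
#'   classifications reuse the same stamp origin.
#' * `"rank"`: the identities of the first (up to) three fields to spike,
#'   in arrival order, after each field's pump program is onset-delayed by
#'   its `delays` entry. Absolute times are discarded.
#'
#' The codebook records whether the per-digit codes are pairwise distinct
#' (`unique` flag); decoding is well-defined only in that case.
#'
#' @param scheme coding scheme.
#' @param font a `digit_font`.
#' @param params a [laser_params()] object.
#' @param bank event scheme: list of [detector_spec()]s.
#' @param tuning temporal schemes: list as returned by [spiketime_tuning()]
#'   or [rank_tuning()].
#' @param delays rank scheme: named per-field onset delays (defaults to the
#'   tuning's).
#' @param slot_gap spike-time scheme: latency gap that separates stamp
#'   clusters.
#' @param allow_empty event scheme: whether an all-zero code is a legal
#'   codebook entry (a digit whose fields trip no detector).
#' @return An object of class `codebook`.
#' @export
build_codebook <- function(scheme = c("event", "spiketime", "rank"), font,
                           params = laser_params(),
                           bank = default_event_bank(),
                           tuning = NULL, delays = NULL, slot_gap = 5,
                           allow_empty = TRUE) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(font, "digit_font"))
  cb <- switch(scheme,
    event = {
      codes <- vapply(font, function(img)
        code_string(event_code(img, bank, params)), "")
      list(scheme = scheme, entries = codes, bank = bank,
           allow_empty = allow_empty)
    },
    spiketime = {
      tuning <- tuning %||% spiketime_tuning()
      lats <- spiketime_latencies(font, tuning, params)
      breaks <- slot_breaks(unlist(lats), slot_gap)
      codes <- vapply(lats, function(l) code_string(stamp_of(l, breaks)), "")
      list(scheme = scheme, entries = codes, tuning = tuning,
           slot_breaks = breaks, slot_gap = slot_gap)
    },
    rank = {
      tuning <- tuning %||% rank_tuning()
      delays <- delays %||% tuning$delays
      stopifnot(!is.null(names(delays)), all(tuning$fields %in% names(delays)))
      rc <- lapply(font, function(img) rank_code(img, tuning, delays, params))
      codes <- vapply(rc, `[[`, "", "code")
      ties <- vapply(rc, `[[`, TRUE, "tie")
      if (any(ties)) {
        warning("arrival-time ties broken by field order for digit(s): ",
                paste(names(font)[ties], collapse = ", "), call. = FALSE)
      }
      list(scheme = scheme, entries = codes, tuning = tuning,
           delays = delays[tuning$fields], ties = ties)
    })
  cb$unique <- !anyDuplicated(cb$entries)
  structure(cb, class = "codebook")
}

code_string <- function(x) paste(x, collapse = "-")

#' @export
print.codebook <- function(x, ...) {
  cat(sprintf("<codebook> scheme %s, %d entries, %s\n", x$scheme,
              length(x$entries),
              if (x$unique) "codes unique" else "CODES NOT UNIQUE"))
  for (d in names(x$entries)) cat(sprintf("  %s: %s\n", d, x$entries[[d]]))
  invisible(x)
}

# ---- scheme primitives -----------------------------------------------------

# event scheme: 0/1 response per detector, in bank order
event_code <- function(img, bank, params = laser_params()) {
  fb <- image_fields(img)
  vapply(bank, function(u) {
    lat <- pattern_latency(fb[[u$field]]$bits, u$mu0, u$c, u$tau_b, u$tau_p,
                           params = params)
    as.integer(is.finite(lat))
  }, 0L)
}

# first-spike latency per scheme field for one image
spiketime_latencies <- function(font_or_img, tuning, params) {
  one <- function(img) {
    fb <- image_fields(img)
    vapply(tuning$fields, function(f)
      pattern_latency(fb[[f]]$bits, tuning$mu0, tuning$c, tuning$tau_b,
                      tuning$tau_p, params = params), 0)
  }
  if (inherits(font_or_img, "digit_font")) lapply(font_or_img, one)
  else one(font_or_img)
}

# cluster upper edges: a gap > slot_gap starts a new cluster
slot_breaks <- function(lats, slot_gap) {
  fin <- sort(unique(lats[is.finite(lats)]))
  if (!length(fin)) return(numeric(0))
  fin[c(which(diff(fin) > slot_gap), length(fin))]
}

# stamp: cluster rank (1 = fastest), 0 for a silent field
stamp_of <- function(lat, breaks) {
  ifelse(is.finite(lat),
         findInterval(lat, breaks + 1e-9) + 1L,
         0L)
}

# rank scheme: arrival order of the first <= 3 field spikes
rank_code <- function(img, tuning, delays, params = laser_params(),
                      tie_tol = 0.5) {
  fb <- image_fields(img)
  tt <- vapply(tuning$fields, function(f)
    pattern_latency(fb[[f]]$bits, tuning$mu0, tuning$c, tuning$tau_b,
                    tuning$tau_p, params = params), 0) +
    delays[tuning$fields]
  fin <- tuning$fields[is.finite(tt)]
  tf <- tt[is.finite(tt)]
  # stable order: ties within tie_tol resolve by field declaration order;
  # only ties among the first arrivals (and the 3rd/4th boundary) can
  # affect the code
  ord <- order(tf)
  lead <- utils::head(sort(tf), 4)
  tie <- length(lead) >= 2 && any(diff(lead) < tie_tol)
  first3 <- utils::head(fin[ord], 3)
  list(code = paste(first3, collapse = ">"), tie = tie,
       times = stats::setNames(tt, tuning$fields))
}

# ---- classification --------------------------------------------------------

#' Classify a digit image with a codebook
#'
#' `classify_event()` simulates each detector of the codebook's bank on its
#' receptive field and looks the resulting spike/no-spike vector up in the
#' codebook (exact match). `classify_spiketime()` stamps each field's first
#' spike with the codebook's stored latency clusters. `classify_rank()`
#' applies the codebook's per-field delays and matches the arrival order of
#' the first three spikes; arrival ties within 0.5 time units are broken by
#' field declaration order with a warning.
#'
#' @param img a [digit_image()].
#' @param codebook a [build_codebook()] result of the matching scheme.
#' @param params a [laser_params()] object.
#' @return The decoded digit label as a character scalar, or
#'   `NA_character_` ("unknown") when no codebook entry matches.
#' @export
classify_event <- function(img, codebook, params = laser_params()) {
  stopifnot(inherits(codebook, "codebook"), codebook$scheme == "event")
  code <- code_string(event_code(img, codebook$bank, params))
  empty <- code_string(rep(0L, length(codebook$bank)))
  if (!codebook$allow_empty && code == empty) return(NA_character_)
  decode(code, codebook)
}

#' @rdname classify_event
#' @export
classify_spiketime <- function(img, codebook, params = laser_params()) {
  stopifnot(inherits(codebook, "codebook"), codebook$scheme == "spiketime")
  lat <- spiketime_latencies(img, codebook$tuning, params)
  decode(code_string(stamp_of(lat, codebook$slot_breaks)), codebook)
}

#' @rdname classify_event
#' @export
classify_rank <- function(img, codebook, params = laser_params()) {
  stopifnot(inherits(codebook, "codebook"), codebook$scheme == "rank")
  rc <- rank_code(img, codebook$tuning, codebook$delays, params)
  if (rc$tie) warning("arrival-time tie broken by field order", call. = FALSE)
  decode(rc$code, codebook)
}

decode <- function(code, codebook) {
  hit <- names(codebook$entries)[codebook$entries == code]
  if (length(hit) == 1) hit else NA_character_
}

# ---- feature-subset and delay searches ------------------------------------

#' Smallest receptive-field subset with unique spike-time codes
#'
#' Exhaustively searches subsets of `candidate_fields` in order of
#' increasing size and returns the first whose per-digit spike-time stamp
#' codes are pairwise distinct over the font. With the ten row/column
#' fields of a 5x5 image there are at most 2^10 subsets, so the search is
#' exact.
#'
#' @param font a `digit_font`.
#' @param candidate_fields fields to search over (default: all ten).
#' @param tuning spike-time tuning (defaults to [spiketime_tuning()]).
#' @param params a [laser_params()] object.
#' @param slot_gap latency gap separating stamp clusters.
#' @return A list with `fields` (one minimal subset) and `size`.
#' @export
min_field_subset <- function(font, candidate_fields = all_field_names(),
                             tuning = NULL, params = laser_params(),
                             slot_gap = 5) {
  tuning <- tuning %||% spiketime_tuning()
  tuning$fields <- candidate_fields
  lats <- spiketime_latencies(font, tuning, params)
  breaks <- slot_breaks(unlist(lats), slot_gap)
  stamps <- vapply(lats, stamp_of, integer(length(candidate_fields)),
                   breaks = breaks)          # fields x digits
  if (anyDuplicated(apply(stamps, 2, code_string))) {
    stop("full candidate set does not yield unique codes", call. = FALSE)
  }
  for (k in seq_along(candidate_fields)) {
    sets <- utils::combn(seq_along(candidate_fields), k, simplify = FALSE)
    for (s in sets) {
      if (!anyDuplicated(apply(stamps[s, , drop = FALSE], 2, code_string))) {
        return(list(fields = candidate_fields[s], size = k))
      }
    }
  }
}

#' Search random per-field delays for the rank scheme
#'
#' Samples integer delay vectors uniformly from `delay_range` for each
#' field and keeps those whose rank codebook over the font is unique and
#' free of arrival ties. The delays are hyperparameters: not all draws
#' work, but suitable ones are common.
#'
#' @param font a `digit_font`.
#' @param tuning rank tuning (defaults to [rank_tuning()]).
#' @param n_trials number of random draws.
#' @param seed RNG seed, for reproducibility.
#' @param delay_range inclusive integer range delays are drawn from.
#' @param params a [laser_params()] object.
#' @return A list with `valid` (list of named delay vectors that work),
#'   `n_trials` and `success_rate`.
#' @export
search_delays <- function(font, tuning = NULL, n_trials = 20, seed = 1,
                          delay_range = c(1, 100), params = laser_params()) {
  stopifnot(n_trials >= 1)
  tuning <- tuning %||% rank_tuning()
  nf <- length(tuning$fields)
  set.seed(seed)
  draws <- replicate(n_trials, stats::setNames(
    sample(seq(delay_range[1], delay_range[2]), nf, replace = TRUE),
    tuning$fields), simplify = FALSE)
  ok <- vapply(draws, function(d) delays_work(font, tuning, d, params), TRUE)
  list(valid = draws[ok], n_trials = n_trials, success_rate = mean(ok))
}

delays_work <- function(font, tuning, delays, params) {
  rc <- lapply(font, function(img) rank_code(img, tuning, delays, params))
  codes <- vapply(rc, `[[`, "", "code")
  !any(vapply(rc, `[[`, TRUE, "tie")) && !anyDuplicated(codes)
}

# ---- serialization ---------------------------------------------------------

#' Read / write codebooks as JSON
#'
#' @param codebook a [build_codebook()] result.
#' @param file path to a JSON file.
#' @return `read_codebook()` returns a `codebook`.
#' @export
write_codebook <- function(codebook, file) {
  x <- unclass(codebook)
  # jsonlite drops names on atomic vectors; store named vectors as objects
  x$entries <- as.list(x$entries)
  if (!is.null(x$delays)) x$delays <- as.list(x$delays)
  if (!is.null(x$ties)) x$ties <- as.list(x$ties)
  if (!is.null(x$bank)) {
    x$bank <- lapply(x$bank, unclass)
  }
  jsonlite::write_json(x, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname write_codebook
#' @export
read_codebook <- function(file) {
  x <- jsonlite::read_json(file, simplifyVector = TRUE)
  x$entries <- unlist(x$entries)
  if (!is.null(x$bank)) {
    x$bank <- lapply(x$bank, function(u) {
      structure(as.list(u), class = "detector_spec")
    })
  }
  if (!is.null(x$tuning)) x$tuning <- as.list(x$tuning)
  if (!is.null(x$delays)) x$delays <- unlist(x$delays)
  structure(x, class = "codebook")
}
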