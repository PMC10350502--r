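font <- digit_font()

test_that("the default event bank has ten units whose tunings work", {
  bank <- default_event_bank()
  expect_length(bank, 10)
  intents <- vapply(bank, `[[`, "", "intent")
  expect_equal(sum(intents == "111"), 5)
  expect_equal(sum(intents == "1111"), 3)
  expect_equal(sum(intents == "10111"), 2)
  expect_true(all(vapply(bank, validate_detector, TRUE)))
  expect_length(default_event_bank(sym_units = "V2"), 9)
})

test_that("event codes are distinct and classify the whole font", {
  cb <- build_codebook("event", font)
  expect_true(cb$unique)
  pred <- vapply(font, classify_event, "", codebook = cb)
  expect_equal(unname(pred), names(font))
})

test_that("event classification is deterministic and rejects a blank", {
  cb <- build_codebook("event", font)
  img <- font[["4"]]
  expect_identical(classify_event(img, cb), classify_event(img, cb))
  blank <- digit_image(matrix(0L, 5, 5))
  expect_true(is.na(classify_event(blank, cb)))
  cb2 <- build_codebook("event", font, allow_empty = FALSE)
  expect_true(is.na(classify_event(blank, cb2)))
})

test_that("digits 2 and 5 are split exactly by the sequence detectors", {
  cb <- build_codebook("event", font)
  c2 <- strsplit(cb$entries[["2"]], "-")[[1]]
  c5 <- strsplit(cb$entries[["5"]], "-")[[1]]
  sym <- vapply(cb$bank, `[[`, "", "intent") == "10111"
  expect_true(all(c2[!sym] == c5[!sym]))
  expect_true(any(c2[sym] != c5[sym]))
  # removing both "10111" units collapses the mirror pair
  cb_nosym <- build_codebook("event", font, bank = cb$bank[!sym])
  expect_false(cb_nosym$unique)
  expect_equal(cb_nosym$entries[["2"]], cb_nosym$entries[["5"]])
})

test_that("spike-time stamps give a unique code per digit", {
  cb <- build_codebook("spiketime", font)
  expect_true(cb$unique)
  pred <- vapply(font, classify_spiketime, "", codebook = cb)
  expect_equal(unname(pred), names(font))
  # a field without a spike stamps 0: digit 1 only drives its centre column
  s1 <- strsplit(cb$entries[["1"]], "-")[[1]]
  expect_equal(s1[cb$tuning$fields == "V3"], "1")
  expect_true(all(s1[!cb$tuning$fields %in% c("V3", "H5")] == "0"))
})

test_that("four-run inputs always stamp earlier than three-run inputs", {
  tu <- spiketime_tuning()
  l4 <- first_spike_latency(neuron_response("11110", tu$mu0, tu$c))
  l3 <- first_spike_latency(neuron_response("11100", tu$mu0, tu$c))
  # separation beyond one bit time: position stamps cannot overlap
  expect_gt(l3 - l4, tu$tau_b)
  cb <- build_codebook("spiketime", font)
  st4 <- stamp_of(l4, cb$slot_breaks)
  st3 <- stamp_of(l3, cb$slot_breaks)
  expect_lt(st4, st3)
})

test_that("rank order of the first three spikes labels every digit", {
  cb <- build_codebook("rank", font)
  expect_true(cb$unique)
  expect_false(any(cb$ties))
  pred <- vapply(font, classify_rank, "", codebook = cb)
  expect_equal(unname(pred), names(font))
  # digits with fewer than three spiking fields still decode
  expect_lt(length(strsplit(cb$entries[["1"]], ">")[[1]]), 3)
  expect_lt(length(strsplit(cb$entries[["7"]], ">")[[1]]), 3)
})

test_that("rank codes are invariant under a global delay shift", {
  cb <- build_codebook("rank", font)
  shifted <- build_codebook("rank", font, delays = cb$delays + 7)
  expect_equal(cb$entries, shifted$entries)
})

test_that("relabelling fields permutes codes without losing uniqueness", {
  tu <- spiketime_tuning()
  cb <- build_codebook("spiketime", font, tuning = tu)
  tu_rev <- tu
  tu_rev$fields <- rev(tu$fields)
  cb_rev <- build_codebook("spiketime", font, tuning = tu_rev)
  expect_true(cb_rev$unique)
  rev_code <- function(s) paste(rev(strsplit(s, "-")[[1]]), collapse = "-")
  expect_equal(vapply(cb$entries, rev_code, ""), cb_rev$entries)
})

test_that("the subset search is exact against a brute-force oracle", {
  # reduced candidate set keeps the oracle enumeration small
  fields <- c("V2", "V3", "V4", "H1", "H3", "H5")
  res <- min_field_subset(font, candidate_fields = fields)
  tu <- spiketime_tuning()
  tu$fields <- fields
  lats <- vapply(font, function(img)
    vapply(fields, function(f)
      first_spike_latency(neuron_response(field_bits(img, f), tu$mu0, tu$c)),
      0), numeric(length(fields)))
  breaks <- microspike:::slot_breaks(lats, 5)
  stamps <- apply(lats, c(1, 2), microspike:::stamp_of, breaks = breaks)
  oracle <- brute_min_subset(stamps)
  expect_equal(res$size, length(oracle))

  # a two-image toy font separable by a single field
  toy <- structure(list(a = font[["1"]], b = font[["8"]]),
                   class = "digit_font")
  expect_equal(min_field_subset(toy, candidate_fields = fields)$size, 1)
})

test_that("subset search fails loudly when the full set is degenerate", {
  same <- structure(list(a = font[["3"]], b = font[["3"]]),
                    class = "digit_font")
  expect_error(min_field_subset(same), "unique")
})

test_that("random delay search is reproducible and finds working vectors", {
  a <- search_delays(font, n_trials = 100, seed = 5)
  b <- search_delays(font, n_trials = 100, seed = 5)
  expect_equal(a$valid, b$valid)
  expect_gt(a$success_rate, 0)
  # every reported vector indeed yields a unique, tie-free codebook
  for (d in utils::head(a$valid, 3)) {
    cb <- build_codebook("rank", font, delays = d)
    expect_true(cb$unique)
  }
  # the published delay vector is among the workable ones
  expect_true(microspike:::delays_work(font, rank_tuning(),
                                       rank_tuning()$delays, laser_params()))
})

test_that("codebooks round-trip through JSON and classify identically", {
  for (scheme in c("event", "spiketime", "rank")) {
    cb <- build_codebook(scheme, font)
    tmp <- withr::local_tempfile(fileext = ".json")
    write_codebook(cb, tmp)
    back <- read_codebook(tmp)
    expect_equal(back$entries, cb$entries)
    expect_equal(back$unique, cb$unique)
    clf <- switch(scheme, event = classify_event,
                  spiketime = classify_spiketime, rank = classify_rank)
    expect_equal(clf(font[["6"]], back), "6")
  }
})

test_that("spike-time and rank schemes agree on well-classified digits", {
  cbs <- build_codebook("spiketime", font)
  cbr <- build_codebook("rank", font)
  ps <- vapply(font, classify_spiketime, "", codebook = cbs)
  pr <- vapply(font, classify_rank, "", codebook = cbr)
  agree <- ps == names(font)
  expect_true(all(pr[agree] == names(font)[agree]))
})
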