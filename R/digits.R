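#' 5x5 binary digit images and receptive fields
#'
#' A digit image is a 5x5 binary pixel grid. Its ten receptive fields are
#' the rows `H1..H5` (read left to right) and columns `V1..V5` (read top to
#' bottom); each field is a 5-bit sequence that drives one neuron through
#' the pump coding of [pump_program()]. The scan direction matters: it
#' decides whether a column reads as "10111" or its mirror "11101", which is
#' exactly the feature that separates digits 2 and 5. The convention is
#' fixed (rows left-to-right, columns top-to-bottom) and
#' `column_from_top = FALSE` in [image_fields()] flips it, which swaps the
#' roles of the 2/5 detectors.
#'
#' @param pixels a 5x5 0/1 matrix, or a character vector of 5 strings of
#'   5 characters ("01110", ...), rows top to bottom.
#' @param label optional digit label 0--9.
#' @return An object of class `digit_image` (a 5x5 integer matrix with a
#'   `label` attribute).
#' @export
digit_image <- function(pixels, label = NA_integer_) {
  if (is.character(pixels)) {
    stopifnot(length(pixels) == 5, all(nchar(pixels) == 5))
    pixels <- do.call(rbind, lapply(strsplit(pixels, ""), as.integer))
  }
  pixels <- as.matrix(pixels)
  if (!all(dim(pixels) == c(5, 5)) || anyNA(pixels) ||
      !all(pixels %in% c(0, 1))) {
    stop("a digit image is exactly 25 binary pixels (5x5)", call. = FALSE)
  }
  storage.mode(pixels) <- "integer"
  structure(pixels, label = label, class = c("digit_image", "matrix", "array"))
}

#' @export
print.digit_image <- function(x, ...) {
  lb <- attr(x, "label")
  cat(sprintf("<digit_image>%s\n",
              if (!is.na(lb)) paste0(" label ", lb) else ""))
  for (i in 1:5) cat(" ", gsub("0", ".", paste(x[i, ], collapse = "")), "\n")
  invisible(x)
}

#' Extract the ten receptive fields of an image
#'
#' @param img a [digit_image()].
#' @param column_from_top read columns top-to-bottom (the default
#'   convention); `FALSE` reads bottom-to-top.
#' @return Named list of ten `receptive_field` objects, `H1..H5, V1..V5`.
#' @examples
#' img <- digit_image(c("00000", "00000", "00111", "00111", "00111"))
#' field_bits(img, "V4")  # "00111"
#' @export
image_fields <- function(img, column_from_top = TRUE) {
  img <- digit_image(img, attr(img, "label") %||% NA_integer_)
  out <- list()
  for (i in 1:5) {
    out[[paste0("H", i)]] <- receptive_field("H", i, img[i, ])
  }
  for (j in 1:5) {
    col <- img[, j]
    if (!column_from_top) col <- rev(col)
    out[[paste0("V", j)]] <- receptive_field("V", j, col)
  }
  out
}

receptive_field <- function(axis, index, bits) {
  structure(list(axis = axis, index = as.integer(index),
                 bits = paste(as.integer(bits), collapse = "")),
            class = "receptive_field")
}

#' @export
print.receptive_field <- function(x, ...) {
  cat(sprintf("<receptive_field> %s%d: %s\n", x$axis, x$index, x$bits))
  invisible(x)
}

#' @rdname image_fields
#' @param field a field name such as `"H1"` or `"V4"`.
#' @export
field_bits <- function(img, field, column_from_top = TRUE) {
  image_fields(img, column_from_top)[[field]]$bits
}

`%||%` <- function(a, b) if (is.null(a)) b else a

all_field_names <- function() c(paste0("H", 1:5), paste0("V", 1:5))

#' The packaged digit font
#'
#' Returns the ten 5x5 binary digit images shipped with the package. The
#' glyphs are a synthetic reconstruction in the classic 5x5 pixel style,
#' drawn so that every digit carries at least one contiguous run of three
#' or more "on" pixels in a row or column, and digits 2 and 5 are exact
#' mirror images whose inner columns read "10111"/"11101" -- the structural
#' properties the feature detectors rely on (see [validate_font()]).
#'
#' @param file path to a font file; defaults to the packaged one.
#' @return A `digit_font`: named list of ten [digit_image()]s, names "0".."9".
#' @export
digit_font <- function(file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "digit_font_synthetic.txt",
                        package = "microspike", mustWork = TRUE)
  }
  read_digit_font(file)
}

#' Read / write a digit font as plain text
#'
#' The format is plain text: for each digit a line `digit: <d>` followed by
#' five lines of five `0`/`1` characters; blank lines and `#` comments are
#' ignored.
#'
#' @param file path to the font file.
#' @return [read_digit_font()] returns a `digit_font`.
#' @export
read_digit_font <- function(file) {
  ln <- readLines(file, warn = FALSE)
  ln <- trimws(sub("#.*$", "", ln))
  ln <- ln[nzchar(ln)]
  font <- list()
  i <- 1
  while (i <= length(ln)) {
    m <- regmatches(ln[i], regexec("^digit:\\s*([0-9])$", ln[i]))[[1]]
    if (length(m) != 2) stop("expected 'digit: <d>' at line: ", ln[i],
                             call. = FALSE)
    rows <- ln[(i + 1):(i + 5)]
    font[[m[2]]] <- digit_image(rows, label = as.integer(m[2]))
    i <- i + 6
  }
  structure(font, class = "digit_font")
}

#' @rdname read_digit_font
#' @param font a `digit_font`.
#' @export
write_digit_font <- function(font, file) {
  out <- character(0)
  for (d in names(font)) {
    out <- c(out, paste0("digit: ", d),
             apply(unclass(font[[d]]), 1, paste, collapse = ""), "")
  }
  writeLines(out, file)
  invisible(file)
}

#' @export
print.digit_font <- function(x, ...) {
  cat(sprintf("<digit_font> %d digit(s): %s\n", length(x),
              paste(names(x), collapse = " ")))
  invisible(x)
}

#' Structural validation of a digit font
#'
#' Checks the structural constraints the spike-code classifiers rely on:
#' (a) every digit has at least one receptive field containing a contiguous
#' run of three or more ones; (b) digits 2 and 5 each expose "10111" or
#' "11101" in at least one field, and their images are mirror images of one
#' another (columns reversed); (c) reports a per-digit inventory of maximal
#' run lengths. Violations are reported, not raised.
#'
#' @param font a `digit_font`.
#' @return An object of class `font_report` with elements `violations`
#'   (character vector, empty when the font is valid) and `runs` (per-digit
#'   data frame of maximal run length per field).
#' @export
validate_font <- function(font) {
  stopifnot(inherits(font, "digit_font"))
  violations <- character(0)
  runs <- list()
  for (d in names(font)) {
    fb <- image_fields(font[[d]])
    maxrun <- vapply(fb, function(f) max_run(f$bits), 0L)
    runs[[d]] <- maxrun
    if (max(maxrun) < 3L) {
      violations <- c(violations, sprintf(
        "digit %s has no receptive field with a run of >= 3 ones", d))
    }
  }
  sym <- function(d) {
    fb <- image_fields(font[[d]])
    any(vapply(fb, function(f) f$bits %in% c("10111", "11101"), TRUE))
  }
  for (d in c("2", "5")) {
    if (!is.null(font[[d]]) && !sym(d)) {
      violations <- c(violations, sprintf(
        "digit %s has no field reading '10111' or '11101'", d))
    }
  }
  if (!is.null(font[["2"]]) && !is.null(font[["5"]])) {
    # mirror relation: digit 5 is digit 2 with columns reversed
    m2 <- unclass(font[["2"]])[, 5:1]
    m5 <- unclass(font[["5"]])
    mirror25 <- all(dim(m2) == dim(m5)) && all(m2 == m5)
    if (!mirror25) {
      violations <- c(violations, "digits 2 and 5 are not mirror images")
    }
  }
  runs <- as.data.frame(do.call(rbind, runs))
  structure(list(violations = violations, runs = runs),
            class = "font_report")
}

max_run <- function(bits) {
  r <- rle(strsplit(bits, "")[[1]])
  ones <- r$lengths[r$values == "1"]
  if (!length(ones)) 0L else max(ones)
}

#' @export
print.font_report <- function(x, ...) {
  if (!length(x$violations)) {
    cat("font OK: 0 violations\n")
  } else {
    cat(length(x$violations), "violation(s):\n")
    for (v in x$violations) cat("  -", v, "\n")
  }
  cat("max run per field:\n")
  print(x$runs)
  invisible(x)
}
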