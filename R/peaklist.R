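#' Construct a 2D peak list
#'
#' A peak list is a tibble with one row per cross-peak of a 2D amide
#' correlation spectrum (HSQC/TROSY). By the common amide convention
#' `w1` is the 15N dimension and `w2` the 1H dimension, both in ppm.
#' Heights are arbitrary spectrometer intensity units and may be negative
#' (artifact peaks).
#'
#' @param data A data frame with columns `w1`, `w2` and optionally
#'   `height` and `label`.
#' @param source_label Free-text provenance tag (e.g. `"free"`,
#'   `"plus_LRP6E1E2"`), stored as an attribute.
#' @return A tibble of class `"peaklist"` with columns
#'   `label`, `w1`, `w2`, `height`.
#' @examples
#' peaklist(data.frame(w1 = 109.8, w2 = 8.42, height = 1.2e6,
#'                     label = "G68N-H"))
#' @export
peaklist <- function(data, source_label = NULL) {
  data <- as_tibble(data)
  if (!all(c("w1", "w2") %in% names(data))) {
    abort("`data` must have columns `w1` and `w2` (ppm).")
  }
  if (!"height" %in% names(data)) data$height <- NA_real_
  if (!"label" %in% names(data)) data$label <- NA_character_
  data$label[!is.na(data$label) & data$label == "?-?"] <- NA_character_
  out <- data[, c("label", "w1", "w2", "height")]
  out$w1 <- as.double(out$w1)
  out$w2 <- as.double(out$w2)
  out$height <- as.double(out$height)
  out$label <- as.character(out$label)
  if (anyNA(out$w1) || anyNA(out$w2)) {
    abort("Peak positions `w1`/`w2` must be finite and non-missing.")
  }
  dup <- duplicated(out[, c("w1", "w2", "label")])
  if (any(dup)) {
    abort(sprintf("Duplicate peaks at rows: %s",
                  paste(which(dup), collapse = ", ")))
  }
  if (nrow(out) > 0 &&
      (any(out$w1 < 90 | out$w1 > 140) || any(out$w2 < 5 | out$w2 > 12))) {
    warn("Some peaks fall outside the usual amide window (w1 90-140, w2 5-12 ppm).")
  }
  structure(out,
            source_label = source_label %||% NA_character_,
            class = c("peaklist", class(out)))
}

#' Read a Sparky-style peak list
#'
#' Parses the whitespace-delimited `.list` export format: one row per peak
#' with columns assignment label, w1 (ppm), w2 (ppm) and an optional
#' height. Header lines (rows whose w1 field is non-numeric) are skipped.
#' The placeholder label `?-?` is treated as unassigned.
#'
#' @param path Path to the peak-list file.
#' @param source_label Optional provenance tag stored on the result.
#' @param swap_axes If `TRUE`, the file's first ppm column is 1H and the
#'   second 15N (swapped relative to the usual amide convention).
#' @return A [peaklist()] tibble.
#' @export
read_sparky_peaklist <- function(path, source_label = NULL, swap_axes = FALSE) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  lines_kept <- lines[keep]
  lineno <- which(keep)
  if (length(lines_kept) == 0) {
    warn(sprintf("Empty peak list: %s", path))
    return(peaklist(tibble(w1 = double(), w2 = double()),
                    source_label = source_label))
  }
  rows <- list()
  n_skipped <- 0L
  for (i in seq_along(lines_kept)) {
    f <- strsplit(trimws(lines_kept[[i]]), "\\s+")[[1]]
    if (length(f) < 3) {
      n_skipped <- n_skipped + 1L
      next
    }
    w1 <- suppressWarnings(as.numeric(f[[2]]))
    if (is.na(w1)) { # header line: first data column non-numeric
      n_skipped <- n_skipped + 1L
      next
    }
    w2 <- suppressWarnings(as.numeric(f[[3]]))
    if (is.na(w2)) {
      abort(sprintf("Malformed numeric field on line %d of %s",
                    lineno[[i]], path))
    }
    height <- NA_real_
    if (length(f) >= 4) {
      height <- suppressWarnings(as.numeric(f[[4]]))
      if (is.na(height) && f[[4]] != "NA") {
        abort(sprintf("Malformed height field on line %d of %s",
                      lineno[[i]], path))
      }
    }
    rows[[length(rows) + 1L]] <- tibble(label = f[[1]], w1 = w1, w2 = w2,
                                        height = height)
  }
  if (length(rows) == 0) {
    warn(sprintf("No data rows in peak list: %s", path))
    return(peaklist(tibble(w1 = double(), w2 = double()),
                    source_label = source_label))
  }
  out <- bind_rows(rows)
  stopifnot(nrow(out) + n_skipped == length(lines_kept))
  if (swap_axes) out <- dplyr::rename(out, w1 = "w2", w2 = "w1")
  peaklist(out, source_label = source_label)
}

#' Write a Sparky-style peak list
#'
#' @param x A [peaklist()] tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sparky_peaklist <- function(x, path) {
  header <- sprintf("%-12s %9s %9s %14s", "Assignment", "w1", "w2", "Height")
  lab <- ifelse(is.na(x$label), "?-?", x$label)
  # %.17g keeps full double precision so write -> read round-trips exactly
  body <- sprintf("%-12s %.17g %.17g %.17g", lab, x$w1, x$w2, x$height)
  body <- sub(" +NA$", "", body)  # drop missing heights
  writeLines(c(header, body), path)
  invisible(path)
}
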