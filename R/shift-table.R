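AA1 <- c("A","C","D","E","F","G","H","I","K","L",
         "M","N","P","Q","R","S","T","V","W","Y")

AA3 <- c(A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE", G = "GLY",
         H = "HIS", I = "ILE", K = "LYS", L = "LEU", M = "MET", N = "ASN",
         P = "PRO", Q = "GLN", R = "ARG", S = "SER", T = "THR", V = "VAL",
         W = "TRP", Y = "TYR")

#' Construct an assigned backbone amide chemical-shift table
#'
#' One row per residue: residue number (1-based, numbered from the
#' initiator methionine of the preprotein; no internal renumbering),
#' one-letter amino-acid code, and backbone amide shifts
#' `H` (1HN, ppm) and `N` (15NH, ppm), `NA` where unassigned. Prolines
#' have no backbone amide and must carry missing shifts.
#'
#' @param data A data frame with columns `residue`, `aa`, `H`, `N`.
#' @return A tibble of class `"shift_table"`.
#' @export
shift_table <- function(data) {
  data <- as_tibble(data)
  need <- c("residue", "aa")
  if (!all(need %in% names(data))) {
    abort("`data` must have columns `residue` and `aa`.")
  }
  if (!"H" %in% names(data)) data$H <- NA_real_
  if (!"N" %in% names(data)) data$N <- NA_real_
  out <- data[, c("residue", "aa", "H", "N")]
  out$residue <- as.integer(out$residue)
  out$aa <- toupper(as.character(out$aa))
  out$H <- as.double(out$H)
  out$N <- as.double(out$N)
  bad <- !out$aa %in% AA1
  if (any(bad)) {
    abort(sprintf("Unknown amino-acid code(s): %s",
                  paste(unique(out$aa[bad]), collapse = ", ")))
  }
  if (is.unsorted(out$residue, strictly = TRUE)) {
    abort("Residue numbers must be strictly increasing.")
  }
  pro_bad <- out$aa == "P" & (!is.na(out$H) | !is.na(out$N))
  if (any(pro_bad)) {
    abort(sprintf("Prolines cannot carry amide shifts (residue %s).",
                  paste(out$residue[pro_bad], collapse = ", ")))
  }
  structure(out, class = c("shift_table", class(out)))
}

#' Read an assigned chemical-shift table
#'
#' Two dialects are supported: `"tsv"` (columns `residue`, `aa`, `H`,
#' `N`; empty cells mean unassigned) and `"nmrstar"`, a minimal NMR-STAR
#' v3 `Atom_chem_shift` loop restricted to backbone amide atoms `H` and
#' `N`. Full STAR grammar is deliberately out of scope.
#'
#' @param path Path to the file.
#' @param dialect `"tsv"` or `"nmrstar"`.
#' @return A [shift_table()] tibble.
#' @export
read_shift_table <- function(path, dialect = c("tsv", "nmrstar")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  if (dialect == "tsv") {
    df <- utils::read.delim(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE,
                            colClasses = c("integer", "character",
                                           "numeric", "numeric"),
                            na.strings = c("", "NA"))
    names(df) <- c("residue", "aa", "H", "N")
    return(shift_table(df))
  }
  read_star_shift_loop(path)
}

# Minimal NMR-STAR v3 Atom_chem_shift loop reader: finds the loop whose
# tags start _Atom_chem_shift., maps Comp_index_ID/Comp_ID/Atom_ID/Val.
read_star_shift_loop <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  i_loop <- which(lines == "loop_")
  if (length(i_loop) == 0) abort("No loop_ found in NMR-STAR file.")
  for (i0 in i_loop) {
    j <- i0 + 1
    tags <- character()
    while (j <= length(lines) && startsWith(lines[[j]], "_")) {
      tags <- c(tags, lines[[j]])
      j <- j + 1
    }
    if (!any(startsWith(tags, "_Atom_chem_shift."))) next
    body <- character()
    while (j <= length(lines) && !lines[[j]] %in% c("stop_", "loop_")) {
      if (nzchar(lines[[j]]) && !startsWith(lines[[j]], "#")) {
        body <- c(body, lines[[j]])
      }
      j <- j + 1
    }
    tag <- sub("^_Atom_chem_shift\\.", "", tags)
    fields <- strsplit(body, "\\s+")
    n_bad <- lengths(fields) != length(tags)
    if (any(n_bad)) {
      abort("Malformed NMR-STAR row: field count does not match tag count.")
    }
    m <- do.call(rbind, fields)
    colnames(m) <- tag
    need <- c("Comp_index_ID", "Comp_ID", "Atom_ID", "Val")
    if (!all(need %in% tag)) {
      abort(sprintf("Atom_chem_shift loop lacks required tag(s): %s",
                    paste(setdiff(need, tag), collapse = ", ")))
    }
    df <- tibble(residue = as.integer(m[, "Comp_index_ID"]),
                 aa3 = toupper(m[, "Comp_ID"]),
                 atom = toupper(m[, "Atom_ID"]),
                 val = as.double(m[, "Val"]))
    df <- df[df$atom %in% c("H", "N"), ]
    if (anyDuplicated(df[, c("residue", "atom")])) {
      abort("Duplicate (residue, atom) rows in chemical-shift loop.")
    }
    aa1 <- names(AA3)[match(df$aa3, AA3)]
    if (anyNA(aa1)) {
      abort(sprintf("Unknown residue type(s): %s",
                    paste(unique(df$aa3[is.na(aa1)]), collapse = ", ")))
    }
    df$aa <- aa1
    wide <- tidyr::pivot_wider(df[, c("residue", "aa", "atom", "val")],
                               names_from = "atom", values_from = "val")
    if (!"H" %in% names(wide)) wide$H <- NA_real_
    if (!"N" %in% names(wide)) wide$N <- NA_real_
    wide <- wide[order(wide$residue), c("residue", "aa", "H", "N")]
    return(shift_table(wide))
  }
  abort("No Atom_chem_shift loop found in NMR-STAR file.")
}

#' Write an assigned chemical-shift table
#'
#' @param x A [shift_table()] tibble.
#' @param path Output path.
#' @param dialect `"tsv"` or `"nmrstar"`.
#' @return `path`, invisibly.
#' @export
write_shift_table <- function(x, path, dialect = c("tsv", "nmrstar")) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    lines <- c(paste(c("residue", "aa", "H", "N"), collapse = "\t"),
               sprintf("%d\t%s\t%s\t%s", x$residue, x$aa,
                       num_or_blank(x$H), num_or_blank(x$N)))
    writeLines(lines, path)
    return(invisible(path))
  }
  long <- tidyr::pivot_longer(x, cols = c("H", "N"), names_to = "atom",
                              values_to = "val")
  long <- long[!is.na(long$val), ]
  head_lines <- c("data_shifts", "", "loop_",
                  "_Atom_chem_shift.Comp_index_ID",
                  "_Atom_chem_shift.Comp_ID",
                  "_Atom_chem_shift.Atom_ID",
                  "_Atom_chem_shift.Atom_type",
                  "_Atom_chem_shift.Val")
  body <- sprintf("%d %s %s %s %.17g", long$residue, AA3[long$aa],
                  long$atom, substr(long$atom, 1, 1), long$val)
  writeLines(c(head_lines, body, "stop_"), path)
  invisible(path)
}

num_or_blank <- function(v) ifelse(is.na(v), "", sprintf("%.17g", v))

#' Convert a shift table to an amide peak list
#'
#' Drops residues with a missing 1H or 15N shift; labels follow the
#' Sparky convention `"<aa><residue>N-H"`.
#'
#' @param x A [shift_table()] tibble.
#' @param heights Optional vector of peak heights (recycled); default 1.
#' @param source_label Provenance tag for the peak list.
#' @return A [peaklist()] tibble.
#' @export
shifts_to_peaklist <- function(x, heights = 1, source_label = NULL) {
  obs <- x[!is.na(x$H) & !is.na(x$N), ]
  peaklist(tibble(label = sprintf("%s%dN-H", obs$aa, obs$residue),
                  w1 = obs$N, w2 = obs$H,
                  height = rep_len(as.double(heights), nrow(obs))),
           source_label = source_label)
}
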