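#' Construct a coordinate ensemble
#'
#' A coordinate ensemble is a tidy atom table covering one or more models
#' of the same molecule: columns `model` (1-based, file order), `chain`,
#' `resno`, `resid` (3-letter residue name), `elety` (atom name), and
#' `x`, `y`, `z` in Angstrom. Every model must contain the identical atom
#' roster.
#'
#' @param data A data frame with the columns above.
#' @return A tibble of class `"coord_ensemble"`.
#' @export
coord_ensemble <- function(data) {
  data <- as_tibble(data)
  need <- c("model", "chain", "resno", "resid", "elety", "x", "y", "z")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0) {
    abort(sprintf("Missing column(s): %s", paste(miss, collapse = ", ")))
  }
  out <- data[, need]
  out$model <- as.integer(out$model)
  out$resno <- as.integer(out$resno)
  if (nrow(out) == 0) abort("Ensemble has no atoms.")
  check_roster(out)
  structure(out, class = c("coord_ensemble", class(out)))
}

atom_key <- function(df) {
  paste(df$chain, df$resno, df$resid, df$elety, sep = "|")
}

check_roster <- function(atoms) {
  keys <- split(atom_key(atoms), atoms$model)
  ref <- keys[[1]]
  if (anyDuplicated(ref)) {
    abort(sprintf("Duplicate atoms within a model: %s",
                  paste(head(ref[duplicated(ref)], 5), collapse = "; ")))
  }
  for (m in names(keys)[-1]) {
    missing <- setdiff(ref, keys[[m]])
    extra <- setdiff(keys[[m]], ref)
    if (length(missing) + length(extra) > 0) {
      abort(sprintf(
        "Inconsistent atom roster in model %s: missing [%s] extra [%s]",
        m, paste(missing, collapse = "; "), paste(extra, collapse = "; ")))
    }
  }
  invisible(TRUE)
}

#' Read a (possibly multi-model) PDB file as a coordinate ensemble
#'
#' Files with `MODEL`/`ENDMDL` records yield one model per block, in file
#' order; a file without `MODEL` records is a single implicit model.
#' Alternate locations are resolved by keeping the highest-occupancy
#' conformer (tie: the first encountered). Record parsing is delegated to
#' [bio3d::read.pdb()].
#'
#' @param path Path to the PDB file.
#' @return A [coord_ensemble()] tibble.
#' @export
read_pdb_ensemble <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^MODEL", lines)
  ends <- grep("^ENDMDL", lines)
  if (length(starts) == 0) {
    blocks <- list(lines)
  } else {
    if (length(starts) != length(ends) || any(ends < starts)) {
      abort("Unbalanced MODEL/ENDMDL records.")
    }
    blocks <- map2(starts, ends, function(s, e) lines[(s + 1):(e - 1)])
  }
  models <- vector("list", length(blocks))
  for (i in seq_along(blocks)) {
    blk <- blocks[[i]]
    if (!any(grepl("^ATOM", blk))) {
      abort(sprintf("Model %d contains no ATOM records.", i))
    }
    tmp <- tempfile(fileext = ".pdb")
    on.exit(unlink(tmp), add = TRUE)
    writeLines(c(blk, "END"), tmp)
    pdb <- bio3d::read.pdb(tmp, rm.alt = FALSE, verbose = FALSE)
    at <- as_tibble(pdb$atom)
    at <- at[at$type == "ATOM", ]
    # alternate locations: keep highest occupancy, tie -> first
    at$o[is.na(at$o)] <- 1
    at <- at |>
      mutate(.ord = row_number()) |>
      group_by(.data$chain, .data$resno, .data$resid, .data$elety) |>
      filter(row_number() == order(-.data$o, .data$.ord)[1]) |>
      ungroup() |>
      arrange(.data$.ord)
    models[[i]] <- tibble(model = i, chain = at$chain, resno = at$resno,
                          resid = at$resid, elety = at$elety,
                          x = at$x, y = at$y, z = at$z)
  }
  coord_ensemble(bind_rows(models))
}

#' Write a coordinate ensemble as a multi-model PDB file
#'
#' Coordinates are written at the standard PDB precision (0.001 A).
#'
#' @param x A [coord_ensemble()] tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pdb_ensemble <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  multi <- length(unique(x$model)) > 1
  for (m in sort(unique(x$model))) {
    a <- x[x$model == m, ]
    if (multi) writeLines(sprintf("MODEL     %4d", m), con)
    # PDB v3 ATOM record layout; atom names left-padded per convention
    name <- ifelse(nchar(a$elety) < 4, sprintf(" %-3s", a$elety),
                   a$elety)
    writeLines(sprintf(
      "ATOM  %5d %4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
      seq_len(nrow(a)), name, a$resid, a$chain, a$resno,
      a$x, a$y, a$z, 1, 0), con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a steady-state binding curve from CSV
#'
#' Expects columns `conc_M` (molar analyte concentration) and
#' `response_nm` (biosensor steady-state response in nm).
#'
#' @param path Path to the CSV file.
#' @param analyte_label Optional analyte name stored as an attribute.
#' @return A tibble of class `"binding_curve"`.
#' @export
read_binding_curve <- function(path, analyte_label = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  binding_curve(df, analyte_label = analyte_label)
}

#' Construct a binding curve
#'
#' @param data A data frame with columns `conc_M` and `response_nm`.
#' @param analyte_label Optional analyte name stored as an attribute.
#' @return A tibble of class `"binding_curve"`.
#' @export
binding_curve <- function(data, analyte_label = NULL) {
  data <- as_tibble(data)
  if (!all(c("conc_M", "response_nm") %in% names(data))) {
    abort("`data` must have columns `conc_M` and `response_nm`.")
  }
  out <- data[, c("conc_M", "response_nm")]
  out$conc_M <- as.double(out$conc_M)
  out$response_nm <- as.double(out$response_nm)
  if (any(out$conc_M < 0)) abort("Concentrations must be >= 0.")
  structure(out,
            analyte_label = analyte_label %||% NA_character_,
            class = c("binding_curve", class(out)))
}

#' Write a binding curve as CSV
#'
#' @param x A `binding_curve` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_binding_curve <- function(x, path) {
  utils::write.csv(as.data.frame(x[, c("conc_M", "response_nm")]), path,
                   row.names = FALSE)
  invisible(path)
}
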