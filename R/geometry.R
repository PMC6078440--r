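BACKBONE_ATOMS <- c("N", "CA", "C")   # carbonyl O excluded by convention
BACKBONE_O_ATOMS <- c("N", "CA", "C", "O")

#' Parse a compact atom-selection string
#'
#' Syntax: `"44-47,50-96:backbone"` - comma-separated inclusive residue
#' ranges (or single residues), optionally followed by `:` and an atom
#' set: `backbone` (N, CA, C'), `backbone_o` (plus carbonyl O) or
#' `heavy` (all non-hydrogen). Default atom set: `backbone`.
#'
#' @param text Selection string.
#' @return A list with `residues` (integer vector) and `atoms`
#'   (atom-set name).
#' @export
parse_selection <- function(text) {
  parts <- strsplit(text, ":", fixed = TRUE)[[1]]
  atoms <- if (length(parts) > 1) parts[[2]] else "backbone"
  if (!atoms %in% c("backbone", "backbone_o", "heavy")) {
    abort(sprintf("Unknown atom set '%s'.", atoms))
  }
  ranges <- strsplit(parts[[1]], ",", fixed = TRUE)[[1]]
  res <- unlist(lapply(ranges, function(r) {
    ab <- as.integer(strsplit(trimws(r), "-", fixed = TRUE)[[1]])
    if (anyNA(ab)) abort(sprintf("Bad residue range '%s'.", r))
    if (length(ab) == 1) ab else seq(ab[1], ab[2])
  }))
  if (anyDuplicated(res)) abort("Selection ranges overlap.")
  list(residues = as.integer(res), atoms = atoms)
}

atom_set_filter <- function(elety, set) {
  switch(set,
         backbone = elety %in% BACKBONE_ATOMS,
         backbone_o = elety %in% BACKBONE_O_ATOMS,
         heavy = !grepl("^[0-9]?H", elety),
         abort(sprintf("Unknown atom set '%s'.", set)))
}

# coordinates of one model restricted to a selection, ordered by
# (residue, atom-name) so rows align across models and structures
select_coords <- function(ensemble, model, selection, chain = NULL) {
  a <- ensemble[ensemble$model == model, ]
  if (!is.null(chain)) {
    a <- a[a$chain == chain, ]
  } else {
    a <- a[a$chain == a$chain[1], ] # default: first chain
  }
  a <- a[a$resno %in% selection$residues &
           atom_set_filter(a$elety, selection$atoms), ]
  missing_res <- setdiff(selection$residues, unique(a$resno))
  if (length(missing_res) > 0) {
    abort(sprintf("Selection residues absent from model %d: %s", model,
                  paste(missing_res, collapse = ", ")))
  }
  a <- a[order(a$resno, a$elety), ]
  m <- as.matrix(a[, c("x", "y", "z")])
  rownames(m) <- paste(a$resno, a$elety, sep = "|")
  m
}

#' Least-squares rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the RMSD of
#' paired point set `A` onto `B` via the SVD of the cross-covariance
#' matrix; reflections are excluded, so the rotation determinant is +1.
#'
#' @param A,B Numeric matrices, one row per paired point, 3 columns;
#'   at least 3 non-collinear points.
#' @return A list of class `"superposition"`: `rotation` (3x3),
#'   `translation` (length 3), `rmsd` (A). The transform maps
#'   `A` onto `B`: `sweep(A %*% t(rotation), 2, -translation)`.
#' @export
kabsch_superpose <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (!all(dim(A) == dim(B)) || ncol(A) != 3) {
    abort("A and B must be n x 3 matrices with equal n.")
  }
  if (nrow(A) < 3) abort("At least 3 paired points required.")
  ca <- colMeans(A); cb <- colMeans(B)
  P <- sweep(A, 2, ca); Q <- sweep(B, 2, cb)
  sv_check <- svd(P)$d
  if (sv_check[2] < 1e-8 * max(sv_check[1], 1)) {
    abort("Degenerate (collinear) point configuration.")
  }
  H <- crossprod(P, Q)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  Pr <- P %*% t(R)
  rmsd <- sqrt(mean(rowSums((Pr - Q)^2)))
  stopifnot(abs(det(R) - 1) < 1e-9)
  structure(list(rotation = R, translation = as.numeric(cb - ca %*% t(R)),
                 rmsd = rmsd),
            class = "superposition")
}

apply_superposition <- function(coords, sup) {
  sweep(coords %*% t(sup$rotation), 2, sup$translation, "+")
}

#' RMSD-to-mean precision statistics of an NMR ensemble
#'
#' Iterative mean-structure procedure: all models are superposed on the
#' first over `fit_selection`, mean coordinates are computed, models are
#' re-superposed onto the mean and the mean recomputed, until the mean
#' coordinates change by less than `tol` (A). Per-model RMSDs to the
#' converged mean are then reported over `report_selection`.
#'
#' @param ensemble A [coord_ensemble()].
#' @param fit_selection Selection string (see [parse_selection()]) used
#'   for superposition.
#' @param report_selection Selection used for the reported RMSDs;
#'   defaults to `fit_selection`.
#' @param chain Chain ID; default the first chain.
#' @param tol Convergence tolerance on the mean coordinates (A).
#' @param max_iter Iteration cap.
#' @return A list of class `"rmsd_to_mean"`: `mean_rmsd`, `sd_rmsd`,
#'   `per_model` (tibble `model`, `rmsd`), `iterations`, selections.
#' @export
rmsd_to_mean <- function(ensemble, fit_selection,
                         report_selection = fit_selection, chain = NULL,
                         tol = 1e-6, max_iter = 200) {
  fit_sel <- if (is.character(fit_selection)) {
    parse_selection(fit_selection)
  } else {
    fit_selection
  }
  rep_sel <- if (is.character(report_selection)) {
    parse_selection(report_selection)
  } else {
    report_selection
  }
  models <- sort(unique(ensemble$model))
  fit <- lapply(models, function(m) select_coords(ensemble, m, fit_sel, chain))
  rep_ <- lapply(models, function(m) select_coords(ensemble, m, rep_sel, chain))
  # superpose everything on model 1 over the fit selection
  for (i in seq_along(models)) {
    sup <- kabsch_superpose(fit[[i]], fit[[1]])
    rep_[[i]] <- apply_superposition(rep_[[i]], sup)
    fit[[i]] <- apply_superposition(fit[[i]], sup)
  }
  mean_fit <- Reduce(`+`, fit) / length(fit)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    for (i in seq_along(models)) {
      sup <- kabsch_superpose(fit[[i]], mean_fit)
      rep_[[i]] <- apply_superposition(rep_[[i]], sup)
      fit[[i]] <- apply_superposition(fit[[i]], sup)
    }
    new_mean <- Reduce(`+`, fit) / length(fit)
    delta <- max(abs(new_mean - mean_fit))
    mean_fit <- new_mean
    if (delta < tol || iter >= max_iter) break
  }
  mean_rep <- Reduce(`+`, rep_) / length(rep_)
  per <- map_dbl(rep_, function(m) sqrt(mean(rowSums((m - mean_rep)^2))))
  structure(list(mean_rmsd = mean(per), sd_rmsd = sd(per),
                 per_model = tibble(model = models, rmsd = per),
                 iterations = iter,
                 fit_selection = fit_sel, report_selection = rep_sel),
            class = "rmsd_to_mean")
}

#' Backbone RMSD between two structures over a segment correspondence
#'
#' Pairs residues sequentially within equal-length segment lists of the
#' two structures, superposes the named atom of the paired residues
#' (Kabsch) and returns the RMSD. When published segment lists are of
#' unequal lengths, an explicit pairing must be supplied as equal-length
#' residue vectors rather than ranges.
#'
#' @param structA,structB [coord_ensemble()] objects (any single- or
#'   multi-model; see `modelA`/`modelB`).
#' @param segmentsA,segmentsB Segment lists: range strings like
#'   `"40-57,59-75,78-93"` or integer residue vectors. Total residue
#'   counts must be equal.
#' @param atom Atom name paired in each residue (default `"CA"`).
#' @param modelA,modelB Model numbers used for the comparison
#'   (default 1).
#' @param chainA,chainB Chain IDs; default the first chain.
#' @return The RMSD in Angstrom (scalar).
#' @export
segment_rmsd <- function(structA, structB, segmentsA, segmentsB,
                         atom = "CA", modelA = 1, modelB = 1,
                         chainA = NULL, chainB = NULL) {
  resA <- if (is.character(segmentsA)) parse_selection(segmentsA)$residues
          else as.integer(segmentsA)
  resB <- if (is.character(segmentsB)) parse_selection(segmentsB)$residues
          else as.integer(segmentsB)
  if (length(resA) != length(resB)) {
    abort(sprintf(
      "Segment lists pair %d with %d residues; totals must be equal.",
      length(resA), length(resB)))
  }
  coords_of <- function(ens, model, res, chain) {
    a <- ens[ens$model == model, ]
    a <- a[a$chain == (chain %||% a$chain[1]), ]
    a <- a[a$elety == atom, ]
    i <- match(res, a$resno)
    if (anyNA(i)) {
      abort(sprintf("Residue(s) lacking atom %s: %s", atom,
                    paste(res[is.na(i)], collapse = ", ")))
    }
    as.matrix(a[i, c("x", "y", "z")])
  }
  A <- coords_of(structA, modelA, resA, chainA)
  B <- coords_of(structB, modelB, resB, chainB)
  kabsch_superpose(A, B)$rmsd
}
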