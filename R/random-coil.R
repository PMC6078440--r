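# Coefficient cache (loaded once per session from inst/extdata).
.rc_env <- new.env(parent = emptyenv())

RC_REF_TEMP <- 298.15 # K, reference temperature of the coefficient table

#' Random-coil amide coefficient table
#'
#' Returns the neighbor-corrected random-coil coefficient set shipped
#' with the package (version 1.0, see
#' `system.file("extdata", "random_coil_amide_coeffs.tsv", package =
#' "solnmr")` for provenance notes and the full schema). Per amino acid:
#' intrinsic 1HN/15NH shifts at 298.15 K, neighbor corrections for
#' positions i-2..i+2, temperature coefficients (ppb/K), and
#' Henderson-Hasselbalch protonation shifts for Asp/Glu/His.
#'
#' @return A tibble with one row per standard amino acid.
#' @export
random_coil_coefficients <- function() {
  if (is.null(.rc_env$tab)) {
    path <- system.file("extdata", "random_coil_amide_coeffs.tsv",
                        package = "solnmr")
    tab <- utils::read.delim(path, comment.char = "#",
                             stringsAsFactors = FALSE)
    stopifnot(nrow(tab) == 20, all(AA1 %in% tab$aa),
              all(is.finite(as.matrix(tab[, -1]))))
    .rc_env$tab <- as_tibble(tab)
  }
  .rc_env$tab
}

# Shift of intrinsic cysteine values when the thiol is reduced rather
# than disulfide-bonded (the tabulated reference state).
CYS_REDUCED_DELTA <- c(H = -0.20, N = -3.50)

#' Predict random-coil backbone amide chemical shifts
#'
#' Sequence-, temperature- and pH-dependent random-coil 1HN and 15NH
#' shifts from the embedded neighbor-corrected coefficient set:
#' per-residue intrinsic value, plus corrections from the residue types
#' at positions i-2..i+2 (terminal residues use only the neighbors that
#' exist), a linear temperature term, and a Henderson-Hasselbalch pH
#' term for Asp/Glu/His side chains affecting the ionizable residue and
#' its i+-1 / i+-2 neighbors. Prolines have no backbone amide and are
#' reported missing.
#'
#' @param sequence One-letter amino-acid sequence (standard residues
#'   only).
#' @param temperature Sample temperature in K (273-373).
#' @param pH Sample pH (2-12).
#' @param first_residue Residue number of the first sequence position
#'   (default 1); numbering is continuous from there.
#' @param cys_reduced If `TRUE`, treat cysteines as reduced thiols;
#'   the default treats them as disulfide-bonded (cystine), appropriate
#'   for proteins whose cysteines are all oxidized.
#' @return A [shift_table()] with predicted `H` and `N` per residue.
#' @examples
#' predict_random_coil("GGAGG", temperature = 308, pH = 6.5)
#' @export
predict_random_coil <- function(sequence, temperature = 308, pH = 6.5,
                                first_residue = 1, cys_reduced = FALSE) {
  stopifnot(length(sequence) == 1, nchar(sequence) >= 1)
  if (temperature < 273 || temperature > 373) {
    abort("`temperature` must be within [273, 373] K.")
  }
  if (pH < 2 || pH > 12) abort("`pH` must be within [2, 12].")
  aa <- strsplit(toupper(sequence), "")[[1]]
  bad <- which(!aa %in% AA1)
  if (length(bad) > 0) {
    abort(sprintf("Nonstandard residue '%s' at position %d.",
                  aa[bad[1]], bad[1]))
  }
  tab <- random_coil_coefficients()
  idx <- match(aa, tab$aa)
  n <- length(aa)

  H <- tab$H[idx]
  N <- tab$N[idx]
  if (cys_reduced) {
    H[aa == "C"] <- H[aa == "C"] + CYS_REDUCED_DELTA[["H"]]
    N[aa == "C"] <- N[aa == "C"] + CYS_REDUCED_DELTA[["N"]]
  }

  # neighbor corrections: contribution to residue i from type at i+k
  nb_col <- list(`-2` = c("H_im2", "N_im2"), `-1` = c("H_im1", "N_im1"),
                 `1` = c("H_ip1", "N_ip1"),  `2` = c("H_ip2", "N_ip2"))
  for (k in c(-2L, -1L, 1L, 2L)) {
    j <- seq_len(n) + k
    ok <- j >= 1 & j <= n
    cols <- nb_col[[as.character(k)]]
    H[ok] <- H[ok] + tab[[cols[1]]][idx[j[ok]]]
    N[ok] <- N[ok] + tab[[cols[2]]][idx[j[ok]]]
  }

  # temperature term (tc in ppb/K)
  H <- H + tab$tcH[idx] * (temperature - RC_REF_TEMP) / 1000
  N <- N + tab$tcN[idx] * (temperature - RC_REF_TEMP) / 1000

  # pH term: protonated fraction of each ionizable residue adds its
  # protonation shift to itself and to sequence neighbors within 2.
  ion <- which(tab$pKa[idx] > 0)
  for (i in ion) {
    f <- 1 / (1 + 10^(pH - tab$pKa[idx[i]]))
    if (f == 0) next
    for (k in -2:2) {
      j <- i + k
      if (j < 1 || j > n) next
      col <- switch(as.character(abs(k)),
                    "0" = c("dH_self", "dN_self"),
                    "1" = c("dH_nb1", "dN_nb1"),
                    "2" = c("dH_nb2", "dN_nb2"))
      H[j] <- H[j] + f * tab[[col[1]]][idx[i]]
      N[j] <- N[j] + f * tab[[col[2]]][idx[i]]
    }
  }

  H[aa == "P"] <- NA_real_
  N[aa == "P"] <- NA_real_
  shift_table(tibble(residue = seq_len(n) + as.integer(first_residue) - 1L,
                     aa = aa, H = H, N = N))
}
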