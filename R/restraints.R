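# Standard distance-limit conventions (Angstrom), CYANA-style:
# disulfide SG-SG 2.0-2.1, CB-SG 3.0-3.1; hydrogen bond upper limits
# HN-O 2.3 and N-O 3.3.
SS_SG_SG <- c(lower = 2.0, upper = 2.1)
SS_CB_SG <- c(lower = 3.0, upper = 3.1)
HB_H_O <- 2.3
HB_N_O <- 3.3

new_restraints <- function(df) {
  stopifnot(all(!is.na(df$lower) | !is.na(df$upper)),
            all(is.na(df$lower) | df$lower > 0),
            all(is.na(df$upper) | df$upper > 0),
            all(is.na(df$lower) | is.na(df$upper) | df$lower <= df$upper))
  structure(as_tibble(df), class = c("restraint_table", class(as_tibble(df))))
}

#' Expand disulfide bonds into distance restraints
#'
#' Each cystine pair yields six distance limits in the standard
#' convention: a lower and an upper limit on SG(i)-SG(j)
#' (2.0 / 2.1 A) and lower and upper limits on CB-SG for both orderings
#' (3.0 / 3.1 A).
#'
#' @param pairs A data frame (or tibble) with columns `res_i`, `res_j`:
#'   cysteine residue numbers, distinct within each pair.
#' @return A `"restraint_table"` tibble: `res_a`, `atom_a`, `res_b`,
#'   `atom_b`, `lower`, `upper`, `category`; 6 rows per input pair.
#' @examples
#' expand_disulfides(data.frame(res_i = 41, res_j = 53))
#' @export
expand_disulfides <- function(pairs) {
  pairs <- as_tibble(pairs)
  if (nrow(pairs) == 0) {
    return(new_restraints(tibble(res_a = integer(), atom_a = character(),
                                 res_b = integer(), atom_b = character(),
                                 lower = double(), upper = double(),
                                 category = character())))
  }
  if (any(pairs$res_i == pairs$res_j)) {
    abort("A disulfide cannot join a residue to itself.")
  }
  key <- paste(pmin(pairs$res_i, pairs$res_j),
               pmax(pairs$res_i, pairs$res_j))
  if (anyDuplicated(key)) abort("Duplicate disulfide pair.")
  one <- function(i, j) {
    tibble(res_a = as.integer(c(i, i, i, i, j, j)),
           atom_a = c("SG", "SG", "CB", "CB", "CB", "CB"),
           res_b = as.integer(c(j, j, j, j, i, i)),
           atom_b = c("SG", "SG", "SG", "SG", "SG", "SG"),
           lower = c(SS_SG_SG[["lower"]], NA, SS_CB_SG[["lower"]], NA,
                     SS_CB_SG[["lower"]], NA),
           upper = c(NA, SS_SG_SG[["upper"]], NA, SS_CB_SG[["upper"]],
                     NA, SS_CB_SG[["upper"]]),
           category = "disulfide")
  }
  new_restraints(bind_rows(map2(pairs$res_i, pairs$res_j, one)))
}

#' Expand hydrogen bonds into distance restraints
#'
#' Each backbone hydrogen bond (amide donor to carbonyl acceptor)
#' yields two upper limits: HN-O at 2.3 A and N-O at 3.3 A.
#'
#' @param bonds A data frame with columns `donor`, `acceptor`: residue
#'   numbers of the amide donor and the carbonyl (C') acceptor.
#' @return A `"restraint_table"` tibble; 2 rows per input bond.
#' @export
expand_hbonds <- function(bonds) {
  bonds <- as_tibble(bonds)
  if (nrow(bonds) == 0) {
    return(new_restraints(tibble(res_a = integer(), atom_a = character(),
                                 res_b = integer(), atom_b = character(),
                                 lower = double(), upper = double(),
                                 category = character())))
  }
  if (any(bonds$donor == bonds$acceptor)) {
    abort("Donor and acceptor residues must differ.")
  }
  one <- function(d, a) {
    tibble(res_a = as.integer(c(d, d)), atom_a = c("H", "N"),
           res_b = as.integer(c(a, a)), atom_b = c("O", "O"),
           lower = NA_real_, upper = c(HB_H_O, HB_N_O),
           category = "hbond")
  }
  new_restraints(bind_rows(map2(bonds$donor, bonds$acceptor, one)))
}

#' Restraint manifest totals
#'
#' Tallies a structure-calculation restraint set by category.
#'
#' @param noe_upper Number of NOE-based upper distance limits.
#' @param torsion Number of backbone torsion-angle restraints.
#' @param hbond_restraints Number of hydrogen-bond distance limits
#'   (after expansion).
#' @param disulfide_restraints Number of disulfide distance limits
#'   (after expansion).
#' @return A one-row tibble of class `"restraint_manifest"` with the
#'   four categories and their `total`.
#' @export
manifest_totals <- function(noe_upper, torsion, hbond_restraints,
                            disulfide_restraints) {
  counts <- c(noe_upper, torsion, hbond_restraints, disulfide_restraints)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("Counts must be non-negative integers.")
  }
  out <- tibble(noe_upper = as.integer(noe_upper),
                torsion = as.integer(torsion),
                hbond = as.integer(hbond_restraints),
                disulfide = as.integer(disulfide_restraints),
                total = as.integer(sum(counts)))
  structure(out, class = c("restraint_manifest", class(out)))
}

#' Disulfide bonds of the Dkk4 CRD1 domain
#'
#' The five mapped cystine pairs of the first cysteine-rich domain:
#' C41-C53, C47-C63, C66-C80, C73-C85, C79-C90 (numbering from the
#' initiator methionine of the preprotein).
#'
#' @return A tibble with columns `res_i`, `res_j`.
#' @export
dkk4_crd1_disulfides <- function() {
  tibble(res_i = c(41L, 47L, 66L, 73L, 79L),
         res_j = c(53L, 63L, 80L, 85L, 90L))
}

#' Backbone hydrogen bonds of the Dkk4 CRD1 domain
#'
#' The twelve slow-exchange backbone amide hydrogen bonds used as
#' structural restraints (donor NH to acceptor C'=O residue numbers).
#'
#' @return A tibble with columns `donor`, `acceptor`.
#' @export
dkk4_crd1_hbonds <- function() {
  tibble(donor = c(46L, 47L, 62L, 64L, 71L, 73L, 84L, 86L, 89L, 90L,
                   91L, 96L),
         acceptor = c(43L, 44L, 54L, 52L, 68L, 88L, 91L, 89L, 86L, 71L,
                      84L, 92L))
}

#' Write a restraint table as TSV (or CYANA-style limit files)
#'
#' The TSV layout is `res_a atom_a res_b atom_b lower upper category`.
#' With `format = "cyana"` two files are written next to `path`
#' (suffixes `.upl`, `.lol`) holding upper and lower limits; this
#' emission is write-only.
#'
#' @param x A `"restraint_table"` tibble.
#' @param path Output path (TSV) or stem (CYANA).
#' @param format `"tsv"` or `"cyana"`.
#' @return `path`, invisibly.
#' @export
write_restraints <- function(x, path, format = c("tsv", "cyana")) {
  format <- match.arg(format)
  if (format == "tsv") {
    lines <- c("res_a\tatom_a\tres_b\tatom_b\tlower\tupper\tcategory",
               sprintf("%d\t%s\t%d\t%s\t%s\t%s\t%s", x$res_a, x$atom_a,
                       x$res_b, x$atom_b, num_or_blank(x$lower),
                       num_or_blank(x$upper), x$category))
    writeLines(lines, path)
    return(invisible(path))
  }
  upl <- x[!is.na(x$upper), ]
  lol <- x[!is.na(x$lower), ]
  writeLines(sprintf("%5d %-4s %-4s %5d %-4s %-4s %8.2f",
                     upl$res_a, "", upl$atom_a, upl$res_b, "", upl$atom_b,
                     upl$upper), paste0(path, ".upl"))
  writeLines(sprintf("%5d %-4s %-4s %5d %-4s %-4s %8.2f",
                     lol$res_a, "", lol$atom_a, lol$res_b, "", lol$atom_b,
                     lol$lower), paste0(path, ".lol"))
  invisible(path)
}
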