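# Fixed 206-residue model sequence for the two-domain architecture
# (residues numbered 19-224): cysteine positions in the first domain
# match the five mapped disulfides, an N-X-I-R motif sits at residues
# 26-29, and prolines are placed in the flexible linker and termini.
DKK4_LIKE_SEQUENCE <- paste0(
  "YFPMQMFNSIRGKNSPDQMGWDCQSDLDCVNDLFCLEMSYWDMFCALCYGQRRRCMIYHNCC",
  "DDLLCVRDVCTTITSAWVQGPIHMYNFAAPHYTKVINPNMWVLNPTQDDGEHPMMWGVVQHR",
  "FDCSHTKWVCVWHYTTKCVNQNWWVTRCTYYLCKQNSDESFCMDMTHCVLKHACIDVSAMCG",
  "IDDKEAACITKDLTTAKPMY")

#' Architecture of a two-domain protein with a flexible linker
#'
#' Builds the fixed study architecture emulated by all generators: a
#' 206-residue chain numbered 19-224 with flexible N-terminus (19-40),
#' inter-domain linker (98-139) and C-terminal tail (220-224), and two
#' structured cysteine-rich domains, CRD1 (41-97) and CRD2 (140-219).
#' The planted binding site is the whole of CRD2 in "lost" mode (its
#' signals vanish in the bound state, as for a tight, slowly tumbling
#' complex) plus six N-terminal residues around the N-X-I-R motif in
#' "shifted" mode (weak transient contact). The architecture itself is
#' identical for every seed; the seed only controls downstream noise.
#'
#' @param seed Integer seed stored on the architecture and used by the
#'   generators.
#' @param flex_sd,struct_sd Named numeric vectors `c(H = , N = )`:
#'   per-class shift-dispersion parameters (ppm) around the random-coil
#'   baseline.
#' @return A list of class `"protein_architecture"`.
#' @export
make_dkk4_like <- function(seed = 1L,
                           flex_sd = c(H = 0.03, N = 0.15),
                           struct_sd = c(H = 0.35, N = 3.0)) {
  stopifnot(all(flex_sd > 0), all(struct_sd > 0))
  regions <- tibble(start = c(19L, 41L, 98L, 140L, 220L),
                    end = c(40L, 97L, 139L, 219L, 224L),
                    class = c("flexible", "structured", "flexible",
                              "structured", "flexible"))
  arch <- list(sequence = DKK4_LIKE_SEQUENCE,
               first_residue = 19L,
               regions = regions,
               site_lost = 140:219,
               site_shifted = c(19L, 25L, 27L, 29L, 30L, 32L),
               flex_sd = flex_sd, struct_sd = struct_sd,
               seed = as.integer(seed))
  stopifnot(sum(regions$end - regions$start + 1) ==
              nchar(arch$sequence))
  class(arch) <- "protein_architecture"
  arch
}

arch_residues <- function(arch) {
  seq(arch$first_residue,
      arch$first_residue + nchar(arch$sequence) - 1L)
}

arch_classes <- function(arch) {
  res <- arch_residues(arch)
  cls <- character(length(res))
  for (i in seq_len(nrow(arch$regions))) {
    in_r <- res >= arch$regions$start[i] & res <= arch$regions$end[i]
    cls[in_r] <- arch$regions$class[i]
  }
  cls
}

#' Generate a free-state assigned shift table and peak list
#'
#' Flexible residues receive shifts equal to the random-coil prediction
#' (308 K, pH 6.5) plus small Gaussian noise; structured residues add
#' larger zero-mean offsets emulating a folded domain's dispersion.
#' Offending residues are redrawn until every inter-peak combined
#' separation is at least `min_separation`; in addition, peaks of the
#' planted lost-mode site keep at least `site_clearance` from every
#' surviving peak, and `shifted_clearance` from peaks that will be
#' displaced in the bound state (and those from each other), so
#' lost-peak detection at a radius up to `site_clearance` and
#' weak-perturbation calls on generated data are exactly decidable.
#' The peak list mirrors the table with unit heights. Fully
#' reproducible from the architecture's seed.
#'
#' @param arch A [make_dkk4_like()] architecture.
#' @param min_separation Global minimum combined-shift separation
#'   between any two peaks (ppm).
#' @param site_clearance Minimum separation between lost-site peaks
#'   and surviving peaks (ppm); lost-peak detection is exact for radii
#'   up to this value.
#' @param shifted_clearance Minimum separation between lost-site peaks
#'   and to-be-displaced peaks, and among the displaced peaks (ppm);
#'   must exceed `site_clearance` by the maximum planted displacement.
#' @param alpha 15N scaling of the separation metric.
#' @param max_rounds Redraw budget before giving up.
#' @return A list: `shifts` ([shift_table()]), `peaks` ([peaklist()]),
#'   `truth` (per-residue class and planted site).
#' @export
generate_free_state <- function(arch, min_separation = 0.05,
                                site_clearance = 0.15,
                                shifted_clearance = 0.25, alpha = 0.2,
                                max_rounds = 20000) {
  set.seed(arch$seed)
  res <- arch_residues(arch)
  aa <- strsplit(arch$sequence, "")[[1]]
  cls <- arch_classes(arch)
  base <- predict_random_coil(arch$sequence, temperature = 308, pH = 6.5,
                              first_residue = arch$first_residue)
  n <- length(res)
  sd_H <- ifelse(cls == "flexible", arch$flex_sd[["H"]],
                 arch$struct_sd[["H"]])
  sd_N <- ifelse(cls == "flexible", arch$flex_sd[["N"]],
                 arch$struct_sd[["N"]])
  H <- base$H + rnorm(n, 0, sd_H)
  N <- base$N + rnorm(n, 0, sd_N)
  obs <- !is.na(H) & !is.na(N) # prolines stay missing
  # separation requirement per pair: stricter when a lost-site peak is
  # involved (makes planted losses unambiguous at the default radius)
  in_site <- res %in% arch$site_lost
  round_i <- 0L
  repeat {
    round_i <- round_i + 1L
    io <- which(obs)
    P <- cbind(H[io], N[io] * alpha)
    d <- as.matrix(stats::dist(P))
    diag(d) <- Inf
    req <- matrix(min_separation, length(io), length(io))
    site_rows <- in_site[io]
    shifted_rows <- res[io] %in% arch$site_shifted
    # lost-site peaks must stand clear of every *surviving* peak (the
    # site peaks themselves all vanish in the bound state, so site-site
    # proximity is harmless); peaks that will be displaced in the bound
    # state need extra clearance covering their maximum displacement
    req[site_rows, !site_rows] <- site_clearance
    req[!site_rows, site_rows] <- site_clearance
    req[site_rows, shifted_rows] <- shifted_clearance
    req[shifted_rows, site_rows] <- shifted_clearance
    req[shifted_rows, shifted_rows] <- shifted_clearance
    diag(req) <- 0
    bad <- which(apply(d < req, 1, any))
    if (length(bad) == 0) break
    if (round_i > max_rounds) {
      abort("Could not satisfy peak-separation guarantee; try a smaller system or looser separation.")
    }
    redo <- io[bad]
    H[redo] <- base$H[redo] + rnorm(length(redo), 0, sd_H[redo])
    N[redo] <- base$N[redo] + rnorm(length(redo), 0, sd_N[redo])
  }
  shifts <- shift_table(tibble(residue = res, aa = aa, H = H, N = N))
  peaks <- suppressWarnings(
    shifts_to_peaklist(shifts, heights = 1, source_label = "free"))
  truth <- list(residue = res, class = cls,
                site_lost = arch$site_lost,
                site_shifted = arch$site_shifted,
                secondary_H = H - base$H, secondary_N = N - base$N)
  list(shifts = shifts, peaks = peaks, truth = truth)
}

#' Generate a bound-state peak list with a planted binding site
#'
#' Starting from the free-state peaks: peaks of lost-mode site residues
#' are removed (tight complex, signals broadened out); shifted-mode
#' residues are displaced by a combined shift drawn uniformly from
#' `shift_range` in a random direction; all other peaks are unchanged.
#'
#' @param arch A [make_dkk4_like()] architecture.
#' @param free Output of [generate_free_state()].
#' @param shift_range Range (ppm, combined units) of planted weak
#'   perturbations.
#' @param alpha 15N scaling used to convert a combined displacement
#'   into H/N components.
#' @param seed Seed for the displacement draws; default derived from
#'   the architecture seed.
#' @return A list: `peaks` (bound-state [peaklist()]), `truth`
#'   (planted per-residue true combined shifts and lost flags).
#' @export
generate_bound_state <- function(arch, free, shift_range = c(0.04, 0.10),
                                 alpha = 0.2, seed = arch$seed + 1L) {
  set.seed(seed)
  pk <- as_tibble(free$peaks)
  pk$residue <- free$shifts$residue[match(
    pk$label, sprintf("%s%dN-H", free$shifts$aa, free$shifts$residue))]
  keep <- !pk$residue %in% arch$site_lost
  pk <- pk[keep, ]
  true_shift <- setNames(rep(0, nrow(pk)), pk$residue)
  sel <- pk$residue %in% arch$site_shifted
  m <- runif(sum(sel), shift_range[1], shift_range[2])
  theta <- runif(sum(sel), 0, 2 * pi)
  pk$w2[sel] <- pk$w2[sel] + m * cos(theta)           # 1H component
  pk$w1[sel] <- pk$w1[sel] + m * sin(theta) / alpha   # 15N component
  true_shift[sel] <- m
  bound <- peaklist(pk[, c("label", "w1", "w2", "height")],
                    source_label = "bound")
  list(peaks = bound,
       truth = list(residue = pk$residue, true_shift = unname(true_shift),
                    lost = sort(intersect(arch$site_lost,
                                          free$shifts$residue[
                                            !is.na(free$shifts$H)]))))
}

#' Generate paired saturated/reference peak lists for het-NOE analysis
#'
#' Reference heights are drawn around 1e6; saturated heights apply a
#' per-residue intensity ratio drawn from `Normal(0.8, 0.05)` for
#' structured residues and `Normal(0.2, 0.1)` for flexible ones.
#'
#' @param arch A [make_dkk4_like()] architecture.
#' @param free Output of [generate_free_state()]; supplies the peak
#'   positions.
#' @param seed Seed; default derived from the architecture seed.
#' @return A list: `sat`, `ref` ([peaklist()]s), `truth` (per-residue
#'   class and true ratio).
#' @export
generate_hetnoe_pairs <- function(arch, free, seed = arch$seed + 2L) {
  set.seed(seed)
  sh <- free$shifts
  obs <- !is.na(sh$H) & !is.na(sh$N)
  cls <- arch_classes(arch)[obs]
  n <- sum(obs)
  I_o <- 1e6 * runif(n, 0.8, 1.2)
  ratio <- ifelse(cls == "structured", rnorm(n, 0.8, 0.05),
                  rnorm(n, 0.2, 0.10))
  labs <- sprintf("%s%dN-H", sh$aa[obs], sh$residue[obs])
  ref <- peaklist(tibble(label = labs, w1 = sh$N[obs], w2 = sh$H[obs],
                         height = I_o), source_label = "no_presat")
  sat <- peaklist(tibble(label = labs, w1 = sh$N[obs], w2 = sh$H[obs],
                         height = I_o * ratio), source_label = "presat")
  list(sat = sat, ref = ref,
       truth = list(residue = sh$residue[obs], class = cls, ratio = ratio))
}

#' Generate a noisy steady-state binding curve
#'
#' Responses follow [one_site_response()] with additive Gaussian noise.
#'
#' @param KD,Rmax Ground-truth parameters (molar, nm).
#' @param conc_M Concentration series, molar.
#' @param sigma Gaussian response noise (nm).
#' @param seed Optional seed.
#' @param analyte_label Label stored on the curve.
#' @return A [binding_curve()] tibble; ground truth in
#'   `attr(x, "truth")`.
#' @export
generate_binding_curve <- function(KD, Rmax, conc_M, sigma = 0,
                                   seed = NULL, analyte_label = NULL) {
  if (sigma < 0) abort("`sigma` must be >= 0.")
  if (!is.null(seed)) set.seed(seed)
  resp <- one_site_response(conc_M, KD, Rmax) +
    (if (sigma > 0) rnorm(length(conc_M), 0, sigma) else 0)
  out <- binding_curve(tibble(conc_M = conc_M, response_nm = resp),
                       analyte_label = analyte_label)
  attr(out, "truth") <- list(KD = KD, Rmax = Rmax, sigma = sigma)
  out
}

#' Generate a jittered coordinate ensemble
#'
#' Replicates a single-model template `n_models` times and adds iid
#' Gaussian noise to every coordinate, then rounds to the standard PDB
#' precision (0.001 A) so written files round-trip exactly.
#'
#' @param template A single-model [coord_ensemble()].
#' @param sigma Coordinate jitter (A) per axis.
#' @param n_models Number of models.
#' @param seed Optional seed.
#' @return A [coord_ensemble()] with `n_models` models.
#' @export
generate_ensemble <- function(template, sigma, n_models, seed = NULL) {
  if (sigma < 0) abort("`sigma` must be >= 0.")
  if (!is.null(seed)) set.seed(seed)
  one <- as_tibble(template[template$model == template$model[1], ])
  models <- map(seq_len(n_models), function(m) {
    jit <- one
    jit$model <- m
    jit$x <- round(jit$x + rnorm(nrow(one), 0, sigma), 3)
    jit$y <- round(jit$y + rnorm(nrow(one), 0, sigma), 3)
    jit$z <- round(jit$z + rnorm(nrow(one), 0, sigma), 3)
    jit
  })
  coord_ensemble(bind_rows(models))
}

#' Idealized helical backbone template
#'
#' A synthetic stand-in structure: a regular alpha-helical backbone
#' (N, CA, C, O per residue) built from ideal helix parameters (rise
#' 1.5 A per residue, 100 degree twist, CA radius 2.3 A). Useful as a
#' template for [generate_ensemble()] and superposition tests.
#'
#' @param n_res Number of residues.
#' @param chain Chain ID.
#' @param first_residue Number of the first residue.
#' @return A single-model [coord_ensemble()].
#' @export
make_helix_template <- function(n_res = 30, chain = "A",
                                first_residue = 1L) {
  rise <- 1.5; twist <- 100 * pi / 180
  atom_off <- list(N = c(r = 1.8, dth = -0.45, dz = -0.8),
                   CA = c(r = 2.3, dth = 0, dz = 0),
                   C = c(r = 2.0, dth = 0.40, dz = 0.7),
                   O = c(r = 3.1, dth = 0.55, dz = 0.8))
  rows <- list()
  for (i in seq_len(n_res)) {
    th <- (i - 1) * twist
    z0 <- (i - 1) * rise
    for (at in names(atom_off)) {
      o <- atom_off[[at]]
      rows[[length(rows) + 1L]] <- tibble(
        model = 1L, chain = chain,
        resno = first_residue + i - 1L, resid = "ALA", elety = at,
        x = round(o[["r"]] * cos(th + o[["dth"]]), 3),
        y = round(o[["r"]] * sin(th + o[["dth"]]), 3),
        z = round(z0 + o[["dz"]], 3))
    }
  }
  coord_ensemble(bind_rows(rows))
}
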