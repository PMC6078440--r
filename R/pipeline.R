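write_tsv_plain <- function(df, path) {
  utils::write.table(as.data.frame(df), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Free-state structure and dynamics characterization
#'
#' Runs the free-state workflow end to end: combined secondary shifts
#' against the random-coil reference, segmentation into structured and
#' flexible regions, optionally a heteronuclear NOE profile with its own
#' flexibility classification, and a consensus segmentation. The
#' consensus calls a residue flexible only where both analyses agree;
#' disagreements resolve conservatively to structured and are flagged.
#'
#' @param shifts [shift_table()] of observed free-state shifts covering
#'   the full (contiguous) chain.
#' @param sat,ref Optional saturated/reference [peaklist()]s for the
#'   het-NOE analysis.
#' @param temperature,pH Conditions for the random-coil reference.
#' @param alpha Combined-shift scaling factor.
#' @param window,threshold,min_len Segmentation parameters, see
#'   [segment_regions()].
#' @param noe_cutoff Flexibility cutoff for [classify_flexible()];
#'   `NULL` uses the convention default.
#' @param convention het-NOE convention, see [het_noe()].
#' @param noise_s,noise_o Spectral noise estimates for the NOE errors.
#' @param out_dir If non-`NULL`, per-residue TSVs and a JSON summary
#'   are written there (deterministic content, no timestamps).
#' @return A list of class `"free_state_report"`: `profile`,
#'   `shift_segments`, `noe_profile` (or `NULL`), `noe_segments` (or
#'   `NULL`), `consensus` (per-residue tibble), `consensus_segments`.
#' @export
run_free_state <- function(shifts, sat = NULL, ref = NULL,
                           temperature = 308, pH = 6.5, alpha = 0.2,
                           window = 5, threshold = 0.1, min_len = 4,
                           noe_cutoff = NULL,
                           convention = c("ratio", "difference"),
                           noise_s = 0, noise_o = 0, out_dir = NULL) {
  convention <- match.arg(convention)
  sequence <- paste(shifts$aa, collapse = "")
  reference <- predict_random_coil(sequence, temperature = temperature,
                                   pH = pH,
                                   first_residue = shifts$residue[1])
  profile <- secondary_shift_profile(shifts, reference, alpha = alpha)
  shift_seg <- segment_regions(profile, window = window,
                               threshold = threshold, min_len = min_len)
  noe_profile <- NULL
  noe_seg <- NULL
  if (!is.null(sat) && !is.null(ref)) {
    noe_profile <- het_noe_profile(sat, ref, shifts, noise_s = noise_s,
                                   noise_o = noise_o, alpha = alpha,
                                   convention = convention)
    noe_seg <- classify_flexible(noe_profile, cutoff = noe_cutoff,
                                 min_len = min_len)
  }
  shift_lab <- attr(shift_seg, "residue_labels")
  consensus <- tibble(residue = shift_lab$residue,
                      shift_label = shift_lab$label)
  if (!is.null(noe_seg)) {
    noe_lab <- attr(noe_seg, "residue_labels")
    consensus$noe_label <-
      noe_lab$label[match(consensus$residue, noe_lab$residue)]
    both <- !is.na(consensus$noe_label)
    consensus$consensus <- consensus$shift_label
    consensus$consensus[both] <-
      ifelse(consensus$shift_label[both] == "flexible" &
               consensus$noe_label[both] == "flexible",
             "flexible", "structured")
    consensus$disagreement <- both &
      consensus$shift_label != consensus$noe_label
  } else {
    consensus$noe_label <- NA_character_
    consensus$consensus <- consensus$shift_label
    consensus$disagreement <- FALSE
  }
  cons_seg <- merge_short_segments(
    labels_to_segments(consensus$residue, consensus$consensus), min_len)
  out <- structure(list(profile = profile, shift_segments = shift_seg,
                        noe_profile = noe_profile, noe_segments = noe_seg,
                        consensus = consensus,
                        consensus_segments = cons_seg),
                   class = "free_state_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    prof_out <- as_tibble(profile)
    prof_out$label <- shift_lab$label
    write_tsv_plain(prof_out, file.path(out_dir, "secondary_shifts.tsv"))
    if (!is.null(noe_profile)) {
      write_tsv_plain(noe_profile, file.path(out_dir, "het_noe.tsv"))
    }
    write_tsv_plain(consensus, file.path(out_dir, "consensus.tsv"))
    summary <- list(
      n_residues = nrow(profile),
      n_assigned = sum(!profile$missing),
      het_noe_present = !is.null(noe_profile),
      flexible_regions = as.data.frame(
        cons_seg[cons_seg$label == "flexible", c("start", "end")]),
      structured_regions = as.data.frame(
        cons_seg[cons_seg$label == "structured", c("start", "end")]),
      parameters = list(alpha = alpha, window = window,
                        threshold = threshold, min_len = min_len,
                        convention = convention))
    jsonlite::write_json(summary, file.path(out_dir, "free_state.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  out
}

#' Free-vs-bound chemical-shift-perturbation workflow
#'
#' Minimal-shift mapping of an assigned free state against an
#' unassigned bound-state peak list, lost-peak detection, and a
#' binding-site report grouped by chain segment.
#'
#' @param shifts Free-state [shift_table()].
#' @param bound Bound-state [peaklist()].
#' @param segments A `"segment_labeling"` of the free chain (e.g. from
#'   [run_free_state()]); used to annotate the report.
#' @param alpha Combined-shift scaling factor.
#' @param lost_radius Lost-peak radius (ppm), see
#'   [detect_lost_peaks()].
#' @param height_floor Optional intensity floor for lost-peak calls.
#' @param shift_threshold Weak-perturbation threshold (ppm).
#' @param min_run Minimum lost-run length for a tight site.
#' @param out_dir Optional output directory (per-residue TSV + JSON
#'   site report).
#' @return A list of class `"csp_report"`: `profile`
#'   (per-residue minimal shifts with lost flags), `sites`
#'   ([infer_binding_regions()] output).
#' @export
run_csp <- function(shifts, bound, segments, alpha = 0.2,
                    lost_radius = 0.25, height_floor = NULL,
                    shift_threshold = 0.04, min_run = 5,
                    out_dir = NULL) {
  profile <- minimal_shift_map(shifts, bound, alpha = alpha,
                               lost_radius = lost_radius,
                               height_floor = height_floor)
  sites <- infer_binding_regions(profile, segments,
                                 shift_threshold = shift_threshold,
                                 min_run = min_run)
  out <- structure(list(profile = profile, sites = sites),
                   class = "csp_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv_plain(profile, file.path(out_dir, "minimal_shifts.tsv"))
    jsonlite::write_json(
      list(parameters = list(alpha = alpha, lost_radius = lost_radius,
                             shift_threshold = shift_threshold,
                             min_run = min_run),
           sites = as.data.frame(sites)),
      file.path(out_dir, "binding_sites.json"),
      auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  out
}

#' Affinity determination across analytes
#'
#' Fits the one-site steady-state model to each supplied binding curve
#' and tabulates the results (analyte, KD, standard error), mirroring a
#' biosensor KD summary table.
#'
#' @param curves A named list of [binding_curve()]s (names are analyte
#'   labels) or a single curve.
#' @param out_dir Optional output directory (TSV fit table).
#' @param ... Passed to [fit_one_site()].
#' @return A tibble: `analyte`, `KD_M`, `KD_se_M`, `Rmax_nm`,
#'   `Rmax_se_nm`, `rss`, `n`.
#' @export
run_affinity <- function(curves, out_dir = NULL, ...) {
  if (inherits(curves, "binding_curve")) curves <- list(curves)
  if (is.null(names(curves))) {
    names(curves) <- vapply(curves, function(c) {
      attr(c, "analyte_label") %||% NA_character_
    }, character(1))
  }
  rows <- map(seq_along(curves), function(i) {
    f <- fit_one_site(curves[[i]], ...)
    tibble(analyte = names(curves)[i] %||% NA_character_,
           KD_M = f$KD, KD_se_M = f$KD_se, Rmax_nm = f$Rmax,
           Rmax_se_nm = f$Rmax_se, rss = f$rss, n = f$n)
  })
  out <- bind_rows(rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv_plain(out, file.path(out_dir, "affinity_fits.tsv"))
  }
  out
}
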