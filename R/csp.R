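#' Minimal-shift chemical-shift-perturbation map
#'
#' For each assigned residue of the free-state protein, the smallest
#' combined shift between its free amide peak and any peak of the
#' (unassigned) bound-state spectrum. Because the true bound-state
#' partner is unknown, this is a lower bound on the real perturbation:
#' the defining property of the minimal-shift approach. Ties are broken
#' toward the lower bound-peak index.
#'
#' @param free [shift_table()] of assigned free-state shifts.
#' @param bound [peaklist()] of the bound-state spectrum (unassigned).
#' @param alpha 15N scaling factor of the combined-shift metric.
#' @param lost_radius If non-`NULL`, residues with no bound peak within
#'   this combined-shift radius (see [detect_lost_peaks()]) are flagged
#'   lost and carry no `min_shift`.
#' @param height_floor Optional intensity floor passed to
#'   [detect_lost_peaks()].
#' @return A tibble of class `"minimal_shift_profile"`: `residue`,
#'   `aa`, `min_shift`, `bound_peak` (matched index), `lost`. Per-peak
#'   match counts are in `attr(x, "bound_match_counts")`.
#' @export
minimal_shift_map <- function(free, bound, alpha = 0.2,
                              lost_radius = NULL, height_floor = NULL) {
  if (nrow(bound) == 0) abort("Bound-state peak list is empty.")
  assigned <- free[!is.na(free$H) & !is.na(free$N), ]
  if (nrow(assigned) == 0) abort("Free table has no assigned residues.")
  # all residue x peak combined shifts (residues in rows)
  dH <- outer(assigned$H, bound$w2, "-")
  dN <- outer(assigned$N, bound$w1, "-")
  d <- sqrt(dH^2 + (dN * alpha)^2)
  best <- apply(d, 1, which.min)
  out <- tibble(residue = assigned$residue, aa = assigned$aa,
                min_shift = d[cbind(seq_len(nrow(d)), best)],
                bound_peak = as.integer(best), lost = FALSE)
  if (!is.null(lost_radius)) {
    lostf <- detect_lost_peaks(assigned, bound, radius = lost_radius,
                               height_floor = height_floor, alpha = alpha)
    out$lost <- lostf$lost[match(out$residue, lostf$residue)]
    out$min_shift[out$lost] <- NA_real_
    out$bound_peak[out$lost] <- NA_integer_
  }
  counts <- tabulate(out$bound_peak[!out$lost], nbins = nrow(bound))
  structure(out, alpha = alpha, bound_match_counts = counts,
            class = c("minimal_shift_profile", class(out)))
}

#' Detect free-state peaks lost from a bound-state spectrum
#'
#' A residue's signal is "lost" when no bound-state peak lies within
#' `radius` of its free-state position (combined-shift metric) - and,
#' when peak heights are available and `height_floor` is given, when no
#' peak within the radius exceeds the floor. Domain-scale runs of lost
#' residues are the fingerprint of a large, tightly associated complex
#' whose signals broaden beyond detection.
#'
#' @param free [shift_table()] of assigned free-state shifts.
#' @param bound [peaklist()] of the bound-state spectrum.
#' @param radius Combined-shift radius in ppm (> 0).
#' @param height_floor Optional minimum height for a peak to count as
#'   observed.
#' @param alpha 15N scaling factor.
#' @return A tibble: `residue`, `lost`.
#' @export
detect_lost_peaks <- function(free, bound, radius = 0.25,
                              height_floor = NULL, alpha = 0.2) {
  if (radius <= 0) abort("`radius` must be > 0.")
  assigned <- free[!is.na(free$H) & !is.na(free$N), ]
  lost <- vapply(seq_len(nrow(assigned)), function(i) {
    d <- combined_shift(assigned$H[i] - bound$w2,
                        assigned$N[i] - bound$w1, alpha)
    near <- which(d <= radius)
    if (length(near) == 0) return(TRUE)
    if (!is.null(height_floor) && !all(is.na(bound$height[near]))) {
      return(!any(bound$height[near] > height_floor, na.rm = TRUE))
    }
    FALSE
  }, logical(1))
  tibble(residue = assigned$residue, lost = lost)
}

contiguous_runs <- function(residues) {
  if (length(residues) == 0) return(tibble(start = integer(), end = integer()))
  residues <- sort(residues)
  grp <- cumsum(c(1L, diff(residues) != 1L))
  tibble(start = tapply(residues, grp, min)[],
         end = tapply(residues, grp, max)[]) |>
    mutate(start = as.integer(.data$start), end = as.integer(.data$end))
}

overlapping_segments <- function(seg, start, end) {
  hit <- seg$start <= end & seg$end >= start
  paste(sprintf("%s(%d-%d)", seg$label[hit], seg$start[hit], seg$end[hit]),
        collapse = ",")
}

#' Infer binding regions from a minimal-shift profile
#'
#' Interprets a minimal-shift profile in the light of a
#' structured/flexible segmentation: contiguous runs of lost residues of
#' at least `min_run` residues are labeled tight interaction sites
#' (signals broadened out by formation of a large, slowly tumbling
#' complex); shorter lost runs are reported as isolated losses, not
#' sites; observable residues whose minimal shift exceeds
#' `shift_threshold` are labeled weak/transient perturbations.
#'
#' @param profile A [minimal_shift_map()] result with lost flags.
#' @param segments A `"segment_labeling"` on the same residue frame.
#' @param shift_threshold Minimal combined shift (ppm) calling a weak
#'   perturbation.
#' @param min_run Minimum lost-run length (residues) for a tight site.
#' @return A tibble of class `"binding_report"`: `type` (`tight_site`,
#'   `weak_perturbation`, `isolated_loss`), `start`, `end`,
#'   `n_residues`, `segments` (overlapped segment labels). Zero rows
#'   when nothing is perturbed.
#' @export
infer_binding_regions <- function(profile, segments,
                                  shift_threshold = 0.04, min_run = 5) {
  lost_runs <- contiguous_runs(profile$residue[profile$lost])
  lost_runs$type <- ifelse(lost_runs$end - lost_runs$start + 1 >= min_run,
                           "tight_site", "isolated_loss")
  shifted <- profile$residue[!profile$lost &
                               !is.na(profile$min_shift) &
                               profile$min_shift > shift_threshold]
  shift_runs <- contiguous_runs(shifted)
  if (nrow(shift_runs) > 0) shift_runs$type <- "weak_perturbation"
  out <- bind_rows(lost_runs, shift_runs)
  if (nrow(out) == 0) {
    out <- tibble(type = character(), start = integer(), end = integer(),
                  n_residues = integer(), segments = character())
    return(structure(out, class = c("binding_report", class(out))))
  }
  out <- arrange(out, .data$start)
  out$n_residues <- out$end - out$start + 1L
  out$segments <- vapply(seq_len(nrow(out)), function(i) {
    overlapping_segments(segments, out$start[i], out$end[i])
  }, character(1))
  out <- out[, c("type", "start", "end", "n_residues", "segments")]
  structure(out, shift_threshold = shift_threshold, min_run = min_run,
            class = c("binding_report", class(out)))
}
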