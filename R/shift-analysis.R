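#' Combined amide chemical-shift difference
#'
#' Merges amide proton and nitrogen shift differences into a single
#' scalar: `sqrt(d_HN^2 + (d_N * alpha)^2)`. The scaling factor `alpha`
#' (default 0.2) compensates for the wider 15N ppm range relative to
#' 1HN.
#'
#' @param d_HN Amide proton shift difference(s), ppm.
#' @param d_N Amide nitrogen shift difference(s), ppm.
#' @param alpha 15N scaling factor, in (0, 1].
#' @return Combined shift(s), ppm (non-negative); vectorized.
#' @examples
#' combined_shift(0.30, 1.00) # 0.3606
#' @export
combined_shift <- function(d_HN, d_N, alpha = 0.2) {
  if (alpha <= 0 || alpha > 1) abort("`alpha` must be in (0, 1].")
  sqrt(d_HN^2 + (d_N * alpha)^2)
}

#' Per-residue combined secondary chemical shifts
#'
#' Subtracts a random-coil reference from observed backbone amide shifts
#' and reports per-residue differences and their absolute combined
#' value. Residues unassigned in the observed table (including
#' prolines) are flagged missing.
#'
#' @param observed [shift_table()] of observed shifts.
#' @param reference [shift_table()] of random-coil reference shifts;
#'   must cover every observed residue (typically
#'   [predict_random_coil()] output).
#' @param alpha 15N scaling factor for the combined value.
#' @return A tibble of class `"secondary_shift_profile"`: `residue`,
#'   `aa`, `d_HN`, `d_N`, `combined`, `missing`.
#' @export
secondary_shift_profile <- function(observed, reference, alpha = 0.2) {
  not_covered <- setdiff(observed$residue, reference$residue)
  if (length(not_covered) > 0) {
    abort(sprintf("Reference lacks residue(s): %s",
                  paste(not_covered, collapse = ", ")))
  }
  ref <- reference[match(observed$residue, reference$residue), ]
  mismatch <- which(ref$aa != observed$aa)
  if (length(mismatch) > 0) {
    abort(sprintf("Residue type mismatch at residue(s): %s",
                  paste(observed$residue[mismatch], collapse = ", ")))
  }
  out <- tibble(residue = observed$residue,
                aa = observed$aa,
                d_HN = observed$H - ref$H,
                d_N = observed$N - ref$N)
  out$combined <- combined_shift(out$d_HN, out$d_N, alpha)
  out$missing <- is.na(out$combined)
  structure(out, alpha = alpha,
            class = c("secondary_shift_profile", class(out)))
}

running_median <- function(v, window) {
  half <- (window - 1) %/% 2
  n <- length(v)
  vapply(seq_len(n), function(i) {
    w <- v[max(1, i - half):min(n, i + half)]
    stats::median(w, na.rm = TRUE)
  }, numeric(1))
}

# nearest non-missing label; ties broken toward the preceding residue
inherit_labels <- function(labels) {
  ok <- which(!is.na(labels))
  if (length(ok) == 0) abort("No labeled residues to inherit from.")
  vapply(seq_along(labels), function(i) {
    if (!is.na(labels[[i]])) return(labels[[i]])
    d <- abs(ok - i)
    cand <- ok[d == min(d)]
    labels[[max(cand[cand < i], cand[1])]]
  }, character(1))
}

# run-length segments from per-residue labels
labels_to_segments <- function(residue, label) {
  r <- rle(label)
  end_i <- cumsum(r$lengths)
  start_i <- end_i - r$lengths + 1
  tibble(start = residue[start_i], end = residue[end_i], label = r$values)
}

# merge segments shorter than min_len into the longer flanking segment
# (tie -> preceding); deterministic: shortest first, then earliest
merge_short_segments <- function(seg, min_len) {
  repeat {
    len <- seg$end - seg$start + 1
    small <- which(len < min_len)
    if (length(small) == 0 || nrow(seg) == 1) break
    i <- small[order(len[small], small)][1]
    if (i == 1) {
      target <- 2
    } else if (i == nrow(seg)) {
      target <- i - 1
    } else {
      target <- if (len[i + 1] > len[i - 1]) i + 1 else i - 1
    }
    seg$label[i] <- seg$label[target]
    # coalesce adjacent equal labels
    keep <- c(TRUE, seg$label[-1] != seg$label[-nrow(seg)])
    grp <- cumsum(keep)
    seg <- seg |>
      mutate(grp = grp) |>
      group_by(.data$grp) |>
      summarise(start = min(.data$start), end = max(.data$end),
                label = .data$label[1], .groups = "drop") |>
      select("start", "end", "label")
  }
  seg
}

new_segment_labeling <- function(seg, residue_labels, params) {
  structure(as_tibble(seg), residue_labels = residue_labels,
            params = params,
            class = c("segment_labeling", class(as_tibble(seg))))
}

#' Segment a chain into structured and flexible regions
#'
#' Labels each residue by thresholding a running median of the combined
#' secondary shift: residues whose windowed median exceeds `threshold`
#' are structured (shifted away from random coil), the rest flexible.
#' Missing residues (prolines, unassigned) inherit the label of the
#' nearest assigned neighbor (tie: preceding), so contiguous domains are
#' not broken by isolated gaps. Segments shorter than `min_len` are
#' merged into the longer flanking segment.
#'
#' @param profile A [secondary_shift_profile()].
#' @param window Odd window length (residues) for the running median.
#' @param threshold Combined-shift threshold (ppm) separating structured
#'   from flexible.
#' @param min_len Minimum segment length retained (residues).
#' @return A tibble of class `"segment_labeling"` with columns `start`,
#'   `end`, `label`; per-residue labels are in
#'   `attr(x, "residue_labels")`.
#' @export
segment_regions <- function(profile, window = 5, threshold = 0.1,
                            min_len = 4) {
  if (window < 1 || window %% 2 == 0) abort("`window` must be odd, >= 1.")
  if (threshold <= 0) abort("`threshold` must be > 0.")
  if (min_len < 1) abort("`min_len` must be >= 1.")
  profile <- arrange(as_tibble(profile), .data$residue)
  if (nrow(profile) < window) {
    abort("Profile is shorter than the smoothing window.")
  }
  med <- running_median(profile$combined, window)
  lab <- ifelse(is.na(profile$combined), NA_character_,
                ifelse(med > threshold, "structured", "flexible"))
  lab <- inherit_labels(lab)
  seg <- labels_to_segments(profile$residue, lab)
  seg <- merge_short_segments(seg, min_len)
  # refresh per-residue labels after merging
  lab_final <- seg$label[findInterval(profile$residue, seg$start)]
  new_segment_labeling(
    seg,
    residue_labels = tibble(residue = profile$residue, label = lab_final),
    params = list(window = window, threshold = threshold,
                  min_len = min_len, source = "secondary_shift"))
}
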