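#' Heteronuclear 15N{1H}-NOE from paired peak heights
#'
#' Computes the steady-state heteronuclear NOE for backbone amide
#' signals from heights measured with (`I_s`) and without (`I_o`)
#' proton presaturation. Two conventions are offered: `"ratio"`
#' (`I_s / I_o`, rigid limit about 0.8 at high field) and
#' `"difference"` (`(I_s - I_o) / I_o`, i.e. ratio minus one).
#' Uncertainty is first-order propagation of the spectral noise:
#' `|I_s/I_o| * sqrt((noise_s/I_s)^2 + (noise_o/I_o)^2)` (identical in
#' both conventions).
#'
#' @param I_s Peak height(s) with presaturation.
#' @param I_o Peak height(s) without presaturation (reference); must be
#'   nonzero.
#' @param noise_s,noise_o Spectral noise estimates (standard deviation
#'   of heights in an empty region), same units as the heights.
#' @param convention `"ratio"` or `"difference"`.
#' @return A tibble: `noe`, `sigma`, `unreliable` (`TRUE` where
#'   `|I_o| < 3 * noise_o`).
#' @examples
#' het_noe(0.8e6, 1.0e6, convention = "difference") # noe -0.2
#' @export
het_noe <- function(I_s, I_o, noise_s = 0, noise_o = 0,
                    convention = c("ratio", "difference")) {
  convention <- match.arg(convention)
  if (any(noise_s < 0) || any(noise_o < 0)) {
    abort("Noise estimates must be >= 0.")
  }
  if (any(I_o == 0)) {
    abort("Reference height I_o = 0: NOE undefined for that record.")
  }
  ratio <- I_s / I_o
  noe <- if (convention == "ratio") ratio else ratio - 1
  sigma <- abs(ratio) * sqrt((noise_s / I_s)^2 + (noise_o / I_o)^2)
  sigma[I_s == 0 & noise_s == 0] <- abs(noise_o / I_o)[I_s == 0 & noise_s == 0]
  tibble(noe = noe, sigma = sigma, unreliable = abs(I_o) < 3 * noise_o)
}

#' Per-residue heteronuclear NOE profile from paired spectra
#'
#' Pairs peaks of the saturated and reference spectra with assigned
#' residues by nearest position (combined-shift metric) within
#' `radius`, then computes the NOE per paired residue. Residues with no
#' peak within radius in either spectrum are reported as unpaired
#' (`attr(x, "unpaired")`); residues with more than one candidate peak
#' are kept but flagged `"ambiguous"` rather than silently resolved.
#'
#' @param sat [peaklist()] recorded with presaturation.
#' @param ref [peaklist()] recorded without presaturation.
#' @param pairing [shift_table()] giving the assigned free-state
#'   position of each residue.
#' @param noise_s,noise_o Spectral noise estimates.
#' @param radius Matching radius in combined-shift ppm.
#' @param alpha 15N scaling factor of the matching metric.
#' @param convention NOE convention, see [het_noe()].
#' @return A tibble of class `"hetnoe_profile"`: `residue`, `I_s`,
#'   `I_o`, `noe`, `sigma`, `flag`.
#' @export
het_noe_profile <- function(sat, ref, pairing, noise_s = 0, noise_o = 0,
                            radius = 0.05, alpha = 0.2,
                            convention = c("ratio", "difference")) {
  convention <- match.arg(convention)
  assigned <- pairing[!is.na(pairing$H) & !is.na(pairing$N), ]
  rows <- list()
  unpaired <- integer()
  for (i in seq_len(nrow(assigned))) {
    dist_s <- combined_shift(assigned$H[i] - sat$w2,
                             assigned$N[i] - sat$w1, alpha)
    dist_r <- combined_shift(assigned$H[i] - ref$w2,
                             assigned$N[i] - ref$w1, alpha)
    hit_s <- which(dist_s <= radius)
    hit_r <- which(dist_r <= radius)
    if (length(hit_s) == 0 || length(hit_r) == 0) {
      unpaired <- c(unpaired, assigned$residue[i])
      next
    }
    flag <- if (length(hit_s) > 1 || length(hit_r) > 1) "ambiguous" else "ok"
    hs <- hit_s[order(dist_s[hit_s])][1]
    hr <- hit_r[order(dist_r[hit_r])][1]
    rows[[length(rows) + 1L]] <- tibble(residue = assigned$residue[i],
                                        I_s = sat$height[hs],
                                        I_o = ref$height[hr],
                                        flag = flag)
  }
  if (length(rows) == 0) abort("No residues could be paired with peaks.")
  out <- bind_rows(rows)
  vals <- het_noe(out$I_s, out$I_o, noise_s, noise_o, convention)
  out$noe <- vals$noe
  out$sigma <- vals$sigma
  out$flag[vals$unreliable] <- "unreliable"
  out <- out[, c("residue", "I_s", "I_o", "noe", "sigma", "flag")]
  structure(out, convention = convention, unpaired = unpaired,
            class = c("hetnoe_profile", class(out)))
}

#' Classify flexible regions from heteronuclear NOE records
#'
#' Residues whose NOE falls below `cutoff` are flexible; gaps between
#' measured residues inherit the nearest neighbor's label (tie:
#' preceding) and segments shorter than `min_len` are merged into the
#' longer flanking segment, as in [segment_regions()].
#'
#' @param records A [het_noe_profile()] result (or any tibble with
#'   `residue` and `noe`).
#' @param cutoff Flexibility cutoff; default 0.6 in the ratio
#'   convention, -0.4 in the difference convention.
#' @param min_len Minimum segment length retained.
#' @return A `"segment_labeling"` tibble.
#' @export
classify_flexible <- function(records, cutoff = NULL, min_len = 4) {
  if (nrow(records) == 0) abort("Empty heteronuclear NOE record set.")
  convention <- attr(records, "convention") %||% "ratio"
  cutoff <- cutoff %||% (if (convention == "ratio") 0.6 else -0.4)
  records <- arrange(as_tibble(records), .data$residue)
  span <- seq(min(records$residue), max(records$residue))
  lab <- rep(NA_character_, length(span))
  lab[match(records$residue, span)] <-
    ifelse(records$noe < cutoff, "flexible", "structured")
  lab <- inherit_labels(lab)
  seg <- merge_short_segments(labels_to_segments(span, lab), min_len)
  lab_final <- seg$label[findInterval(span, seg$start)]
  new_segment_labeling(
    seg, residue_labels = tibble(residue = span, label = lab_final),
    params = list(cutoff = cutoff, min_len = min_len,
                  convention = convention, source = "het_noe"))
}
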