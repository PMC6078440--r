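#' Plot a combined secondary-shift profile
#'
#' Per-residue bar chart of the absolute combined secondary shift with
#' the segmentation threshold overlaid when supplied.
#'
#' @param object A [secondary_shift_profile()].
#' @param threshold Optional horizontal reference line (ppm).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot secondary_shift_profile
#' @export
autoplot.secondary_shift_profile <- function(object, threshold = NULL,
                                             ...) {
  p <- ggplot(as_tibble(object), aes(x = .data$residue,
                                     y = .data$combined)) +
    geom_col(width = 1, na.rm = TRUE) +
    labs(x = "Residue", y = "Combined secondary shift (ppm)") +
    theme_bw()
  if (!is.null(threshold)) {
    p <- p + geom_hline(yintercept = threshold, linetype = "dashed")
  }
  p
}

#' Plot a heteronuclear NOE profile
#'
#' @param object A [het_noe_profile()].
#' @param cutoff Optional flexibility cutoff line.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hetnoe_profile
#' @export
autoplot.hetnoe_profile <- function(object, cutoff = NULL, ...) {
  df <- as_tibble(object)
  p <- ggplot(df, aes(x = .data$residue, y = .data$noe)) +
    geom_point(size = 0.8) +
    geom_errorbar(aes(ymin = .data$noe - .data$sigma,
                      ymax = .data$noe + .data$sigma),
                  width = 0, color = "red") +
    labs(x = "Residue",
         y = sprintf("15N{1H}-NOE (%s)",
                     attr(object, "convention") %||% "ratio")) +
    theme_bw()
  if (!is.null(cutoff)) {
    p <- p + geom_hline(yintercept = cutoff, linetype = "dashed")
  }
  p
}

#' Plot a minimal-shift perturbation profile
#'
#' Lost residues (no observable bound-state signal) are drawn at a
#' sentinel ceiling value and highlighted, matching common practice for
#' perturbation histograms; observable residues show their minimal
#' combined shift.
#'
#' @param object A [minimal_shift_map()] result.
#' @param lost_ceiling Bar height used to mark lost residues.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot minimal_shift_profile
#' @export
autoplot.minimal_shift_profile <- function(object, lost_ceiling = NULL,
                                           ...) {
  df <- as_tibble(object)
  if (is.null(lost_ceiling)) {
    lost_ceiling <- 1.1 * max(df$min_shift, na.rm = TRUE)
  }
  df$value <- ifelse(df$lost, lost_ceiling, df$min_shift)
  ggplot(df, aes(x = .data$residue, y = .data$value,
                 fill = .data$lost)) +
    geom_col(width = 1, na.rm = TRUE, show.legend = TRUE) +
    labs(x = "Residue", y = "Minimal combined shift (ppm)",
         fill = "Lost") +
    theme_bw()
}

#' Plot a one-site binding fit
#'
#' Observed steady-state responses on a log concentration axis with the
#' fitted isotherm overlaid.
#'
#' @param object A [fit_one_site()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot one_site_fit
#' @export
autoplot.one_site_fit <- function(object, ...) {
  df <- object$data[object$data$conc_M > 0, ]
  grid <- tibble(conc_M = exp(seq(log(min(df$conc_M)),
                                  log(max(df$conc_M)),
                                  length.out = 100)))
  grid$response_nm <- one_site_response(grid$conc_M, object$KD,
                                        object$Rmax)
  ggplot(df, aes(x = .data$conc_M, y = .data$response_nm)) +
    geom_point() +
    geom_line(data = grid) +
    scale_x_log10() +
    labs(x = "Concentration (M)", y = "Response (nm)") +
    theme_bw()
}
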