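#' One-site steady-state binding response
#'
#' The equilibrium binding isotherm `Req = Rmax * C / (KD + C)`:
#' monotone increasing in the analyte concentration `C`, half-saturated
#' at `C = KD`, and approaching `Rmax` as `C` grows.
#'
#' @param conc Analyte concentration(s), molar; >= 0.
#' @param KD Equilibrium dissociation constant, molar; > 0.
#' @param Rmax Saturating response, nm; > 0.
#' @return Response(s) in nm, vectorized over `conc`.
#' @examples
#' one_site_response(300e-9, KD = 100e-9, Rmax = 1) # 0.75
#' @export
one_site_response <- function(conc, KD, Rmax) {
  if (KD <= 0 || Rmax <= 0) abort("`KD` and `Rmax` must be > 0.")
  if (any(conc < 0)) abort("Concentrations must be >= 0.")
  Rmax * conc / (KD + conc)
}

#' Fit a one-site binding model to a steady-state curve
#'
#' Nonlinear least squares on `Req = Rmax * C / (KD + C)` against
#' steady-state biosensor responses. Initialization: `Rmax0` is 1.1x
#' the maximum observed response and `KD0` the concentration at half of
#' the maximum response (linearly interpolated). Standard errors come
#' from the curvature of the residual surface at the optimum. With
#' `fix_Rmax`, only `KD` floats.
#'
#' @param curve A [binding_curve()] (or data frame with `conc_M`,
#'   `response_nm`); at least 3 distinct nonzero concentrations.
#' @param init Optional named list/vector with starting values `KD`,
#'   `Rmax` (molar / nm).
#' @param fix_Rmax Optional fixed `Rmax` (nm); default both parameters
#'   float.
#' @return An object of class `"one_site_fit"`; see [tidy()] and
#'   [glance()] methods. Fields: `KD`, `Rmax`, `KD_se`, `Rmax_se`,
#'   `rss`, `n`, `poorly_constrained`, `fit` (the underlying `nls`
#'   object, fitted with concentrations normalized by their maximum so
#'   results are unit-invariant) and `data`.
#' @export
fit_one_site <- function(curve, init = NULL, fix_Rmax = NULL) {
  df <- as_tibble(curve)[, c("conc_M", "response_nm")]
  if (!all(is.finite(df$response_nm))) abort("Responses must be finite.")
  nz <- unique(df$conc_M[df$conc_M > 0])
  if (length(nz) < 3) {
    abort("At least 3 distinct nonzero concentrations are required.")
  }
  if (all(df$response_nm == 0)) {
    abort("All responses are zero: one-site fit is degenerate.")
  }
  rmax0 <- if (!is.null(init) && !is.null(init[["Rmax"]])) {
    init[["Rmax"]]
  } else {
    1.1 * max(df$response_nm)
  }
  kd0 <- if (!is.null(init) && !is.null(init[["KD"]])) {
    init[["KD"]]
  } else {
    half <- max(df$response_nm) / 2
    ord <- order(df$conc_M)
    est <- suppressWarnings(
      approx(df$response_nm[ord], df$conc_M[ord], xout = half,
             ties = mean)$y)
    if (is.na(est) || est <= 0) est <- stats::median(nz)
    est
  }
  ctrl <- minpack.lm::nls.lm.control(ftol = 1e-10, ptol = 1e-10,
                                     maxiter = 500)
  # fit in normalized concentration units so the optimizer (and hence
  # the result) is invariant to the unit the curve was supplied in
  cscale <- max(df$conc_M)
  dfs <- tibble(conc_s = df$conc_M / cscale,
                response_nm = df$response_nm)
  fit <- tryCatch({
    if (is.null(fix_Rmax)) {
      minpack.lm::nlsLM(response_nm ~ Rmax * conc_s / (KD + conc_s),
                        data = dfs,
                        start = list(KD = kd0 / cscale, Rmax = rmax0),
                        lower = c(KD = .Machine$double.xmin, Rmax = 0),
                        control = ctrl)
    } else {
      minpack.lm::nlsLM(response_nm ~ fix_Rmax * conc_s / (KD + conc_s),
                        data = dfs, start = list(KD = kd0 / cscale),
                        lower = c(KD = .Machine$double.xmin),
                        control = ctrl)
    }
  }, error = function(e) {
    abort(sprintf("One-site fit failed to converge: %s (KD0 = %.3g, Rmax0 = %.3g)",
                  conditionMessage(e), kd0, rmax0))
  })
  est <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) {
    setNames(rep(NA_real_, length(est)), names(est))
  })
  est[["KD"]] <- est[["KD"]] * cscale
  if ("KD" %in% names(se)) se[["KD"]] <- se[["KD"]] * cscale
  kd <- est[["KD"]]
  rmax <- if (is.null(fix_Rmax)) est[["Rmax"]] else fix_Rmax
  poorly <- max(df$conc_M) < kd / 10
  if (poorly) {
    warn("Fit poorly constrained: maximum concentration is far below the fitted KD.")
  }
  structure(list(KD = kd, Rmax = rmax,
                 KD_se = se[["KD"]],
                 Rmax_se = if (is.null(fix_Rmax)) se[["Rmax"]] else NA_real_,
                 rss = sum(stats::resid(fit)^2), n = nrow(df),
                 poorly_constrained = poorly,
                 Rmax_fixed = !is.null(fix_Rmax),
                 fit = fit, data = df,
                 analyte_label = attr(curve, "analyte_label") %||%
                   NA_character_),
            class = "one_site_fit")
}

#' @export
print.one_site_fit <- function(x, ...) {
  cat("One-site steady-state binding fit\n")
  if (!is.na(x$analyte_label)) cat("  analyte:", x$analyte_label, "\n")
  cat(sprintf("  KD   = %.4g M (SE %.3g)%s\n", x$KD, x$KD_se,
              if (x$poorly_constrained) "  [poorly constrained]" else ""))
  cat(sprintf("  Rmax = %.4g nm%s (SE %.3g)\n", x$Rmax,
              if (x$Rmax_fixed) " [fixed]" else "", x$Rmax_se))
  cat(sprintf("  RSS  = %.4g over %d points\n", x$rss, x$n))
  invisible(x)
}

#' Tidy a one-site binding fit
#'
#' @param x A `"one_site_fit"` object.
#' @param ... Unused.
#' @return A tibble with one row per parameter: `term`, `estimate`,
#'   `std.error`.
#' @method tidy one_site_fit
#' @export
tidy.one_site_fit <- function(x, ...) {
  tibble(term = c("KD", "Rmax"),
         estimate = c(x$KD, x$Rmax),
         std.error = c(x$KD_se, x$Rmax_se))
}

#' One-row summary of a one-site binding fit
#'
#' @param x A `"one_site_fit"` object.
#' @param ... Unused.
#' @return A one-row tibble: `KD`, `KD_se`, `Rmax`, `Rmax_se`, `rss`,
#'   `n`, `poorly_constrained`.
#' @method glance one_site_fit
#' @export
glance.one_site_fit <- function(x, ...) {
  tibble(KD = x$KD, KD_se = x$KD_se, Rmax = x$Rmax, Rmax_se = x$Rmax_se,
         rss = x$rss, n = x$n, poorly_constrained = x$poorly_constrained)
}
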