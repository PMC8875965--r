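#' EC50 estimate container
#'
#' All model EC50s in the package are expressed as the bulk-phase activity
#' of HAsO4^2- (mol/L), following the convention of the underlying BLM.
#'
#' @param value EC50 as HAsO4^2- activity, mol/L (> 0).
#' @param sd Standard deviation, mol/L (>= 0), or `NA`.
#' @param basis One of `"measured"`, `"blm"`, `"blm+psi0"`.
#' @return An object of class `ec_estimate`.
#' @export
ec_estimate <- function(value, sd = NA_real_, basis = c("measured", "blm", "blm+psi0")) {
  basis <- match.arg(basis)
  if (!is.finite(value) || value <= 0) stop("EC50 value must be > 0")
  if (!is.na(sd) && sd < 0) stop("sd must be >= 0")
  structure(list(value = value, sd = sd, basis = basis), class = "ec_estimate")
}

#' @export
print.ec_estimate <- function(x, ...) {
  cat(sprintf("<ec_estimate> %.4g M {HAsO4^2-}%s  [%s]\n", x$value,
              if (is.na(x$sd)) "" else sprintf(" +/- %.3g", x$sd), x$basis))
  invisible(x)
}

#' Environmental modulator (EM) of a medium
#'
#' The medium-specific factor that collects phosphate competition and the
#' pH-dependent partitioning of As(V) over H2AsO4-/HAsO4^2-:
#' \deqn{EM = \frac{1 + K_{XH2PO4}\{H_2PO_4^-\} + K_{XHPO4}\{HPO_4^{2-}\}}
#'              {K_{XH2AsO4}\{H^+\}/K_{As} + K_{XHAsO4}}}
#' in mol/L of HAsO4^2- activity. The site-specific EC50 is the inherent
#' sensitivity times this quantity.
#'
#' @param spec An `as_speciation` object (must contain H, H2PO4, HPO4).
#' @param constants A `blm_constants` object.
#' @return EM in mol/L.
#' @export
#' @examples
#' environmental_modulator(speciate_medium(background_medium()))
environmental_modulator <- function(spec, constants = blm_constants()) {
  a <- activity_of(spec, c("H", "H2PO4", "HPO4"))
  K <- constants
  num <- 1 + 10^K$logK_XH2PO4 * a[["H2PO4"]] + 10^K$logK_XHPO4 * a[["HPO4"]]
  den <- 10^K$logK_XH2AsO4 * a[["H"]] / 10^(-K$pK_As) + 10^K$logK_XHAsO4
  unname(num / den)
}

#' BLM-predicted EC50 from site occupancy
#'
#' \eqn{EC50\{HAsO_4^{2-}\} = \frac{f}{1-f} \times EM}, where f is the
#' fraction of active binding sites occupied by As(V) species at 50%
#' effect.
#'
#' @param f_mix50 Occupancy fraction in (0, 1).
#' @param spec An `as_speciation` object for the medium.
#' @param constants A `blm_constants` object.
#' @return An `ec_estimate` with basis `"blm"`.
#' @export
#' @examples
#' ec50_blm(0.626, speciate_medium(background_medium()))
ec50_blm <- function(f_mix50, spec, constants = blm_constants()) {
  if (!is.finite(f_mix50) || f_mix50 <= 0 || f_mix50 >= 1) {
    stop("f_mix50 must lie strictly inside (0, 1)")
  }
  em <- environmental_modulator(spec, constants)
  ec_estimate(f_mix50 / (1 - f_mix50) * em, basis = "blm")
}

#' Inherent sensitivity from a measured EC50
#'
#' IS = EC50_test / EM_test; the corresponding occupancy is
#' f = IS / (1 + IS). This is the single calibration step of the
#' interspecies extrapolation: one measured EC50 in a chemically
#' characterised medium fixes the species' sensitivity.
#'
#' @param ec50_measured Measured EC50 as HAsO4^2- activity, mol/L.
#' @param em Environmental modulator of the test medium, mol/L.
#' @param species,endpoint Metadata carried into the record.
#' @return A list of class `sensitivity_record` with `species`, `endpoint`,
#'   `f_mix50`, `IS`.
#' @export
#' @examples
#' inherent_sensitivity(45.1e-6, 2.70e-5, "Hordeum vulgare")
inherent_sensitivity <- function(ec50_measured, em,
                                 species = "unknown", endpoint = "unknown") {
  if (ec50_measured <= 0 || em <= 0) stop("ec50 and em must be > 0")
  IS <- ec50_measured / em
  structure(
    list(species = species, endpoint = endpoint,
         f_mix50 = IS / (1 + IS), IS = IS),
    class = "sensitivity_record"
  )
}

#' @export
print.sensitivity_record <- function(x, ...) {
  cat(sprintf("<sensitivity_record> %s (%s): IS = %.4g, f_mix50 = %.4g\n",
              x$species, x$endpoint, x$IS, x$f_mix50))
  invisible(x)
}

#' Site-specific EC50 from inherent sensitivity
#'
#' EC50_site = IS x EM_site. Algebraically identical to [ec50_blm()] for
#' the matching occupancy f = IS/(1+IS).
#'
#' @param sens A `sensitivity_record`.
#' @param em_site Environmental modulator of the target medium, mol/L.
#' @return An `ec_estimate` with basis `"blm"`.
#' @export
predict_ec50_site <- function(sens, em_site) {
  stopifnot(inherits(sens, "sensitivity_record"))
  if (em_site <= 0) stop("em_site must be > 0")
  ec_estimate(sens$IS * em_site, basis = "blm")
}

#' Linear surface-potential correction of a predicted EC50
#'
#' \eqn{EC50_{site} = EC50_{ini} + p(\Psi_{0,site} - \Psi_{0,ini})} with the
#' slope p in uM per mV. A less negative surface potential at the site
#' accumulates more arsenate at the membrane and lowers the EC50 (p < 0).
#' Outside the linear range the affine correction can cross zero; by
#' default the result is floored at `floor_frac` of the initial EC50 with
#' a warning, so extreme extrapolations fail loudly rather than silently
#' returning a non-physical value. Set `floor_frac = NA` to error instead.
#'
#' @param ec50_ini An `ec_estimate` (the BLM prediction at the calibration
#'   conditions).
#' @param slope_uM_per_mV Slope p, uM/mV (see [psi_slope_registry()]).
#' @param psi0_site_mV,psi0_ini_mV Surface potentials, mV.
#' @param floor_frac Lower floor as a fraction of `ec50_ini` (default 0.01),
#'   or `NA` to raise an error on non-positive results.
#' @return An `ec_estimate` with basis `"blm+psi0"`.
#' @export
#' @examples
#' ini <- ec_estimate(45.1e-6, basis = "blm")
#' psi0_adjust(ini, -0.615, psi0_site_mV = -3.3, psi0_ini_mV = -53.8)
psi0_adjust <- function(ec50_ini, slope_uM_per_mV, psi0_site_mV, psi0_ini_mV,
                        floor_frac = 0.01) {
  stopifnot(inherits(ec50_ini, "ec_estimate"))
  adj_uM <- ec50_ini$value * 1e6 +
    slope_uM_per_mV * (psi0_site_mV - psi0_ini_mV)
  if (adj_uM <= 0) {
    if (is.na(floor_frac)) {
      stop(sprintf(
        "psi0 correction drove EC50 to %.3g uM (ini %.3g uM, dPsi0 %.1f mV)",
        adj_uM, ec50_ini$value * 1e6, psi0_site_mV - psi0_ini_mV))
    }
    warning(sprintf(
      "psi0 correction drove EC50 to %.3g uM; flooring at %g%% of the initial value",
      adj_uM, floor_frac * 100))
    adj_uM <- floor_frac * ec50_ini$value * 1e6
  }
  ec_estimate(adj_uM * 1e-6, sd = ec50_ini$sd, basis = "blm+psi0")
}

#' Normalised EC50
#'
#' The measured EC50 divided by the y-axis intercept of the species'
#' Psi0-EC50 regression (its value at Psi0 = 0). Normalisation removes the
#' species-sensitivity scale so that the residual Psi0 dependence is a
#' shared physicochemical property.
#'
#' @param ec50 An `ec_estimate`.
#' @param fit A `psi_slope_fit` from [fit_psi0_slope()] (or any list with a
#'   positive `intercept_uM`).
#' @return Dimensionless normalised EC50.
#' @export
normalized_ec50 <- function(ec50, fit) {
  stopifnot(inherits(ec50, "ec_estimate"))
  if (!is.finite(fit$intercept_uM) || fit$intercept_uM <= 0) {
    stop("normalisation requires a positive fitted intercept")
  }
  ec50$value * 1e6 / fit$intercept_uM
}

#' Fit the linear Psi0-EC50 relationship
#'
#' Ordinary least squares of measured EC50 (uM, HAsO4^2- activity) on the
#' calculated surface potential (mV).
#'
#' @param psi0_mV Numeric vector of surface potentials, mV.
#' @param ec50_uM Numeric vector of EC50 values, uM.
#' @param species Metadata label.
#' @return An object of class `psi_slope_fit`: list with `species`,
#'   `slope_uM_per_mV`, `intercept_uM`, `r_squared`, `n`.
#' @export
#' @examples
#' fit_psi0_slope(c(-53.8, -30, -3.3), c(45.1, 30, 15))
fit_psi0_slope <- function(psi0_mV, ec50_uM, species = "unknown") {
  if (length(psi0_mV) != length(ec50_uM)) stop("input lengths differ")
  if (length(psi0_mV) < 3) stop("at least 3 points are required")
  if (length(unique(psi0_mV)) < 2) stop("psi0 values are degenerate")
  fit <- stats::lm(ec50_uM ~ psi0_mV)
  # R^2 computed directly so that exactly collinear input is handled
  # without the "perfect fit" warning from summary.lm
  tss <- sum((ec50_uM - mean(ec50_uM))^2)
  r2 <- if (tss > 0) 1 - sum(stats::residuals(fit)^2) / tss else NA_real_
  structure(
    list(
      species = species,
      slope_uM_per_mV = unname(stats::coef(fit)[2]),
      intercept_uM = unname(stats::coef(fit)[1]),
      r_squared = r2,
      n = length(psi0_mV)
    ),
    class = "psi_slope_fit"
  )
}

#' @export
print.psi_slope_fit <- function(x, ...) {
  cat(sprintf(
    "<psi_slope_fit> %s: EC50 = %.4g %+.4g * Psi0  (uM, mV; R2 = %.3f, n = %d)\n",
    x$species, x$intercept_uM, x$slope_uM_per_mV, x$r_squared, x$n))
  invisible(x)
}
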