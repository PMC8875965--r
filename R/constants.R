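#' Physical constants for membrane electrostatics
#'
#' Faraday constant, gas constant, default absolute temperature, and the
#' lumped Graham-equation coefficient \eqn{2 \epsilon_r \epsilon_0 R T}.
#' The coefficient equals 0.00345 when bulk concentrations are expressed in
#' mol/L at 25 degrees C, and all equilibrium constants in the package are
#' 25 degrees C values, so the default temperature is 298.15 K throughout.
#'
#' @return A list with elements `F` (C/mol), `R_gas` (J mol^-1 K^-1),
#'   `T` (K) and `graham_coefficient` (dimensioned so that sigma^2 comes out
#'   in (C/m^2)^2 with concentrations in mol/L).
#' @export
#' @examples
#' phys_constants()$F
phys_constants <- function() {
  list(F = 96485, R_gas = 8.314, T = 298.15, graham_coefficient = 0.00345)
}

# Thermal voltage RT/F in volts at the default temperature.
rt_over_f <- function(const = phys_constants()) const$R_gas * const$T / const$F

#' Acid dissociation constants for arsenate and phosphate
#'
#' Stepwise pKa values (25 degrees C, infinite dilution) for the two
#' triprotic oxyanion systems handled by the speciation engine. The second
#' arsenate step is fixed at pKa = 6.76, the conditional value used by the
#' arsenate BLM; the remaining steps are standard critical-compilation
#' values (NIST 46: arsenic acid 2.24 / 11.60, phosphoric acid
#' 2.148 / 7.198 / 12.35).
#'
#' @param acid `"arsenate"` or `"phosphate"`.
#' @return Numeric vector of three strictly increasing pKa values.
#' @export
#' @examples
#' acidity_constants("arsenate")
acidity_constants <- function(acid = c("arsenate", "phosphate")) {
  acid <- match.arg(acid)
  pka <- switch(acid,
    arsenate  = c(2.24, 6.76, 11.60),
    phosphate = c(2.148, 7.198, 12.35)
  )
  stopifnot(all(diff(pka) > 0))
  pka
}

#' Conditional BLM binding constants for As(V) and phosphate
#'
#' The conditional constants for H2AsO4-, HAsO4^2-, H2PO4- and HPO4^2-
#' binding to the active binding site X of the cell membrane, together with
#' the conditional acid dissociation constant of As(V) (pK_As = 6.76).
#' These were derived from Aliivibrio fischeri bioluminescence-inhibition
#' assays and are shared across species under the interspecies-extrapolation
#' assumption: only the inherent sensitivity differs between organisms.
#'
#' @return An object of class `blm_constants`: a list with `logK_XH2AsO4`,
#'   `logK_XHAsO4`, `logK_XH2PO4`, `logK_XHPO4` (log10 L/mol) and `pK_As`.
#' @export
#' @examples
#' blm_constants()
blm_constants <- function() {
  structure(
    list(
      logK_XH2AsO4 = 3.067,
      logK_XHAsO4  = 4.802,
      logK_XH2PO4  = 3.424,
      logK_XHPO4   = 4.588,
      pK_As        = 6.76
    ),
    class = "blm_constants"
  )
}

#' @export
print.blm_constants <- function(x, ...) {
  cat("Conditional BLM binding constants (log10 L/mol):\n")
  cat(sprintf("  X-H2AsO4: %.3f   X-HAsO4: %.3f\n", x$logK_XH2AsO4, x$logK_XHAsO4))
  cat(sprintf("  X-H2PO4:  %.3f   X-HPO4:  %.3f\n", x$logK_XH2PO4, x$logK_XHPO4))
  cat(sprintf("  pK_As: %.2f\n", x$pK_As))
  invisible(x)
}

#' Published surface-potential / EC50 regression constants
#'
#' Read-only registry of the published linear relationships between the
#' membrane surface potential Psi0 (mV) and the measured EC50 expressed as
#' HAsO4^2- activity (uM). The per-calcium EC50 points behind these fits are
#' only available graphically, so the fitted constants are consumed as
#' published values rather than re-derived. The `normalized` row is the
#' common species-independent slope of EC50 divided by the fit's y-axis
#' intercept (per mV). Intercepts were not published and are `NA`; use
#' [fit_psi0_slope()] on your own data when an intercept is needed.
#'
#' @return A data.frame with columns `species`, `slope` (uM/mV; per mV for
#'   the normalized row), `intercept_uM` and `r_squared`.
#' @export
#' @examples
#' psi_slope_registry()
psi_slope_registry <- function() {
  data.frame(
    species      = c("Hordeum vulgare", "Triticum aestivum", "normalized"),
    slope        = c(-0.615, -0.003, -0.055),
    intercept_uM = c(NA_real_, NA_real_, NA_real_),
    r_squared    = c(0.771, 0.729, 0.742),
    stringsAsFactors = FALSE
  )
}

#' Inherent-sensitivity registry
#'
#' The fraction of active binding sites that must be occupied by As(V)
#' species to produce a 50% effect (`f_mix50`), per species and toxic
#' endpoint, with the derived inherent sensitivity IS = f/(1-f).
#'
#' @return A data.frame with columns `species`, `endpoint`, `f_mix50`, `IS`.
#' @export
#' @examples
#' sensitivity_registry()
sensitivity_registry <- function() {
  f <- c(0.616, 0.626, 0.015)
  data.frame(
    species  = c("Aliivibrio fischeri", "Hordeum vulgare", "Triticum aestivum"),
    endpoint = c("5 min bioluminescence inhibition",
                 "5 d relative root elongation",
                 "2 d relative root elongation"),
    f_mix50  = f,
    IS       = f / (1 - f),
    stringsAsFactors = FALSE
  )
}

#' Measured barley EC50 anchors across the calcium ladder
#'
#' Published EC50 values (HAsO4^2- activity) for Hordeum vulgare root
#' elongation at the two calcium extremes of the hydroponic test series.
#' These measured values are inputs for calibration and for
#' measured-vs-predicted comparisons; the intermediate calcium levels were
#' only published graphically.
#'
#' @return A data.frame with columns `ca_mM`, `ec50_uM`, `sd_uM`.
#' @export
#' @examples
#' measured_ec50_registry()
measured_ec50_registry <- function() {
  data.frame(
    ca_mM   = c(0.2, 20),
    ec50_uM = c(45.1, 15.0),
    sd_uM   = c(4.34, 2.60)
  )
}
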