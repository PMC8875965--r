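#' Speciate every medium in a CSV
#'
#' Thin orchestration over [read_medium_csv()], [speciate_medium()] and
#' [write_speciation_csv()]: outputs are identical to direct module calls.
#'
#' @param media_csv Input media CSV path.
#' @param out_csv Output CSV path (optional).
#' @return A list of `as_speciation` objects, invisibly if writing.
#' @export
run_speciate <- function(media_csv, out_csv = NULL) {
  specs <- lapply(read_medium_csv(media_csv), speciate_medium)
  if (!is.null(out_csv)) {
    write_speciation_csv(specs, out_csv)
    return(invisible(specs))
  }
  specs
}

#' Solve the surface potential for every medium in a CSV
#'
#' @param media_csv Input media CSV path.
#' @param params_file Optional YAML membrane-parameter file; defaults to
#'   the vendored calibrated set.
#' @param out_csv Output CSV path (optional).
#' @return A list of `membrane_state` objects, invisibly if writing.
#' @export
run_psi0 <- function(media_csv, params_file = NULL, out_csv = NULL) {
  params <- if (is.null(params_file)) default_membrane_params()
            else read_membrane_params(params_file)
  states <- lapply(read_medium_csv(media_csv), function(m)
    solve_psi0(speciate_medium(m), params))
  if (!is.null(out_csv)) {
    write_membrane_csv(states, out_csv)
    return(invisible(states))
  }
  states
}

#' Fit dose-response curves and extract EC50s from an assay table
#'
#' Computes RRE per calcium level, fits the logistic curve on ln HAsO4^2-
#' activity (activities computed by the speciation engine from the medium
#' recipe), and reports EC50s with bootstrap uncertainty.
#'
#' @param root_length_csv Assay-table CSV (see [read_root_length_csv()]).
#' @param out_csv Output CSV path (optional).
#' @param n_boot Bootstrap draws for the EC50 sd.
#' @return A data.frame `ca_mM, ec50_M, ec50_sd_M`.
#' @export
run_fit_ec50 <- function(root_length_csv, out_csv = NULL, n_boot = 1000) {
  rl <- read_root_length_csv(root_length_csv)
  if (is.null(rl$ca_mM)) stop("assay table needs a 'ca_mM' column")
  acts <- dose_activity_map(unique(rl$ca_mM), sort(unique(rl$as_total_uM)))
  out <- recover_ec50s(rl, acts, n_boot = n_boot)
  if (!is.null(out_csv)) utils::write.csv(out, out_csv, row.names = FALSE)
  out
}

#' HAsO4^2- activity for every (calcium, dose) combination
#'
#' @param ca_mM Calcium levels, mM.
#' @param as_doses_uM As(V) doses, uM.
#' @return A data.frame `ca_mM, as_total_uM, hasO4_activity_M` (NA at the
#'   zero dose).
#' @export
dose_activity_map <- function(ca_mM, as_doses_uM) {
  do.call(rbind, lapply(ca_mM, function(ca) {
    acts <- vapply(as_doses_uM, function(d) {
      if (d == 0) return(NA_real_)
      activity_of(speciate_medium(background_medium(ca_mM = ca, as_uM = d)),
                  "HAsO4")[[1]]
    }, numeric(1))
    data.frame(ca_mM = ca, as_total_uM = as_doses_uM, hasO4_activity_M = acts)
  }))
}

#' Calibrate the inherent sensitivity from a reference medium
#'
#' The single calibration step of the interspecies extrapolation: the
#' measured EC50 (HAsO4^2- activity) in a chemically characterised
#' reference medium is divided by that medium's computed environmental
#' modulator to give IS and the occupancy f.
#'
#' @param ec50_measured_M Measured EC50, mol/L HAsO4^2- activity.
#' @param ref_medium An `as_medium` (default: the 0.2 mM Ca background
#'   medium).
#' @param constants A `blm_constants` object.
#' @param species,endpoint Metadata.
#' @return A `sensitivity_record`.
#' @export
#' @examples
#' run_calibrate(45.1e-6, species = "Hordeum vulgare")
run_calibrate <- function(ec50_measured_M, ref_medium = background_medium(),
                          constants = blm_constants(),
                          species = "unknown", endpoint = "unknown") {
  em <- environmental_modulator(speciate_medium(ref_medium), constants)
  inherent_sensitivity(ec50_measured_M, em, species = species,
                       endpoint = endpoint)
}

#' Predict site-specific EC50s with the Psi0 correction
#'
#' For each site medium: EC50_ini = IS x EM_site, then the linear Psi0
#' shift relative to the calibration medium. When measured EC50s are
#' supplied the output includes the log10 prediction ratio and a flag for
#' agreement within one order of magnitude.
#'
#' @param sens A `sensitivity_record`.
#' @param site_media List of `as_medium` objects.
#' @param slope_uM_per_mV Psi0-EC50 slope (uM/mV).
#' @param ref_medium Calibration medium (defines Psi0_ini).
#' @param params A `membrane_params` object.
#' @param constants A `blm_constants` object.
#' @param measured_M Optional numeric vector of measured EC50s (mol/L),
#'   one per site medium.
#' @param out_csv Optional output CSV path.
#' @return A data.frame `label, em_M, psi0_mV, ec50_blm_M,
#'   ec50_adjusted_M, basis` plus `measured_M, log10_ratio,
#'   within_order_of_magnitude` when measurements are given.
#' @export
run_predict <- function(sens, site_media, slope_uM_per_mV,
                        ref_medium = background_medium(),
                        params = default_membrane_params(),
                        constants = blm_constants(),
                        measured_M = NULL, out_csv = NULL) {
  stopifnot(inherits(sens, "sensitivity_record"))
  if (inherits(site_media, "as_medium")) site_media <- list(site_media)
  psi_ini <- solve_psi0(speciate_medium(ref_medium), params)$psi0_mV
  rows <- lapply(site_media, function(m) {
    sp <- speciate_medium(m)
    em <- environmental_modulator(sp, constants)
    psi <- solve_psi0(sp, params)$psi0_mV
    ini <- predict_ec50_site(sens, em)
    adj <- psi0_adjust(ini, slope_uM_per_mV, psi0_site_mV = psi,
                       psi0_ini_mV = psi_ini)
    data.frame(label = m$label, em_M = em, psi0_mV = psi,
               ec50_blm_M = ini$value, ec50_adjusted_M = adj$value,
               basis = adj$basis)
  })
  out <- do.call(rbind, rows)
  if (!is.null(measured_M)) {
    stopifnot(length(measured_M) == nrow(out))
    out$measured_M <- measured_M
    out$log10_ratio <- log10(out$ec50_adjusted_M / measured_M)
    out$within_order_of_magnitude <- abs(out$log10_ratio) <= 1
  }
  if (!is.null(out_csv)) utils::write.csv(out, out_csv, row.names = FALSE)
  out
}

#' Recompute the package's reference quantities
#'
#' Runs the full chain on the vendored medium definitions and parameter
#' set and returns a computed-vs-reference table for the headline numbers:
#' the environmental modulator of the background medium, the barley
#' inherent sensitivity, the four surface-potential anchors, the fold
#' decrease of the measured EC50 across the calcium ladder, and the
#' Psi0-corrected EC50 prediction at 20 mM Ca.
#'
#' @param params A `membrane_params` object.
#' @param constants A `blm_constants` object.
#' @return A data.frame `quantity, units, computed, reference`.
#' @export
#' @examples
#' \donttest{reproduce_anchors()}
reproduce_anchors <- function(params = default_membrane_params(),
                              constants = blm_constants()) {
  sp_lo <- speciate_medium(background_medium(ca_mM = 0.2))
  sp_hi <- speciate_medium(background_medium(ca_mM = 20))
  sp_af0 <- speciate_medium(fischeri_medium(ca_mM = 0))
  sp_af25 <- speciate_medium(fischeri_medium(ca_mM = 25))
  em <- environmental_modulator(sp_lo, constants)
  anchors <- measured_ec50_registry()
  ec50_lo <- anchors$ec50_uM[anchors$ca_mM == 0.2] * 1e-6
  ec50_hi <- anchors$ec50_uM[anchors$ca_mM == 20] * 1e-6
  sens <- inherent_sensitivity(ec50_lo, em, species = "Hordeum vulgare")
  psi_lo <- solve_psi0(sp_lo, params)$psi0_mV
  psi_hi <- solve_psi0(sp_hi, params)$psi0_mV
  psi_af0 <- solve_psi0(sp_af0, params)$psi0_mV
  psi_af25 <- solve_psi0(sp_af25, params)$psi0_mV
  slope <- psi_slope_registry()
  p_hv <- slope$slope[slope$species == "Hordeum vulgare"]
  adj <- psi0_adjust(ec_estimate(ec50_lo, basis = "blm"), p_hv,
                     psi0_site_mV = psi_hi, psi0_ini_mV = psi_lo)
  data.frame(
    quantity = c("EM (background medium)", "IS (H. vulgare)",
                 "f_mix50 (H. vulgare)",
                 "psi0 (plant, 0.2 mM Ca)", "psi0 (plant, 20 mM Ca)",
                 "psi0 (0.342 M NaCl, 0 Ca)", "psi0 (0.342 M NaCl, 25 mM Ca)",
                 "EC50 fold decrease (measured)",
                 "EC50 at 20 mM Ca, psi0-corrected"),
    units = c("mol/L", "-", "-", "mV", "mV", "mV", "mV", "-", "uM"),
    computed = c(em, sens$IS, sens$f_mix50, psi_lo, psi_hi, psi_af0,
                 psi_af25, ec50_lo / ec50_hi, adj$value * 1e6),
    reference = c(2.70e-5, 1.675, 0.626, -53.8, -3.3, -13.7, -0.4, 3.02, 15.0)
  )
}
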