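#' Configuration for a synthetic root-elongation study
#'
#' Encodes the design of the hydroponic assay: a calcium ladder that moves
#' the membrane surface potential, an As(V) dose series including the
#' control, six seeds per treatment, and additive Gaussian noise on the
#' per-seed elongation scaled so the stated `noise_sd_rre` is the standard
#' deviation in RRE percentage points. Defaults mirror the study design the
#' package models: Ca at 0.2/1/5/10/20 mM and As(V) doses of
#' 0/0.5/2/10/50/200/1000 uM at pH 7.
#'
#' @param seed Integer RNG seed; a fixed seed makes the generated study
#'   bit-identical.
#' @param f_mix50 Injected inherent-sensitivity occupancy (default 0.626,
#'   the barley value).
#' @param psi_slope_uM_per_mV Injected Psi0-EC50 slope (default -0.615).
#' @param ca_ladder_mM Calcium levels, mM.
#' @param as_doses_uM As(V) doses, uM; must include 0 (the control).
#' @param seeds_per_treatment Seeds per treatment (default 6).
#' @param noise_sd_rre Elongation noise, RRE percentage points (default 5).
#' @param control_elongation_mm Mean 5-day control elongation (default 55).
#' @param control_elongation_sd_mm Between-seed SD of control elongation
#'   (default 5).
#' @param initial_length_mm,initial_length_sd_mm Initial root length
#'   distribution (default 6 +/- 0.5 mm).
#' @param shape_b Logistic shape parameter b on the ln-activity axis
#'   (default -0.5; negative for a decreasing response).
#' @return A list of class `sim_config`.
#' @export
simulation_config <- function(seed = 1L,
                              f_mix50 = 0.626,
                              psi_slope_uM_per_mV = -0.615,
                              ca_ladder_mM = c(0.2, 1, 5, 10, 20),
                              as_doses_uM = c(0, 0.5, 2, 10, 50, 200, 1000),
                              seeds_per_treatment = 6L,
                              noise_sd_rre = 5,
                              control_elongation_mm = 55,
                              control_elongation_sd_mm = 5,
                              initial_length_mm = 6,
                              initial_length_sd_mm = 0.5,
                              shape_b = -0.5) {
  if (!0 %in% as_doses_uM) stop("as_doses_uM must include 0 (the control)")
  if (f_mix50 <= 0 || f_mix50 >= 1) stop("f_mix50 must be in (0, 1)")
  if (noise_sd_rre < 0) stop("noise_sd_rre must be >= 0")
  if (shape_b >= 0) stop("shape_b must be negative (decreasing response)")
  structure(as.list(environment()), class = "sim_config")
}

#' Generate a complete synthetic toxicity study
#'
#' For each calcium level the standard background medium is built, its
#' speciation and surface potential computed, and the "true" EC50 assembled
#' from the injected sensitivity (EC50 = IS x EM at that medium) plus the
#' linear Psi0 shift relative to the lowest-calcium (calibration) medium.
#' Per-seed root lengths are then generated so that the expected RRE
#' follows the logistic dose-response in ln HAsO4^2- activity with that
#' true EC50 (y0 = 0, a = 100, b = `shape_b`), with additive Gaussian
#' elongation noise, truncated at zero final elongation. The generator and
#' the estimation pipeline share one forward model by design: simulated
#' studies test the code path, not the biology.
#'
#' @param config A `sim_config`.
#' @param constants A `blm_constants` object.
#' @param params A `membrane_params` object.
#' @return A list of class `sim_study`: `media` (list of `as_medium` for
#'   each Ca x dose), `root_lengths` (data.frame in the assay-table
#'   format), `truth` (data.frame `ca_mM, psi0_mV, em_M, ec50_true_M,
#'   f_mix50, psi_slope_uM_per_mV`), `dose_activities` (data.frame
#'   `ca_mM, as_total_uM, hasO4_activity_M`), and `config`.
#' @export
#' @examples
#' st <- simulate_study(simulation_config(seed = 7, ca_ladder_mM = c(0.2, 20),
#'                                        noise_sd_rre = 0))
#' st$truth
simulate_study <- function(config = simulation_config(),
                           constants = blm_constants(),
                           params = default_membrane_params()) {
  stopifnot(inherits(config, "sim_config"))
  cas <- config$ca_ladder_mM
  doses <- sort(config$as_doses_uM)

  # deterministic forward model per calcium level
  design <- lapply(cas, function(ca) {
    med0 <- background_medium(ca_mM = ca)
    sp0 <- speciate_medium(med0)
    em <- environmental_modulator(sp0, constants)
    psi <- solve_psi0(sp0, params)$psi0_mV
    acts <- vapply(doses, function(d) {
      if (d == 0) return(NA_real_)
      activity_of(speciate_medium(background_medium(ca_mM = ca, as_uM = d)),
                  "HAsO4")[[1]]
    }, numeric(1))
    list(ca = ca, em = em, psi = psi, activities = acts)
  })
  psi_ref <- design[[1]]$psi
  IS <- config$f_mix50 / (1 - config$f_mix50)
  truth <- do.call(rbind, lapply(design, function(d) {
    ec50_ini_uM <- IS * d$em * 1e6
    ec50_uM <- ec50_ini_uM +
      config$psi_slope_uM_per_mV * (d$psi - psi_ref)
    if (ec50_uM <= 0) stop("injected parameters drive the true EC50 <= 0")
    data.frame(ca_mM = d$ca, psi0_mV = d$psi, em_M = d$em,
               ec50_true_M = ec50_uM * 1e-6,
               f_mix50 = config$f_mix50,
               psi_slope_uM_per_mV = config$psi_slope_uM_per_mV)
  }))

  dose_act <- do.call(rbind, lapply(design, function(d) {
    data.frame(ca_mM = d$ca, as_total_uM = doses, hasO4_activity_M = d$activities)
  }))

  # noisy per-seed tables under one seed
  root_lengths <- withr_seed(config$seed, {
    do.call(rbind, lapply(seq_along(design), function(i) {
      d <- design[[i]]
      ec50 <- truth$ec50_true_M[i]
      do.call(rbind, lapply(seq_along(doses), function(j) {
        dose <- doses[j]
        rre_expected <- if (dose == 0) 100 else {
          100 / (1 + exp(-(log(d$activities[j]) - log(ec50)) / config$shape_b))
        }
        n <- config$seeds_per_treatment
        init <- stats::rnorm(n, config$initial_length_mm,
                             config$initial_length_sd_mm)
        # RRE-scale assay noise plus per-seed growth variability that
        # scales with the expected elongation, combined in quadrature
        sd_elong <- sqrt(
          (config$noise_sd_rre / 100 * config$control_elongation_mm)^2 +
            (config$control_elongation_sd_mm * rre_expected / 100)^2
        )
        elong <- rre_expected / 100 * config$control_elongation_mm +
          stats::rnorm(n, 0, sd_elong)
        elong <- pmax(elong, 0)
        data.frame(
          medium_label = sprintf("sim_Ca%g", d$ca),
          ca_mM = d$ca, as_total_uM = dose,
          seed_id = seq_len(n),
          length_initial_mm = round(init, 2),
          length_final_mm = round(init + elong, 2),
          is_control = dose == 0
        )
      }))
    }))
  })

  structure(
    list(media = NULL, root_lengths = root_lengths, truth = truth,
         dose_activities = dose_act, config = config),
    class = "sim_study"
  )
}

#' Recover per-calcium EC50s from a simulated (or real) study table
#'
#' Splits the assay table by calcium level, computes RRE against each
#' level's own control, and fits the logistic dose-response on ln
#' HAsO4^2- activity using the supplied dose-activity map.
#'
#' @param root_lengths Assay table (see [simulate_study()]).
#' @param dose_activities Data.frame `ca_mM, as_total_uM, hasO4_activity_M`.
#' @param n_boot Bootstrap draws for the EC50 sd (0 to skip).
#' @return A data.frame `ca_mM, ec50_M, ec50_sd_M`.
#' @export
recover_ec50s <- function(root_lengths, dose_activities, n_boot = 0) {
  cas <- sort(unique(root_lengths$ca_mM))
  do.call(rbind, lapply(cas, function(ca) {
    d <- root_lengths[root_lengths$ca_mM == ca, ]
    rre <- compute_rre(d)
    rre <- rre[rre$as_total_uM > 0, ]
    act <- dose_activities[dose_activities$ca_mM == ca, ]
    x <- log(act$hasO4_activity_M[match(rre$as_total_uM, act$as_total_uM)])
    fit <- fit_dose_response(x, rre$rre)
    est <- ec50_from_fit(fit, n_boot = n_boot)
    data.frame(ca_mM = ca, ec50_M = est$value, ec50_sd_M = est$sd)
  }))
}

#' Write the three CSV artefacts of a simulated study
#'
#' Emits `<stem>_media.csv` (medium definitions), `<stem>_root_lengths.csv`
#' (assay table) and `<stem>_truth.csv` (truth table).
#'
#' @param study A `sim_study`.
#' @param stem Output path stem.
#' @return Named character vector of the three paths, invisibly.
#' @export
write_sim_study <- function(study, stem) {
  stopifnot(inherits(study, "sim_study"))
  paths <- c(media = paste0(stem, "_media.csv"),
             root_lengths = paste0(stem, "_root_lengths.csv"),
             truth = paste0(stem, "_truth.csv"))
  media <- unlist(lapply(study$truth$ca_mM, function(ca) {
    lapply(study$config$as_doses_uM, function(d)
      background_medium(ca_mM = ca, as_uM = d))
  }), recursive = FALSE)
  write_medium_csv(media, paths[["media"]])
  utils::write.csv(study$root_lengths, paths[["root_lengths"]], row.names = FALSE)
  utils::write.csv(study$truth, paths[["truth"]], row.names = FALSE)
  invisible(paths)
}
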