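# Species table shared by the speciation and membrane stages.
# Charges are formal charges; the oxyanion ladders run from the fully
# protonated neutral acid to the fully deprotonated anion.
.species_charge <- c(
  H = 1, OH = -1, Ca = 2, Mg = 2, K = 1, Na = 1, Cl = -1, NO3 = -1, SO4 = -2,
  H3AsO4 = 0, H2AsO4 = -1, HAsO4 = -2, AsO4 = -3,
  H3PO4 = 0, H2PO4 = -1, HPO4 = -2, PO4 = -3
)

.as_ladder <- c("H3AsO4", "H2AsO4", "HAsO4", "AsO4")
.p_ladder  <- c("H3PO4", "H2PO4", "HPO4", "PO4")

#' First-pass ionic strength of a medium
#'
#' \eqn{I = 1/2 \sum c_i z_i^2} over the dissolved totals, treating the
#' major salts as fully dissociated, distributing the oxyanion totals over
#' their protonation states at the medium pH (infinite-dilution constants on
#' this first pass), and closing the charge balance with Na+ or Cl-. Inside
#' [speciate_medium()] this estimate is refined once with
#' activity-corrected speciation.
#'
#' @param med An `as_medium` object.
#' @return Ionic strength in mol/L.
#' @export
#' @examples
#' ionic_strength(medium("nacl", totals = c(Na = 0.342, Cl = 0.342)))
ionic_strength <- function(med) {
  stopifnot(inherits(med, "as_medium"))
  .speciate_pass(med, I = 0)$I
}

#' Davies single-ion activity coefficient
#'
#' \eqn{\log_{10}\gamma = -A z^2 (\sqrt I/(1+\sqrt I) - 0.3 I)} with
#' A = 0.509 at 25 degrees C. Neutral species get gamma = 1. The Davies
#' model is an empirical extension of Debye-Hueckel theory; above
#' I = 0.5 mol/L it is used outside its nominal validity range and a
#' warning is emitted (the high-salt bacterial medium sits just inside
#' this edge).
#'
#' @param charge Integer formal charge (sign ignored).
#' @param I Ionic strength, mol/L.
#' @return Activity coefficient (dimensionless).
#' @export
#' @examples
#' activity_coefficient(2, 0.01)
activity_coefficient <- function(charge, I) {
  if (any(I < 0)) stop("ionic strength must be >= 0")
  if (any(I > 0.5)) {
    warning("ionic strength ", max(I),
            " mol/L exceeds the Davies validity limit (0.5 mol/L)")
  }
  z <- abs(charge)
  s <- sqrt(I)
  g <- 10^(-0.509 * z^2 * (s / (1 + s) - 0.3 * I))
  g[z == 0 | I == 0] <- 1
  g
}

#' Acid-base speciation of a triprotic oxyanion
#'
#' Distributes a total over the four protonation states by mass action.
#' The tabulated constants are thermodynamic (activity-based); with the
#' activity coefficients supplied per |charge| they are converted to mixed
#' constants, so concentration ratios obey
#' \eqn{c_{j+1}/c_j = K_j \gamma_j / (\gamma_{j+1} \{H^+\})}.
#'
#' @param total Total concentration, mol/L.
#' @param pH Solution pH ({H+} = 10^-pH).
#' @param pKa Three stepwise pKa values (see [acidity_constants()]).
#' @param gamma Activity coefficients for |z| = 0..3 (length-4 vector).
#' @return A data.frame with `species` index 0:3 (protons lost),
#'   `charge`, `concentration_M`, `activity_M`.
#' @export
#' @examples
#' g <- activity_coefficient(0:3, 0.002)
#' speciate_acid(5e-5, 7, acidity_constants("phosphate"), g)
speciate_acid <- function(total, pH, pKa, gamma) {
  stopifnot(length(pKa) == 3, length(gamma) == 4)
  if (total < 0) stop("total must be >= 0")
  aH <- 10^(-pH)
  Ka <- 10^(-pKa)
  r <- Ka * gamma[1:3] / (gamma[2:4] * aH)   # c_{j+1}/c_j
  f <- cumprod(c(1, r))
  conc <- total * f / sum(f)
  data.frame(
    species = 0:3, charge = -(0:3),
    concentration_M = conc, activity_M = conc * gamma
  )
}

# One speciation pass at a given ionic strength: returns concentrations of
# all species, the Na/Cl addition closing the charge balance, and the
# ionic strength recomputed from the speciated composition.
.speciate_pass <- function(med, I) {
  tot <- med$totals
  pH <- med$pH
  gam <- activity_coefficient(0:3, I)
  asr <- speciate_acid(tot[["As"]], pH, acidity_constants("arsenate"), gam)
  pr  <- speciate_acid(tot[["P"]], pH, acidity_constants("phosphate"), gam)
  aH <- 10^(-pH)
  cH <- aH / gam[2]
  cOH <- (1e-14 / aH) / gam[2]
  conc <- c(
    H = cH, OH = cOH,
    Ca = tot[["Ca"]], Mg = tot[["Mg"]], K = tot[["K"]], Na = tot[["Na"]],
    Cl = tot[["Cl"]], NO3 = tot[["NO3"]], SO4 = tot[["SO4"]],
    stats::setNames(asr$concentration_M, .as_ladder),
    stats::setNames(pr$concentration_M, .p_ladder)
  )
  z <- .species_charge[names(conc)]
  net <- sum(conc * z)
  added <- c(Na = 0, Cl = 0)
  if (net < 0) {
    conc[["Na"]] <- conc[["Na"]] - net
    added[["Na"]] <- -net
  } else if (net > 0) {
    conc[["Cl"]] <- conc[["Cl"]] + net
    added[["Cl"]] <- net
  }
  list(conc = conc, z = z, added = added,
       I = 0.5 * sum(conc * z^2))
}

#' Full equilibrium speciation of a medium
#'
#' One-pass ionic strength on the totals, Davies activity coefficients,
#' acid-base speciation of the arsenate and phosphate systems, major ions
#' treated as fully dissociated free ions, then a single refinement cycle
#' of the ionic strength on the speciated composition (a fixed 2-cycle;
#' the compositions handled here are far from the regime where further
#' iteration would move any activity at reportable precision). The charge
#' balance is closed by adding Na+ or Cl- (recorded in the result), which
#' stands in for the counter-ions of the real salts and of pH adjustment.
#' Ion pairing and the carbonate system are deliberately omitted; see the
#' methods vignette for the accuracy implications.
#'
#' @param med An `as_medium` object.
#' @return An object of class `as_speciation`: list with `label`,
#'   `ionic_strength` (mol/L), `gamma` (activity coefficients for
#'   |z| = 0..3), `table` (data.frame `species`, `charge`,
#'   `concentration_M`, `activity_M`), and `counter_ion_added_M`
#'   (named vector, Na/Cl).
#' @export
#' @examples
#' sp <- speciate_medium(background_medium())
#' sp$table[sp$table$species == "HPO4", ]
speciate_medium <- function(med) {
  stopifnot(inherits(med, "as_medium"))
  p1 <- .speciate_pass(med, I = 0)
  p2 <- .speciate_pass(med, I = p1$I)
  p3 <- .speciate_pass(med, I = p2$I)   # second refinement: stabilises gamma
  gam <- activity_coefficient(0:3, p3$I)
  conc <- p3$conc
  z <- p3$z
  act <- conc * gam[abs(z) + 1]
  act[["H"]] <- 10^(-med$pH)            # pH is activity-defined
  structure(
    list(
      label = med$label,
      ionic_strength = p3$I,
      gamma = stats::setNames(gam, 0:3),
      table = data.frame(
        species = names(conc), charge = unname(z),
        concentration_M = unname(conc), activity_M = unname(act),
        row.names = NULL
      ),
      counter_ion_added_M = p3$added
    ),
    class = "as_speciation"
  )
}

#' @export
print.as_speciation <- function(x, ...) {
  cat(sprintf("<as_speciation> %s  I = %.4g mol/L\n", x$label, x$ionic_strength))
  tb <- x$table[x$table$concentration_M > 0, ]
  print(tb, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Look up one species activity (mol/L)
#'
#' @param spec An `as_speciation` object.
#' @param species Species name, e.g. `"HAsO4"`.
#' @return Activity in mol/L.
#' @export
#' @examples
#' activity_of(speciate_medium(background_medium(as_uM = 50)), "HAsO4")
activity_of <- function(spec, species) {
  stopifnot(inherits(spec, "as_speciation"))
  i <- match(species, spec$table$species)
  if (anyNA(i)) stop("unknown species: ", paste(species[is.na(i)], collapse = ", "))
  stats::setNames(spec$table$activity_M[i], species)
}

#' Write speciation results to a long-format CSV
#'
#' Columns `label, ionic_strength_M, species, charge, concentration_M,
#' activity_M`, one block of rows per medium.
#'
#' @param specs A list of `as_speciation` objects (or one).
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_speciation_csv <- function(specs, path) {
  if (inherits(specs, "as_speciation")) specs <- list(specs)
  df <- do.call(rbind, lapply(specs, function(s) {
    cbind(data.frame(label = s$label, ionic_strength_M = s$ionic_strength),
          s$table)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
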