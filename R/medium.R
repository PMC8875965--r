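#' Define a test-medium composition
#'
#' A medium is the total (analytical) dissolved composition of one
#' hydroponic test solution: totals of the major cations and anions, total
#' orthophosphate, total As(V), pH, temperature, and the concentration of a
#' chemically inert pH buffer (MOPS; zwitterionic at pH 7, so it is excluded
#' from the ionic strength).
#'
#' @param label Medium identifier.
#' @param pH Solution pH (0 < pH < 14).
#' @param temp_C Temperature in degrees C (0-40; equilibrium constants are
#'   evaluated at 25 degrees C regardless, see the methods vignette).
#' @param totals Named numeric vector of total concentrations in mol/L.
#'   Recognised names: `Ca`, `Mg`, `K`, `Na`, `Cl`, `NO3`, `SO4`, `P`, `As`.
#'   Missing entries default to 0.
#' @param buffer_M Inert buffer concentration (mol/L).
#' @return An object of class `as_medium`.
#' @export
#' @examples
#' medium("demo", totals = c(Ca = 2e-4, Na = 1e-3))
medium <- function(label = "medium", pH = 7, temp_C = 25,
                   totals = numeric(0), buffer_M = 0) {
  known <- c("Ca", "Mg", "K", "Na", "Cl", "NO3", "SO4", "P", "As")
  tot <- stats::setNames(numeric(length(known)), known)
  if (length(totals)) {
    bad <- setdiff(names(totals), known)
    if (length(bad)) stop("unknown ions in totals: ", paste(bad, collapse = ", "))
    tot[names(totals)] <- as.numeric(totals)
  }
  if (any(tot < 0) || buffer_M < 0) stop("concentrations must be >= 0")
  if (!(pH > 0 && pH < 14)) stop("pH must be in (0, 14)")
  if (temp_C < 0 || temp_C > 40) stop("temperature must be in [0, 40] degrees C")
  structure(
    list(label = label, pH = pH, temp_C = temp_C,
         totals = tot, buffer_M = buffer_M),
    class = "as_medium"
  )
}

#' @export
print.as_medium <- function(x, ...) {
  cat(sprintf("<as_medium> %s  pH %.2f  %.0f degC\n", x$label, x$pH, x$temp_C))
  nz <- x$totals[x$totals > 0]
  if (length(nz)) {
    cat("  totals (mM):",
        paste(sprintf("%s=%.4g", names(nz), nz * 1e3), collapse = "  "), "\n")
  } else cat("  (pure water)\n")
  invisible(x)
}

#' Standard hydroponic background medium
#'
#' The root-elongation test medium: Ca 0.2, Mg 0.05, K 0.2, Na 1, PO4 0.05,
#' SO4 0.05, NO3 0.2 mM at pH 7 in 3.6 mM MOPS, with the calcium level and
#' total As(V) adjustable. Calcium is added as its nitrate-free salt here;
#' charge is closed with Cl-/Na+ automatically at speciation time, which
#' mirrors pH adjustment of the real media with HCl/NaOH.
#'
#' @param ca_mM Total calcium, mM.
#' @param as_uM Total As(V), uM.
#' @param p_mM Total orthophosphate, mM.
#' @param pH Solution pH.
#' @param label Optional label; default encodes Ca and As levels.
#' @return An `as_medium` object.
#' @export
#' @examples
#' background_medium()                 # 0.2 mM Ca, no As
#' background_medium(ca_mM = 20)      # high-calcium end of the ladder
background_medium <- function(ca_mM = 0.2, as_uM = 0, p_mM = 0.05, pH = 7,
                              label = NULL) {
  if (is.null(label)) {
    label <- sprintf("bg_Ca%g_As%g", ca_mM, as_uM)
  }
  medium(
    label = label, pH = pH, temp_C = 20,
    totals = c(Ca = ca_mM * 1e-3, Mg = 0.05e-3, K = 0.2e-3, Na = 1e-3,
               NO3 = 0.2e-3, SO4 = 0.05e-3, P = p_mM * 1e-3,
               As = as_uM * 1e-6),
    buffer_M = 3.6e-3
  )
}

#' Bacterial bioluminescence assay medium
#'
#' The Aliivibrio fischeri osmotic-control medium: 0.342 M NaCl with an
#' adjustable amount of added calcium, pH 7. Used to contrast the weak
#' surface-potential response of a high-salt medium with the plant test
#' medium.
#'
#' @param ca_mM Added calcium, mM.
#' @param as_uM Total As(V), uM.
#' @param label Optional label.
#' @return An `as_medium` object.
#' @export
#' @examples
#' fischeri_medium()
fischeri_medium <- function(ca_mM = 0, as_uM = 0, label = NULL) {
  if (is.null(label)) label <- sprintf("af_Ca%g_As%g", ca_mM, as_uM)
  medium(
    label = label, pH = 7, temp_C = 25,
    totals = c(Na = 0.342, Cl = 0.342, Ca = ca_mM * 1e-3, As = as_uM * 1e-6)
  )
}

#' Read media definitions from CSV
#'
#' One row per medium with columns `label, pH, temp_C, Ca_mM, Mg_mM, K_mM,
#' Na_mM, Cl_mM, NO3_mM, SO4_mM, P_mM, As_uM, buffer_mM`; any missing
#' concentration column is treated as 0. Concentrations are totals.
#'
#' @param path CSV file path.
#' @return A list of `as_medium` objects.
#' @export
read_medium_csv <- function(path) {
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) data.frame())
  if (!nrow(df)) return(list())
  if (is.null(df$label)) stop("medium CSV needs a 'label' column")
  col <- function(name, default = 0) {
    if (is.null(df[[name]])) rep(default, nrow(df)) else df[[name]]
  }
  lapply(seq_len(nrow(df)), function(i) {
    medium(
      label = df$label[i],
      pH = col("pH", 7)[i],
      temp_C = col("temp_C", 25)[i],
      totals = c(c(Ca = col("Ca_mM")[i], Mg = col("Mg_mM")[i],
                   K = col("K_mM")[i], Na = col("Na_mM")[i],
                   Cl = col("Cl_mM")[i], NO3 = col("NO3_mM")[i],
                   SO4 = col("SO4_mM")[i], P = col("P_mM")[i]) * 1e-3,
                 As = col("As_uM")[i] * 1e-6),
      buffer_M = col("buffer_mM")[i] * 1e-3
    )
  })
}

#' Write media definitions to CSV
#'
#' Inverse of [read_medium_csv()].
#'
#' @param media A list of `as_medium` objects (or a single one).
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_medium_csv <- function(media, path) {
  if (inherits(media, "as_medium")) media <- list(media)
  if (!length(media)) {
    empty <- paste(c("label", "pH", "temp_C", "Ca_mM", "Mg_mM", "K_mM",
                     "Na_mM", "Cl_mM", "NO3_mM", "SO4_mM", "P_mM", "As_uM",
                     "buffer_mM"), collapse = ",")
    writeLines(paste0("\"", gsub(",", "\",\"", empty), "\""), path)
    return(invisible(path))
  }
  df <- do.call(rbind, lapply(media, function(m) {
    t <- m$totals
    data.frame(
      label = m$label, pH = m$pH, temp_C = m$temp_C,
      Ca_mM = t[["Ca"]] * 1e3, Mg_mM = t[["Mg"]] * 1e3, K_mM = t[["K"]] * 1e3,
      Na_mM = t[["Na"]] * 1e3, Cl_mM = t[["Cl"]] * 1e3,
      NO3_mM = t[["NO3"]] * 1e3, SO4_mM = t[["SO4"]] * 1e3,
      P_mM = t[["P"]] * 1e3, As_uM = t[["As"]] * 1e6,
      buffer_mM = m$buffer_M * 1e3
    )
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
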