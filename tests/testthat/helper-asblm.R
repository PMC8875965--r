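# Shared fixtures, built in code.

# Memoised speciations of the media used across many tests.
.fixture_env <- new.env(parent = emptyenv())

bg_speciation <- function(ca_mM = 0.2, as_uM = 0) {
  key <- sprintf("bg_%g_%g", ca_mM, as_uM)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- speciate_medium(
      background_medium(ca_mM = ca_mM, as_uM = as_uM))
  }
  .fixture_env[[key]]
}

# A random but plausible hydroponic medium; deterministic per index.
random_medium <- function(i) {
  set.seed(1000 + i)
  medium(
    label = sprintf("rand_%d", i),
    pH = runif(1, 5.5, 8.5),
    totals = c(
      Ca = 10^runif(1, -4.5, -1.7), Mg = 10^runif(1, -5, -3),
      K = 10^runif(1, -4.5, -3), Na = 10^runif(1, -4, -1.5),
      NO3 = 10^runif(1, -4.5, -3), SO4 = 10^runif(1, -5, -3.3),
      P = 10^runif(1, -5.5, -3.8), As = 10^runif(1, -7, -4.5)
    )
  )
}

# Mass balance of one element ladder against its total.
ladder_total <- function(spec, ladder) {
  sum(spec$table$concentration_M[match(ladder, spec$table$species)])
}

as_ladder <- c("H3AsO4", "H2AsO4", "HAsO4", "AsO4")
p_ladder <- c("H3PO4", "H2PO4", "HPO4", "PO4")

# Toy six-seed root-length table with hand-computable means.
toy_root_table <- function() {
  data.frame(
    medium_label = "toy",
    as_total_uM = rep(c(0, 10, 100), each = 2),
    seed_id = rep(1:2, 3),
    length_initial_mm = c(5, 5, 6, 4, 5, 5),
    length_final_mm = c(55, 65, 36, 34, 5, 5),
    is_control = rep(c(TRUE, FALSE, FALSE), each = 2)
  )
}
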