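test_that("ionic strength matches hand-summed oracles", {
  # pure 1:1 electrolyte: I equals the salt concentration
  nacl <- medium("nacl", totals = c(Na = 0.342, Cl = 0.342))
  expect_equal(ionic_strength(nacl), 0.342, tolerance = 1e-5)

  # empty medium: only water autoionisation remains
  expect_lt(ionic_strength(medium("water")), 1e-6)

  # background hydroponic medium: spreadsheet-style 1/2 sum c z^2 over the
  # printed ion table, with phosphate split across H2PO4-/HPO4^2- at pH 7
  # (pKa2 = 7.198, Davies-corrected by explicit arithmetic) and Cl- added
  # to close the charge balance.
  I_guess <- 0.002
  g1 <- 10^(-0.509 * (sqrt(I_guess) / (1 + sqrt(I_guess)) - 0.3 * I_guess))
  g2 <- g1^4
  # mixed-constant ratio c(HPO4)/c(H2PO4) = Ka2 * g1 / (g2 * aH)
  r <- 10^(-7.198) * g1 / (g2 * 1e-7)
  P <- 0.05e-3
  cH2PO4 <- P / (1 + r); cHPO4 <- P * r / (1 + r)
  cations <- 2 * 0.2e-3 + 2 * 0.05e-3 + 0.2e-3 + 1e-3        # Ca Mg K Na (eq)
  anions <- 0.2e-3 + 2 * 0.05e-3 + cH2PO4 + 2 * cHPO4        # NO3 SO4 P (eq)
  cCl <- cations - anions
  I_oracle <- 0.5 * (4 * 0.2e-3 + 4 * 0.05e-3 + 0.2e-3 + 1e-3 + cCl +
                       0.2e-3 + 4 * 0.05e-3 + cH2PO4 + 4 * cHPO4)
  expect_equal(ionic_strength(background_medium()), I_oracle,
               tolerance = 0.01)

  expect_error(medium("bad", totals = c(Ca = -1e-3)), "concentrations")
})

test_that("Davies activity coefficients follow the closed form", {
  expect_identical(activity_coefficient(2, 0), 1)
  expect_identical(activity_coefficient(0, 0.3), 1)
  # independent hand evaluation at z = 2, I = 0.01
  g_hand <- 10^(-0.509 * 4 * (sqrt(0.01) / (1 + sqrt(0.01)) - 0.3 * 0.01))
  expect_equal(activity_coefficient(2, 0.01), g_hand, tolerance = 1e-12)
  expect_warning(activity_coefficient(1, 0.6), "Davies")
})

test_that("Davies gamma is monotone in I and scales as z^2 in log space", {
  # the linear 0.3 I term turns the curve back up near I ~ 0.38 mol/L, so
  # monotone decrease is only expected below that turning point
  Is <- seq(0.001, 0.3, length.out = 60)
  g1 <- activity_coefficient(1, Is)
  expect_true(all(diff(g1) < 0))
  Is_all <- seq(0.001, 0.5, length.out = 60)
  expect_equal(log10(activity_coefficient(2, Is_all)),
               4 * log10(activity_coefficient(1, Is_all)), tolerance = 1e-12)
})

test_that("acid speciation satisfies its defining equilibrium equations", {
  # pH = pKa2 at infinite dilution forces equal activities of the two
  # central arsenate species
  g0 <- rep(1, 4)
  out <- speciate_acid(5e-5, 6.76, acidity_constants("arsenate"), g0)
  expect_equal(out$activity_M[2], out$activity_M[3], tolerance = 1e-12)

  # zero total: everything zero
  expect_true(all(speciate_acid(0, 7, acidity_constants("arsenate"), g0)$concentration_M == 0))

  # scale invariance: doubling the total doubles every species
  a <- speciate_acid(1e-5, 7.3, acidity_constants("phosphate"), g0)
  b <- speciate_acid(2e-5, 7.3, acidity_constants("phosphate"), g0)
  expect_equal(b$concentration_M, 2 * a$concentration_M, tolerance = 1e-12)

  # brute-force oracle on a pH grid at I = 0: the returned activities must
  # satisfy each mass-action law and the mass balance to 1e-8
  pKa <- acidity_constants("arsenate")
  for (pH in seq(2, 12, by = 0.5)) {
    out <- speciate_acid(1e-4, pH, pKa, g0)
    a <- out$activity_M
    aH <- 10^(-pH)
    for (j in 1:3) {
      expect_equal(a[j + 1] * aH / a[j], 10^(-pKa[j]), tolerance = 1e-8)
    }
    expect_equal(sum(out$concentration_M), 1e-4, tolerance = 1e-10)
  }
})

test_that("medium speciation conserves mass and applies gamma consistently", {
  for (i in 1:20) {
    med <- random_medium(i)
    sp <- speciate_medium(med)
    expect_equal(ladder_total(sp, as_ladder), med$totals[["As"]],
                 tolerance = 1e-6)
    expect_equal(ladder_total(sp, p_ladder), med$totals[["P"]],
                 tolerance = 1e-6)
    for (ion in c("Ca", "Mg", "K", "NO3", "SO4")) {
      expect_equal(sp$table$concentration_M[sp$table$species == ion],
                   med$totals[[ion]], tolerance = 1e-12)
    }
    # activity = gamma * concentration for every species except H+, whose
    # activity is pinned by the pH electrode convention
    tb <- sp$table[sp$table$species != "H", ]
    g <- sp$gamma[as.character(abs(tb$charge))]
    expect_equal(tb$activity_M, tb$concentration_M * unname(g),
                 tolerance = 1e-12)
    expect_true(all(tb$activity_M >= 0))
  }
})

test_that("pure water has no foreign species and charge is closed with Na/Cl", {
  sp <- speciate_medium(medium("water", pH = 7))
  other <- sp$table[!sp$table$species %in% c("H", "OH", "Na", "Cl"), ]
  expect_true(all(other$activity_M == 0))

  # background medium needs Cl- (cation surplus from Ca/Mg/K/Na salts)
  sp_bg <- bg_speciation()
  expect_gt(sp_bg$counter_ion_added_M[["Cl"]], 0)
  expect_identical(sp_bg$counter_ion_added_M[["Na"]], 0)
  conc <- sp_bg$table$concentration_M
  z <- sp_bg$table$charge
  expect_lt(abs(sum(conc * z)), 1e-15)
})

test_that("medium CSV round-trips through read/write", {
  media <- list(background_medium(ca_mM = 5, as_uM = 50), fischeri_medium(25))
  path <- withr::local_tempfile(fileext = ".csv")
  write_medium_csv(media, path)
  back <- read_medium_csv(path)
  expect_length(back, 2)
  expect_equal(back[[1]]$totals, media[[1]]$totals, tolerance = 1e-12)
  expect_equal(back[[2]]$totals, media[[2]]$totals, tolerance = 1e-12)
  expect_equal(back[[1]]$pH, 7)
})
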