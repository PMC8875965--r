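test_that("Graham equation reduces to the symmetric-electrolyte closed form", {
  expect_identical(graham_sigma(0, bg_speciation()), 0)

  # pure 1:1 electrolyte: sigma = sign(psi) * sqrt(0.00345 * 2c(cosh(u)-1))
  c0 <- 0.1
  sp <- speciate_medium(medium("nacl", totals = c(Na = c0, Cl = c0)))
  const <- phys_constants()
  for (psi in c(-0.1, -0.05, -0.01, 0.02)) {
    u <- psi / (const$R_gas * const$T / const$F)
    sig_oracle <- sign(psi) * sqrt(0.00345 * 2 * c0 * (cosh(u) - 1))
    expect_equal(graham_sigma(psi, sp), sig_oracle, tolerance = 1e-4)
  }
  expect_error(graham_sigma(0.6, sp), "outside")
})

test_that("Boltzmann surface scaling follows the closed form", {
  expect_identical(boltzmann_surface(3.2e-4, 0, -0.08), 3.2e-4)
  expect_identical(boltzmann_surface(3.2e-4, -2, 0), 3.2e-4)
  const <- phys_constants()
  rtf <- const$R_gas * const$T / const$F
  expect_equal(boltzmann_surface(1, -1, -rtf), exp(-1), tolerance = 1e-12)
  expect_equal(boltzmann_surface(1, 2, -rtf), exp(2), tolerance = 1e-12)
})

test_that("Stern binding charge obeys its limiting cases", {
  sp <- speciate_medium(medium("cacl2", totals = c(Ca = 1e-3, Cl = 2e-3)))
  const <- phys_constants()

  none <- membrane_params(R_total = 0, P_total = 0)
  expect_identical(binding_sigma(-0.05, sp, none), 0)

  # saturating Ca2+ binding: all R- sites become RCa+ (z-1 = +1), all P0
  # sites become PCa2+ (z = +2)
  RT <- 0.3e-6; PT <- 0.2e-6
  sat <- membrane_params(R_total = RT, P_total = PT,
                         K_R = c(Ca = 1e12), K_P = c(Ca = 1e12))
  expect_equal(binding_sigma(-0.05, sp, sat),
               const$F * (RT + 2 * PT), tolerance = 1e-6)

  # no binding ions with R sites present: fully deprotonated surface
  bare <- membrane_params(R_total = RT, P_total = 0)
  expect_equal(binding_sigma(-0.05, sp, bare), -const$F * RT,
               tolerance = 1e-12)

  # algebraic oracle: independent evaluation of the site mass balance at
  # trial psi0 values for the background medium
  par <- default_membrane_params()
  conc <- setNames(sp$table$concentration_M, sp$table$species)
  z <- setNames(sp$table$charge, sp$table$species)
  for (psi in c(-0.12, -0.05, -0.01)) {
    surf <- conc * exp(-z * psi / (const$R_gas * const$T / const$F))
    tR <- par$K_R * surf[names(par$K_R)]
    tP <- par$K_P * surf[names(par$K_P)]
    zR <- z[names(par$K_R)]; zP <- z[names(par$K_P)]
    sig <- const$F * ((-1 + sum((zR - 1) * tR)) * par$R_total / (1 + sum(tR)) +
                        sum(zP * tP) * par$P_total / (1 + sum(tP)))
    expect_equal(binding_sigma(psi, sp, par), unname(sig), tolerance = 1e-12)
  }
})

test_that("the GCS solver converges to a tight fixed point", {
  par <- default_membrane_params()
  st <- solve_psi0(bg_speciation(), par)
  expect_true(st$converged)
  expect_lt(st$residual_C_m2, 1e-9)
  expect_lt(st$psi0_mV, 0)

  # membrane with no sites carries no charge: psi0 = 0
  none <- membrane_params(R_total = 0, P_total = 0)
  st0 <- solve_psi0(bg_speciation(), none)
  expect_lt(abs(st0$psi0_mV), 1e-6)
})

test_that("surface activities are Boltzmann-consistent across charges", {
  st <- solve_psi0(speciate_medium(background_medium(as_uM = 50)),
                   default_membrane_params())
  s <- st$surface
  ratio <- function(sp) {
    i <- match(sp, s$species)
    s$surface_activity_M[i] / s$bulk_activity_M[i]
  }
  # z = -2 ratio is the square of the z = -1 ratio
  expect_equal(ratio("HAsO4"), ratio("H2AsO4")^2, tolerance = 1e-10)
  expect_equal(ratio("HPO4"), ratio("H2PO4")^2, tolerance = 1e-10)
  # negative psi0: anions depleted, cations enriched at the surface
  expect_lt(ratio("HAsO4"), 1)
  expect_gt(ratio("Ca"), 1)
})

test_that("calcium raises psi0 monotonically and high salt collapses it", {
  par <- default_membrane_params()
  psi <- vapply(c(0.2, 1, 5, 10, 20),
                function(ca) solve_psi0(bg_speciation(ca_mM = ca), par)$psi0_mV,
                numeric(1))
  expect_true(all(diff(psi) > 0))
  expect_lt(psi[1], -50)

  # screening collapse: |psi0| falls monotonically with 1:1 salt and is
  # nearly fully screened at 1 M
  salt <- vapply(c(0.01, 0.1, 0.342, 1), function(c0) {
    sp <- suppressWarnings(
      speciate_medium(medium("salt", totals = c(Na = c0, Cl = c0))))
    abs(solve_psi0(sp, par)$psi0_mV)
  }, numeric(1))
  expect_true(all(diff(salt) < 0))
  expect_lt(salt[4], salt[3] / 2)
})

test_that("the solver agrees with a brute-force psi0 grid scan", {
  par <- default_membrane_params()
  const <- phys_constants()
  for (i in 1:12) {
    sp <- speciate_medium(random_medium(i))
    st <- solve_psi0(sp, par)
    # coarse bracket then a 0.01 mV local grid around the root
    grid <- seq(st$psi0_V - 5e-4, st$psi0_V + 5e-4, by = 1e-5)
    res <- vapply(grid, function(p)
      graham_sigma(p, sp, const) - binding_sigma(p, sp, par, const),
      numeric(1))
    cross <- which(diff(sign(res)) != 0)
    expect_length(cross, 1)
    expect_lt(abs(grid[cross] - st$psi0_V) * 1e3, 0.02)
  }
})

test_that("membrane parameter config round-trips and validates", {
  par <- default_membrane_params()
  expect_s3_class(par, "membrane_params")
  expect_equal(par$R_total, 0.3192e-6, tolerance = 1e-6)
  expect_equal(unname(par$K_R[["H"]]), 21380, tolerance = 1e-4)
  expect_error(membrane_params(1e-6, 0, K_R = c(Cl = 10)), "cations")
  expect_error(membrane_params(-1e-6, 0), "site densities")
})
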