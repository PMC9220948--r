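test_that("domain count follows the fixed-total-area coupling", {
  R_max <- sqrt(20e-12 / pi) / 1e-9
  expect_equal(domain_count(R_max, 20), 1, tolerance = 1e-12)
  expect_equal(domain_count(500, 20), 20 / (pi * 0.25), tolerance = 1e-12)
  expect_equal(domain_count(500, 20), 25.46479, tolerance = 1e-6)
  expect_equal(domain_count(250, 20), 4 * domain_count(500, 20),
    tolerance = 1e-12
  )
  expect_error(domain_count(R_max * 1.01, 20), "must lie in")
  expect_error(domain_count(-1, 20), "must lie in")
})

test_that("perimeter energy is boundary length times line tension", {
  expect_identical(perimeter_energy(100, 5, 0), 0)
  expect_equal(perimeter_energy(1000, 1, 1e-12), 2 * pi * 1e-18,
    tolerance = 1e-12
  )
  # with N_D substituted, E_perim = 2 A_tot sigma / R: doubling R halves it
  sigma <- 0.8e-12
  e1 <- perimeter_energy(200, domain_count(200, 20), sigma)
  e2 <- perimeter_energy(400, domain_count(400, 20), sigma)
  expect_equal(e1, 2 * 20e-12 * sigma / 200e-9, tolerance = 1e-12)
  expect_equal(e1, 2 * e2, tolerance = 1e-12)
})

test_that("dipole moment per lipid follows the parallel-plate relation", {
  expect_identical(dipole_moment_per_lipid(0, 8, 8.8541878128e-12, 55e-20), 0)
  mu <- dipole_moment_per_lipid(0.1, 8, 8.8541878128e-12, 55e-20)
  expect_equal(mu, 8 * 8.8541878128e-12 * 0.1 * 55e-20, tolerance = 1e-12)
  expect_equal(mu, 3.8958e-30, tolerance = 1e-4)
  expect_equal(dipole_moment_per_lipid(0.2, 8, 8.8541878128e-12, 55e-20),
    2 * mu,
    tolerance = 1e-12
  )
})

test_that("electrostatic terms vanish without a dipole contrast and scale as delta_V^2", {
  p0 <- bilayer_params(delta_V_mV = 0)
  expect_identical(intraleaflet_energy(50, p0), 0)
  expect_identical(interleaflet_energy(50, p0), 0)
  expect_identical(electrostatic_energy(50, p0), 0)
  p1 <- bilayer_params(delta_V_mV = 100)
  p2 <- bilayer_params(delta_V_mV = 200)
  for (R in c(5, 80, 1200)) {
    expect_equal(electrostatic_energy(R, p2), 4 * electrostatic_energy(R, p1),
      tolerance = 1e-10
    )
  }
})

test_that("component energies match independent dense-grid trapezoid integration", {
  for (R in c(3, 40, 700)) {
    p <- bilayer_params()
    expect_equal(intraleaflet_energy(R, p), oracle_intra_energy(R, p),
      tolerance = 1e-6
    )
    expect_equal(interleaflet_energy(R, p), oracle_inter_energy(R, p),
      tolerance = 1e-6
    )
  }
  # a second parameter set to exercise the prefactors
  p2 <- bilayer_params(delta_V_mV = 110, d_min_nm = 1.2, h_nm = 4.2, A_L_A2 = 60)
  expect_equal(intraleaflet_energy(90, p2), oracle_intra_energy(90, p2),
    tolerance = 1e-6
  )
  expect_equal(interleaflet_energy(90, p2), oracle_inter_energy(90, p2),
    tolerance = 1e-6
  )
})

test_that("mechanism monotonicities hold on a default-parameter grid", {
  p <- bilayer_params()
  Rg <- exp(seq(log(10), log(sqrt(20e-12 / pi) / 1e-9), length.out = 12))
  intra <- vapply(Rg, intraleaflet_energy, numeric(1), params = p)
  expect_true(all(diff(intra) > 0)) # repulsion grows with domain size
  elec <- vapply(Rg, electrostatic_energy, numeric(1), params = p)
  expect_true(all(diff(elec) > 0))
  # with sigma = 0 the total energy is the electrostatic term: increasing
  p_s0 <- bilayer_params(sigma_pN = 0)
  tot0 <- vapply(Rg, function(R) total_energy(R, p_s0)$E_total, numeric(1))
  expect_equal(tot0, elec, tolerance = 1e-12)
  # with delta_V = 0 the total energy is the perimeter term: decreasing
  p_v0 <- bilayer_params(delta_V_mV = 0)
  totv <- vapply(Rg, function(R) total_energy(R, p_v0)$E_total, numeric(1))
  expect_true(all(diff(totv) < 0))
})

test_that("interleaflet coupling weakens with leaflet separation", {
  vals <- vapply(
    1:6,
    function(h) interleaflet_energy(50, bilayer_params(h_nm = h)),
    numeric(1)
  )
  expect_true(all(diff(abs(vals)) < 0))
})

test_that("energy terms have the expected homogeneity in sigma and A_tot", {
  R <- 120
  p <- bilayer_params(sigma_pN = 0.5)
  p2 <- bilayer_params(sigma_pN = 1.5)
  b1 <- total_energy(R, p)
  b2 <- total_energy(R, p2)
  expect_equal(b2$E_perim, 3 * b1$E_perim, tolerance = 1e-12)
  expect_equal(b2$E_elec, b1$E_elec, tolerance = 1e-10)
  # at fixed radius both terms are proportional to the total raft area
  pA <- bilayer_params(sigma_pN = 0.5, A_tot_um2 = 40)
  bA <- total_energy(R, pA)
  expect_equal(bA$E_perim, 2 * b1$E_perim, tolerance = 1e-12)
  expect_equal(bA$E_elec, 2 * b1$E_elec, tolerance = 1e-10)
})

test_that("breakdown additivity holds across random parameter draws", {
  set.seed(101)
  for (i in 1:20) {
    p <- bilayer_params(
      sigma_pN = runif(1, 0, 3),
      delta_V_mV = runif(1, 0, 300),
      d_min_nm = runif(1, 0.5, 2),
      h_nm = runif(1, 2, 5)
    )
    R <- exp(runif(1, log(2), log(2000)))
    b <- total_energy(R, p)
    expect_equal(b$E_total, b$E_perim + b$E_elec, tolerance = 1e-12)
    expect_equal(b$E_elec, b$E_intra + b$E_inter, tolerance = 1e-12)
    expect_equal(b$E_perim, perimeter_energy(R, b$N_D, p$sigma),
      tolerance = 1e-12
    )
    expect_gte(b$E_intra, 0)
    expect_true(is.finite(b$E_total))
  }
})
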