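# Stopping power, ranges, WEPL arithmetic, scattering moments, straggling.

test_that("stopping power follows the Bethe formula", {
  # frozen value from an independent arbitrary-precision evaluation of the
  # same Bethe expression (I = 75 eV, no corrections): 4.49098 MeV/cm
  expect_equal(stopping_power(200, "proton"), 0.449098382744227, tolerance = 1e-9)
  # z^2 scaling at exactly equal velocity (equal E / mc2)
  p <- ion_species("proton"); he <- ion_species("helium")
  E_p <- 150
  E_he <- E_p * he$mc2 / p$mc2
  expect_equal(stopping_power(E_he, he) / stopping_power(E_p, p), 4, tolerance = 1e-12)
  # identity ratio and domain errors
  expect_equal(stopping_power(37.3, p) / stopping_power(37.3, p), 1)
  expect_error(stopping_power(0, p), "positive")
  expect_error(stopping_power(-5, p), "positive")
  expect_error(stopping_power(600, p), "validity")
})

test_that("CSDA range matches an adaptive quadrature oracle and is monotone", {
  oracle <- stats::integrate(function(E) 1 / stopping_power(E, "proton"),
                             0.5, 200, rel.tol = 1e-10)$value
  expect_equal(csda_range(200, "proton"), oracle, tolerance = 1e-6)
  E <- seq(5, 400, by = 5)
  expect_true(all(diff(csda_range(E, "proton")) > 0))
  expect_equal(csda_range(0, "proton"), 0)
})

test_that("WEPL from energies is additive and inverts exactly", {
  expect_equal(wepl_from_energies(180, 180), 0)
  w1 <- wepl_from_energies(200, 150); w2 <- wepl_from_energies(150, 90)
  expect_equal(w1 + w2, wepl_from_energies(200, 90), tolerance = 1e-12)
  expect_error(wepl_from_energies(100, 150), "exceeds")
  # round trip wepl -> energy -> wepl
  w <- c(0, 12.3, 57.91, 180.044)
  E_out <- energy_from_wepl(200, w)
  expect_equal(wepl_from_energies(200, E_out), w, tolerance = 1e-8)
  # cross-check against the quadrature oracle for 200 -> 100 MeV protons
  oracle <- stats::integrate(function(E) 1 / stopping_power(E, "proton"),
                             100, 200, rel.tol = 1e-10)$value
  expect_equal(wepl_from_energies(200, 100), oracle, tolerance = 1e-6)
})

test_that("pv is the momentum-velocity product", {
  p <- ion_species("proton")
  expect_equal(pv(0, p), 0)
  expect_equal(pv(p$mc2, p), 1.5 * p$mc2) # E = mc2: m*3m/2m
  expect_equal(pv(200, p), 200 * (200 + 2 * 938.272) / (200 + 938.272))
  E <- seq(1, 400, by = 1)
  expect_true(all(diff(pv(E, p)) > 0))
  expect_error(pv(-1, p), "non-negative")
})

test_that("Fermi-Eyges moments match the quadrature oracle and scale as z^2", {
  prof <- slab_profile(200, 200, "proton")
  fe <- fermi_eyges_moments(prof, "proton")
  or <- fe_oracle(prof, "proton")
  expect_equal(fe$sigma_theta2, or$sigma_theta2, tolerance = 1e-6)
  expect_equal(fe$sigma_ytheta, or$sigma_ytheta, tolerance = 1e-6)
  expect_equal(fe$sigma_y2, or$sigma_y2, tolerance = 1e-6)

  # zero thickness: all moments vanish
  z0 <- fermi_eyges_moments(depth_profile(0, 1, 361, 200), "proton")
  expect_identical(z0$sigma_theta2, 0)
  expect_identical(z0$sigma_y2, 0)

  # helium on an identical pv(x) profile: sigma_theta^2 ratio exactly 4.
  # Solve E_he so that pv(E_he, he) equals the proton profile's pv:
  # E^2 + (2m - q) E - q m = 0 with q the target pv
  p <- ion_species("proton"); he <- ion_species("helium")
  q <- pv(prof$E, p)
  m <- he$mc2
  E_he <- (-(2 * m - q) + sqrt((2 * m - q)^2 + 4 * q * m)) / 2
  expect_equal(pv(E_he, he), q, tolerance = 1e-12)
  prof_he <- depth_profile(prof$x, prof$rsp, prof$X0, E_he)
  fe_he <- fermi_eyges_moments(prof_he, he)
  expect_equal(fe_he$sigma_theta2 / fe$sigma_theta2, 4, tolerance = 1e-5)
  expect_equal(fe_he$sigma_y2 / fe$sigma_y2, 4, tolerance = 1e-5)
})

test_that("scattering covariance is symmetric positive semidefinite on random profiles", {
  set.seed(7)
  for (i in 1:25) {
    thick <- stats::runif(1, 5, 250)
    rsp <- stats::runif(1, 0.2, 1.8)
    E0 <- stats::runif(1, 120, 240)
    prof <- slab_profile(thick, E0, "proton", step = 2, rsp = rsp)
    fe <- fermi_eyges_moments(prof, "proton")
    expect_identical(fe$Sigma[1, 2], fe$Sigma[2, 1])
    expect_gte(det(fe$Sigma), 0)
    expect_gte(fe$sigma_theta2, 0)
    expect_gte(fe$sigma_y2, 0)
  }
})

test_that("Tschalar straggling matches the quadrature oracle and grows with depth", {
  k <- physics_constants()
  p <- ion_species("proton")
  k2 <- function(E) { # independent transcription of the straggling rate
    b2 <- 1 - 1 / (1 + E / p$mc2)^2
    k$K_bethe * k$me_c2 * (1 - b2 / 2) / (1 - b2)
  }
  E_out <- energy_from_wepl(200, 200, p)
  oracle <- stopping_power(E_out, p)^2 *
    stats::integrate(function(E) k2(E) / stopping_power(E, p)^3,
                     E_out, 200, rel.tol = 1e-10)$value
  expect_equal(tschalar_variance(200, E_out, p), oracle, tolerance = 1e-6)

  # zero path -> zero variance; thicker absorber -> strictly more straggling
  expect_equal(tschalar_variance(200, 200, p), 0)
  w <- c(50, 100, 150, 200)
  v <- tschalar_variance(200, energy_from_wepl(200, w, p), p)
  expect_true(all(diff(v) > 0))
  expect_error(tschalar_variance(200, -1, p), "stopped")

  # profile interface takes the endpoints
  prof <- slab_profile(200, 200, "proton")
  expect_equal(tschalar_variance(prof, species = p),
               tschalar_variance(200, prof$E[nrow(prof)], p), tolerance = 1e-9)
})

test_that("energy-to-WEPL width conversion is first-order propagation", {
  expect_equal(sigma_wepl_from_sigma_E(0, 100), 0)
  s1 <- sigma_wepl_from_sigma_E(1, 100)
  expect_equal(sigma_wepl_from_sigma_E(2, 100), 2 * s1)
  expect_equal(s1, 1 / stopping_power(100, "proton"))
  expect_error(sigma_wepl_from_sigma_E(1, 0), "positive")
})
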