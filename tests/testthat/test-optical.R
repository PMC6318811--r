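# Optical-property model: closed-form checks against the tabulated
# skin, blood and particle values, and algebraic properties of the
# mixing rules.

test_that("baseline and melanosome absorption follow the printed formulas", {
  expect_equal(round(mu_a_baseline(585), 3), 0.037)
  expect_equal(round(mu_a_baseline(755), 3), 0.025)
  # asymptote: the exponential term vanishes at long wavelengths
  expect_equal(mu_a_baseline(1100), 0.0244, tolerance = 1e-3)
  # power law, monotone decreasing
  expect_equal(mu_a_melanosome(585), 6.6e10 * 585^-3.33)
  expect_equal(round(mu_a_melanosome(585), 1), 40.3)
  expect_equal(round(mu_a_melanosome(755), 1), 17.2)
  wl <- seq(450, 1050, by = 50)
  expect_true(all(diff(mu_a_melanosome(wl)) < 0))
  expect_error(mu_a_baseline(300), "wavelength")
})

test_that("basal-layer absorption reproduces the tabulated pigmentation levels", {
  # printed table values, +/- 0.005 mm^-1 (half a printed digit); the
  # 755 nm moderate entry is printed from the melanin term alone, so it
  # is compared at the same half-digit band against the full mixture
  expect_lt(abs(mu_a_basal(585, 0.04) - 1.65), 0.005)
  expect_lt(abs(mu_a_basal(585, 0.15) - 6.07), 0.005)
  expect_lt(abs(mu_a_basal(585, 0.50) - 20.15), 0.05)
  expect_lt(abs(mu_a_basal(755, 0.04) - 0.71), 0.005)
  expect_lt(abs(mu_a_basal(755, 0.15) - 2.58), 0.03)
  expect_lt(abs(mu_a_basal(755, 0.50) - 8.61), 0.02)
  # zero melanin reduces to the baseline
  expect_identical(mu_a_basal(700, 0), mu_a_baseline(700))
  expect_error(mu_a_basal(585, 1.2), "fmel")
})

test_that("skin scattering matches the table and rejects g = 1", {
  expect_lt(abs(mu_s_skin(585, 0.80) - 15.61), 0.005)
  expect_lt(abs(mu_s_skin(755, 0.91) - 17.55), 0.005)
  expect_identical(skin_anisotropy(585), 0.80)
  expect_identical(skin_anisotropy(755), 0.91)
  expect_error(mu_s_skin(585, 1), "g must be")
})

test_that("vessel screening factor has the right limits and monotonicity", {
  # zero absorption: constants sum
  expect_equal(vessel_screening_factor(0, 30), 0.039 + 0.486 + 0.468)
  # strong absorption: both exponentials negligible
  expect_equal(vessel_screening_factor(17.91, 25), 0.039, tolerance = 1e-6)
  # strictly decreasing until both exponentials underflow
  x <- vessel_screening_factor(seq(0, 0.5, by = 0.05), 25)
  expect_true(all(diff(x) < 0))
  expect_true(all(diff(vessel_screening_factor(seq(0, 2, by = 0.1), 25)) <= 0))
  expect_error(vessel_screening_factor(-1, 10), "non-negative")
  expect_error(vessel_screening_factor(1, 0), "positive")
})

test_that("adjusted dermal absorption reproduces the depth-binned table", {
  bins <- dermis_depth_bins()
  tab585 <- c(0.071, 0.090, 0.062, 0.053, 0.050, 0.047)
  tab755 <- c(0.025, 0.024, 0.025, 0.025, 0.025, 0.025)
  for (i in seq_len(nrow(bins))) {
    expect_lt(abs(mu_a_dermis_adjusted(585, bins[i, ]) - tab585[i]), 0.005)
    expect_lt(abs(mu_a_dermis_adjusted(755, bins[i, ]) - tab755[i]), 0.005)
  }
  expect_lt(abs(mu_a_dermis_oct(585) - 0.073), 0.0005)
  expect_lt(abs(mu_a_dermis_oct(755) - 0.026), 0.0005)
  expect_identical(mu_a_dermis_oct(700, 0), mu_a_baseline(700))
})

test_that("blood properties are the tabulated two-wavelength values", {
  b <- blood_properties(585)
  expect_equal(c(b$mu_a, b$mu_s, b$g), c(17.91, 76.05, 0.970))
  b <- blood_properties(755)
  expect_equal(c(b$mu_a, b$mu_s, b$g), c(0.44, 79.85, 0.983))
  expect_error(blood_properties(650), "tabulated")
})

test_that("vessel effective properties are affine in the particle fraction", {
  blood <- blood_properties(755)
  net0 <- net_formulation("nano", f_nets = 0, mu_a_nets = 50)
  expect_equal(unclass(vessel_effective_properties(blood, net0))[c("mu_a", "mu_s", "g")],
               unclass(blood)[c("mu_a", "mu_s", "g")])
  net1 <- net_formulation("micro", f_nets = 1, mu_a_nets = 50)
  v1 <- vessel_effective_properties(blood, net1)
  expect_equal(c(v1$mu_a, v1$mu_s, v1$g), c(50, 2.20, 0.99))
  # affine: value at f is the straight line between the endpoints
  f <- 0.37
  nf <- net_formulation("micro", f_nets = f, mu_a_nets = 50)
  vf <- vessel_effective_properties(blood, nf)
  expect_equal(vf$mu_s, (1 - f) * blood$mu_s + f * 2.20)
  # the printed scattering bounds
  v_lo <- vessel_effective_properties(blood, net_formulation("nano", 0.25, mu_a_nets = 1))
  v_hi <- vessel_effective_properties(blood, net_formulation("micro", 0.10, mu_a_nets = 1))
  # printed to two decimals; the micro bound sits exactly half an ULP off
  expect_lt(abs(v_lo$mu_s - 59.90), 0.005 + 1e-9)
  expect_lt(abs(v_hi$mu_s - 72.09), 0.005 + 1e-9)
  expect_identical(vessel_effective_properties(blood, NULL), blood)
})

test_that("ICG design equation reproduces the printed series and inverts the forward chain", {
  expect_equal(round(icg_for_target_mu_a(18, 0.25, 0.44)), 1258)
  targets <- 1:6
  expect_equal(round(sapply(targets, icg_for_target_mu_a, f_nets = 0.10,
                            mu_a_blood = 0.44)),
               c(108, 286, 464, 642, 820, 998))
  # mutual inverse with the forward mixture to machine precision
  blood <- blood_properties(755)
  for (tgt in c(1, 3.7, 18)) {
    icg <- icg_for_target_mu_a(tgt, 0.25, blood$mu_a)
    net <- net_formulation("nano", 0.25, icg_conc = icg)
    v <- vessel_effective_properties(blood, net)
    expect_equal(v$mu_a, tgt, tolerance = 1e-12)
  }
  expect_error(icg_for_target_mu_a(0.2, 0.10, 0.44), "minimum achievable")
})

test_that("formulation constructor resolves any one of the three specifications", {
  n1 <- net_formulation("micro", 0.10, target_mu_a_bv = 1, wavelength = 755)
  expect_equal(n1$mu_a_nets, 6.04, tolerance = 1e-6)
  expect_equal(n1$icg_conc, 17.8 * 6.04, tolerance = 1e-6)
  n2 <- net_formulation("nano", 0.10, icg_conc = n1$icg_conc)
  expect_equal(n2$mu_a_nets, n1$mu_a_nets)
  expect_equal(c(n2$mu_s_nets, n2$g_nets), c(0.06, 0.55))
  expect_error(net_formulation("micro", 0.10), "exactly one")
  expect_error(net_formulation("micro", 0.10, mu_a_nets = 1, icg_conc = 3),
               "exactly one")
})
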