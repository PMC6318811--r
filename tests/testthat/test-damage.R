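# Arrhenius damage quantification and the threshold-dosage search.

test_that("the damage integral matches the closed form at constant temperature", {
  # hold the whole domain at a fixed temperature: insulated, film at T0
  ap <- arrhenius_params()
  for (Tc in c(35, 70, 85)) {
    m <- narrow_skin(585)
    tl <- data.frame(phase = "hold", h = 1e-12, T_med = Tc, duration_ms = 200)
    f <- solve_heat(m, NULL, timeline = tl, dt_post_ms = 1, T0 = Tc,
                    damage_window_ms = c(0, 200), store_history = TRUE)
    d <- damage_integral(f, m)
    closed <- ap$skin$A * 0.2 * exp(-ap$skin$E / (ap$R_gas * (Tc + 273.15)))
    expect_equal(max(abs(d$omega / closed - 1)), 0, tolerance = 1e-6)
    # re-integration from stored history with explicit parameters agrees
    d2 <- damage_integral(f, m, params_by_class = ap)
    expect_equal(d2$omega, d$omega, tolerance = 1e-9)
  }
})

test_that("doubling the exposure window doubles the damage index", {
  m <- narrow_skin(585)
  mk <- function(dur) {
    tl <- data.frame(phase = "hold", h = 1e-12, T_med = 80, duration_ms = dur)
    f <- solve_heat(m, NULL, timeline = tl, dt_post_ms = 1, T0 = 80,
                    damage_window_ms = c(0, dur))
    max(damage_integral(f, m)$omega)
  }
  expect_equal(mk(200) / mk(100), 2, tolerance = 1e-9)
})

test_that("vessel nodes integrate with blood parameters, tissue with skin parameters", {
  ap <- arrhenius_params()
  m <- make_single_vessel_case(500, 200, "light", NULL, 585, width_x = 600)
  tl <- data.frame(phase = "hold", h = 1e-12, T_med = 80, duration_ms = 100)
  f <- solve_heat(m, NULL, timeline = tl, dt_post_ms = 1, T0 = 80,
                  damage_window_ms = c(0, 100))
  d <- damage_integral(f, m)
  TK <- 80 + 273.15
  om_skin <- ap$skin$A * 0.1 * exp(-ap$skin$E / (ap$R_gas * TK))
  om_blood <- ap$blood$A * 0.1 * exp(-ap$blood$E / (ap$R_gas * TK))
  ves <- m$labels == 4L
  expect_equal(unique(round(d$omega[ves] / om_blood, 9)), 1)
  expect_equal(unique(round(d$omega[!ves] / om_skin, 9)), 1)
})

test_that("percent vessel damage counts the damaged cross-section", {
  m <- make_single_vessel_case(500, 200, "light", NULL, 585, width_x = 600)
  d <- structure(list(omega = matrix(0, m$grid$nz, m$grid$nx),
                      mask = matrix(FALSE, m$grid$nz, m$grid$nx),
                      labels = m$labels, grid = m$grid),
                 class = "damage_field")
  expect_equal(percent_vessel_damage(d, m), 0)
  d$mask[m$labels == 4L] <- TRUE
  expect_equal(percent_vessel_damage(d, m), 100)
  # half-damaged lumen (upper half by depth)
  ves <- which(m$labels == 4L, arr.ind = TRUE)
  zmid <- stats::median(m$grid$z[ves[, 1]])
  d$mask[] <- FALSE
  d$mask[ves[m$grid$z[ves[, 1]] < zmid, ]] <- TRUE
  half <- percent_vessel_damage(d, m)
  expect_gt(half, 35); expect_lt(half, 65)
  # depth limit excludes the vessel entirely
  expect_equal(percent_vessel_damage(d, m, depth_limit_um = 400), NA_real_)
  # no-vessel model yields NA
  m0 <- narrow_skin(585)
  d0 <- structure(list(omega = matrix(0, m0$grid$nz, m0$grid$nx),
                       mask = matrix(FALSE, m0$grid$nz, m0$grid$nx),
                       labels = m0$labels, grid = m0$grid),
                  class = "damage_field")
  expect_true(is.na(percent_vessel_damage(d0, m0)))
})

test_that("epidermal damage flags any damaged epidermal or basal node", {
  m <- narrow_skin(585)
  d <- structure(list(omega = matrix(0, m$grid$nz, m$grid$nx),
                      mask = matrix(FALSE, m$grid$nz, m$grid$nx),
                      labels = m$labels, grid = m$grid),
                 class = "damage_field")
  expect_false(epidermis_damaged(d, m))
  basal_row <- which(m$labels[, 1] == 2L)[1]
  d$mask[basal_row, 1] <- TRUE
  expect_true(epidermis_damaged(d, m))
})

test_that("damage is monotone in dosage for a fixed source", {
  m <- narrow_skin(585, "moderate")
  s <- run_mc(m, beam(585), n_photons = 2e4, seed = 6, mode = "planar")
  om <- sapply(c(1, 2, 4, 8), function(D) {
    sw <- source_to_power_density(s, radiant_exposure = D, nx = m$grid$nx)
    max(damage_integral(solve_heat(m, sw), m)$omega)
  })
  expect_true(all(diff(om) > 0))
})

test_that("the threshold search brackets and bisects on the dosage grid", {
  # heavily pigmented 585-nm skin: threshold at the bottom of the grid
  r <- find_threshold_dosage(585, pigmentation("heavy"), n_photons = 2e4,
                             seed = 3)
  expect_s3_class(r, "dth_result")
  expect_true(r$d_th >= 1 && r$d_th <= 3)
  probed <- as.numeric(names(r$max_omega_at))
  om <- r$max_omega_at
  expect_true(all(om[probed <= r$d_th] < 1))
  expect_true(any(om[probed > r$d_th] >= 1))
  # censoring: no damaging dosage on a deliberately short grid
  expect_warning(
    r2 <- find_threshold_dosage(755, pigmentation("light"), n_photons = 5e3,
                                seed = 3, d_max = 4),
    "censored")
  expect_equal(r2$d_th, 4)
})
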