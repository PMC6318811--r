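# Voxelized geometry construction, label accounting, vessel placement
# and array-container round trips.

test_that("layer arithmetic matches the standard skin stack", {
  # uniform 5-um z pitch: 9 melaninless + 3 basal + 388 dermis rows
  m <- build_layered_model(width_x = 100, depth_z = 2000, dx = 10,
                           dz_epi = 5, dz_dermis = 5,
                           pigmentation = pigmentation("light"),
                           wavelength = 585)
  lab_z <- m$labels[, 1]
  expect_equal(sum(lab_z == 1L), 9L)
  expect_equal(sum(lab_z == 2L), 3L)
  expect_equal(sum(lab_z >= 11L), 388L)
  # label counts conserve the total voxel count
  expect_equal(sum(table(m$labels)), prod(dim(m$labels)))
})

test_that("a vessel occupies the expected depth span at the beam center", {
  m <- build_layered_model(width_x = 1000, dx = 10, dz_epi = 5, dz_dermis = 10,
                           pigmentation = pigmentation("light"),
                           vessels = list(cyl_vessel(500, 200)),
                           wavelength = 585)
  ic <- which.min(abs(m$grid$x))  # center column
  zv <- m$grid$z[m$labels[, ic] == 4L]
  expect_true(all(zv >= 500 & zv < 700))
  expect_equal(range(zv), c(505, 695))
  # no vessel voxels outside the circumscribing box
  anyv <- apply(m$labels == 4L, 1, any)
  expect_true(all(m$grid$z[anyv] > 500 & m$grid$z[anyv] < 700))
})

test_that("overlapping vessels union without double labeling and bad vessels error", {
  m <- build_layered_model(width_x = 1000, dx = 10,
                           pigmentation = pigmentation("light"),
                           vessels = list(cyl_vessel(500, 200),
                                          cyl_vessel(550, 200, cx = 50)),
                           wavelength = 585)
  expect_true(all(m$labels %in% c(1L, 2L, 4L, 11:16)))
  n_union <- sum(m$labels == 4L)
  m1 <- build_layered_model(width_x = 1000, dx = 10,
                            pigmentation = pigmentation("light"),
                            vessels = list(cyl_vessel(500, 200)),
                            wavelength = 585)
  expect_lt(n_union, 2 * sum(m1$labels == 4L))
  expect_error(build_layered_model(width_x = 500, vessels = list(cyl_vessel(30, 100)),
                                   pigmentation = pigmentation("light")),
               "outside the dermis")
  expect_error(build_layered_model(width_x = 500, vessels = list(cyl_vessel(1900, 200)),
                                   pigmentation = pigmentation("light")),
               "below the bottom")
})

test_that("grid refinement moves layer boundaries by less than one coarse voxel", {
  mc_ <- build_layered_model(width_x = 100, dx = 10, dz_epi = 5, dz_dermis = 10,
                             pigmentation = pigmentation("light"), wavelength = 585)
  mf <- build_layered_model(width_x = 100, dx = 10, dz_epi = 2.5, dz_dermis = 5,
                            pigmentation = pigmentation("light"), wavelength = 585)
  top_dermis_c <- min(mc_$grid$z[mc_$labels[, 1] >= 11L])
  top_dermis_f <- min(mf$grid$z[mf$labels[, 1] >= 11L])
  expect_lt(abs(top_dermis_c - top_dermis_f), 10)
})

test_that("imported masks become vessel labels beneath a prepended epidermis", {
  # all-zero mask: pure layered skin
  m0 <- import_vessel_mask(array(0L, c(8, 8, 20)), dx = 20, dy = 20, dz = 20,
                           pigmentation = pigmentation("light"), wavelength = 585)
  expect_equal(sum(m0$labels == 4L), 0L)
  expect_equal(dim(m0$labels), c(12L + 20L, 8L, 8L))
  # single voxel at a known depth
  mk <- array(0L, c(8, 8, 40))
  mk[3, 5, 31] <- 1L  # depth 60 + (31 - 0.5) * 20 = 670 um
  m1 <- import_vessel_mask(mk, dx = 20, dy = 20, dz = 20,
                           pigmentation = pigmentation("light"), wavelength = 585)
  w <- which(m1$labels == 4L, arr.ind = TRUE)
  expect_equal(nrow(w), 1L)
  expect_equal(unname(w[1, 2:3]), c(3L, 5L))
  expect_equal(m1$grid$z[w[1, 1]], 60 + 30.5 * 20)
  expect_error(import_vessel_mask(mk, dx = 20, dy = 20,
                                  pigmentation = pigmentation("light")),
               "pitch")
})

test_that("volumes and label maps round-trip through multi-page TIFF", {
  vol <- array(runif(6 * 5 * 4), c(6, 5, 4))
  f <- tempfile(fileext = ".tif")
  write_volume_tiff(vol, f, pitch = c(10, 10, 20))
  r <- read_volume_tiff(f)
  expect_equal(r$vol, vol, tolerance = 1e-6)
  expect_equal(r$pitch_um, c(10, 10, 20))
  # label maps are lossless
  m <- build_layered_model(width_x = 200, dx = 10,
                           pigmentation = pigmentation("moderate"),
                           vessels = list(cyl_vessel(500, 200)),
                           wavelength = 585)
  f2 <- tempfile(fileext = ".tif")
  export_model_labels(m, f2)
  r2 <- read_volume_tiff(f2)
  expect_identical(aperm(r2$vol, c(3, 1, 2))[, , 1], m$labels + 0)
})

test_that("synthetic plexus imports with the generator's vessel volume fraction", {
  syn <- make_plexus_volume(extent_um = c(600, 600, 600), pitch_um = 20,
                            n_vessels = 3, seed = 11)
  m <- import_vessel_mask(syn$mask, dx = 20, dy = 20, dz = 20,
                          pigmentation = pigmentation("light"), wavelength = 585)
  frac_mask <- mean(syn$mask)
  dermal <- m$labels[-(1:12), , ]
  expect_equal(mean(dermal == 4L), frac_mask, tolerance = 1e-12)
})
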