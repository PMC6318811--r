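# End-to-end orchestration: geometry -> Monte Carlo -> heat -> damage,
# with ready-made configurations for the study scenarios.

#' Scenario configuration
#'
#' Bundles everything one treatment simulation needs.  `dosage = "auto"`
#' triggers the epidermal threshold-dosage search on the matching
#' vessel-free skin and irradiates at the threshold.
#'
#' @param name Scenario id (free text, carried into the metrics row).
#' @param wavelength Wavelength (nm).
#' @param pigmentation A [pigmentation()] level or its name.
#' @param dosage Incident dosage (J/cm^2) or `"auto"`.
#' @param vessel_depth Depth of the vessel top (um), or `NULL` for a
#'   vessel-free run.
#' @param vessel_diameter Vessel diameter (um), default 200.
#' @param net `NULL`, a [net_formulation()], or a list with fields
#'   `kind`, `f_nets` and `mu_a_bv` (resolved at the scenario wavelength).
#' @param mask Optional list `(mask, dx, dy, dz)` describing a binary
#'   vessel volume for an imported 3-D geometry (overrides
#'   `vessel_depth`).
#' @param beam_diameter_mm Beam diameter (mm); default 6, or 8 for
#'   imported geometries.
#' @param n_photons Photon packets, default 1e5 (fast mode).
#' @param seed Integer seed.
#' @param dx,dz_dermis,width_x Simulated-geometry grid controls (um).
#' @param depth_limit_um Depth limit for the percent-damage metric
#'   (default 1000 for imported geometries, none otherwise).
#' @return List of class `pws_scenario`.
#' @export
scenario <- function(name, wavelength, pigmentation = "light",
                     dosage = "auto", vessel_depth = 500,
                     vessel_diameter = 200, net = NULL, mask = NULL,
                     beam_diameter_mm = if (is.null(mask)) 6 else 8,
                     n_photons = 1e5, seed = 1L,
                     dx = 10, dz_dermis = 10, width_x = 3000,
                     depth_limit_um = if (is.null(mask)) NULL else 1000) {
  if (is.character(pigmentation)) pigmentation <- pwstherm::pigmentation(pigmentation)
  if (!is.null(net) && !inherits(net, "net_formulation"))
    net <- net_formulation(kind = net$kind, f_nets = net$f_nets,
                           target_mu_a_bv = net$mu_a_bv,
                           wavelength = wavelength)
  structure(list(name = name, wavelength = wavelength,
                 pigmentation = pigmentation, dosage = dosage,
                 vessel_depth = vessel_depth,
                 vessel_diameter = vessel_diameter, net = net, mask = mask,
                 beam_diameter_mm = beam_diameter_mm,
                 n_photons = n_photons, seed = seed, dx = dx,
                 dz_dermis = dz_dermis, width_x = width_x,
                 depth_limit_um = depth_limit_um),
            class = "pws_scenario")
}

#' Run one treatment scenario end to end
#'
#' Executes geometry construction, Monte Carlo energy deposition,
#' the heat-diffusion solve over the cooling/pulse/rewarming timeline
#' and Arrhenius damage quantification, and assembles a one-row metrics
#' table.  For imported 3-D geometries the Monte Carlo scores in 3-D,
#' the deposition is averaged over a central y slab (`slab_mm`), and
#' the thermal/damage stages run on the central x-z cross-section.
#'
#' @param config A [scenario()].
#' @param slab_mm y-slab thickness for 3-D deposition averaging (mm).
#' @param verbose Log per-stage progress to stderr?
#' @return Object of class `pws_result`: `model`, `source`, `field`,
#'   `damage`, `dosage_used`, `dth` (when searched), and `metrics`
#'   (one-row data frame: scenario, wavelength, fmel, dosage,
#'   percent_vessel_damage, epidermis_damaged).
#' @export
run_scenario <- function(config, slab_mm = 0.3, verbose = FALSE) {
  stopifnot(inherits(config, "pws_scenario"))
  say <- function(...) if (verbose) message(sprintf(...))
  t_all <- Sys.time()
  bm <- beam(config$wavelength, diameter_mm = config$beam_diameter_mm)

  dth <- NULL
  dosage <- config$dosage
  if (identical(dosage, "auto")) {
    say("stage dth-search (%g nm, fmel %g%%)", config$wavelength,
        100 * config$pigmentation$fmel)
    dth <- find_threshold_dosage(config$wavelength, config$pigmentation,
                                 beam = bm, n_photons = config$n_photons,
                                 seed = config$seed, dx = config$dx,
                                 dz_dermis = config$dz_dermis)
    dosage <- dth$d_th
    if (dosage <= 0) stop("threshold search found no safe dosage")
  }
  stopifnot(is.numeric(dosage), dosage > 0)

  say("stage geometry")
  if (!is.null(config$mask)) {
    model3 <- import_vessel_mask(config$mask$mask, config$mask$dx,
                                 config$mask$dy, config$mask$dz,
                                 pigmentation = config$pigmentation,
                                 wavelength = config$wavelength,
                                 net = config$net)
    model <- central_slice_model(model3)
    say("stage mc (3-D, %g photons)", config$n_photons)
    src <- run_mc(model3, bm, n_photons = config$n_photons,
                  seed = config$seed, mode = "xyz")
    # average deposition over the central y slab
    yc <- src$grid$y
    keep <- which(abs(yc - stats::median(yc)) <= slab_mm * 1000 / 2)
    S2 <- apply(src$S[, , keep, drop = FALSE], c(1, 2), mean)
    src2 <- src; src2$S <- S2; src2$mode <- "slab"
  } else if (is.null(config$vessel_depth)) {
    model <- build_layered_model(width_x = 4 * config$dx, dx = config$dx,
                                 dz_dermis = config$dz_dermis,
                                 pigmentation = config$pigmentation,
                                 wavelength = config$wavelength)
    say("stage mc (planar, %g photons)", config$n_photons)
    src <- src2 <- run_mc(model, bm, n_photons = config$n_photons,
                          seed = config$seed, mode = "planar")
  } else {
    model <- make_single_vessel_case(depth = config$vessel_depth,
                                     diameter = config$vessel_diameter,
                                     pigmentation = config$pigmentation,
                                     net = config$net,
                                     wavelength = config$wavelength,
                                     width_x = config$width_x,
                                     dx = config$dx,
                                     dz_dermis = config$dz_dermis)
    say("stage mc (slab, %g photons)", config$n_photons)
    src <- src2 <- run_mc(model, bm, n_photons = config$n_photons,
                          seed = config$seed, mode = "slab")
  }

  say("stage heat")
  sw <- source_to_power_density(src2, radiant_exposure = dosage,
                                nx = model$grid$nx)
  field <- solve_heat(model, sw)
  say("stage damage")
  dmg <- damage_integral(field, model)
  pvd <- percent_vessel_damage(dmg, model, config$depth_limit_um)
  epi <- epidermis_damaged(dmg, model)
  metrics <- data.frame(
    scenario = config$name, wavelength = config$wavelength,
    fmel = config$pigmentation$fmel,
    net = if (is.null(config$net)) "none" else config$net$kind,
    f_nets = if (is.null(config$net)) 0 else config$net$f_nets,
    dosage_j_cm2 = dosage,
    vessel_depth_um = if (is.null(config$vessel_depth)) NA_real_ else config$vessel_depth,
    percent_vessel_damage = pvd, epidermis_damaged = epi,
    seed = config$seed)
  say("done in %.1f s", as.numeric(difftime(Sys.time(), t_all, units = "secs")))
  structure(list(model = model, source = src, field = field, damage = dmg,
                 dosage_used = dosage, dth = dth, metrics = metrics,
                 config = config),
            class = "pws_result")
}

#' @export
print.pws_result <- function(x, ...) {
  cat("scenario result:\n")
  print(x$metrics, row.names = FALSE)
  invisible(x)
}

#' Ready-to-run scenario batches for the study tables and figures
#'
#' @param name One of `"table4"` (threshold dosages, 2 wavelengths x 3
#'   pigmentations, vessel-free), `"fig4"` (light skin, both wavelengths
#'   at threshold, vessels at 500/800 um, no particles), `"fig5"`
#'   (moderate skin analogue), `"fig6"` (light skin, 755 nm, micro/nano
#'   particles at f = 10%, mu_a,BV = 1), `"fig7"` (moderate skin
#'   absorption sweep) or `"fig8"` (heavy skin, f = 25%, mu_a,BV = 18).
#' @param seed Seed assigned to every config.
#' @param n_photons Photon packets per config.
#' @return List of [scenario()] configs.
#' @export
scenario_suite <- function(name, seed = 1L, n_photons = 1e5) {
  valid <- c("table4", "fig4", "fig5", "fig6", "fig7", "fig8")
  if (!name %in% valid)
    stop("unknown suite '", name, "'; valid names: ",
         paste(valid, collapse = ", "))
  mk <- function(...) scenario(..., seed = seed, n_photons = n_photons)
  depths <- c(500, 800)
  kinds <- c("micro", "nano")
  out <- switch(name,
    table4 = {
      grid <- expand.grid(wl = c(585, 755),
                          pig = c("light", "moderate", "heavy"),
                          stringsAsFactors = FALSE)
      lapply(seq_len(nrow(grid)), function(i)
        mk(sprintf("table4_%d_%s", grid$wl[i], grid$pig[i]),
           wavelength = grid$wl[i], pigmentation = grid$pig[i],
           dosage = "auto", vessel_depth = NULL))
    },
    fig4 = {
      grid <- expand.grid(wl = c(585, 755), depth = depths)
      d_at <- c(`585` = 8, `755` = 21)
      lapply(seq_len(nrow(grid)), function(i)
        mk(sprintf("fig4_%dnm_%dum", grid$wl[i], grid$depth[i]),
           wavelength = grid$wl[i], pigmentation = "light",
           dosage = unname(d_at[as.character(grid$wl[i])]),
           vessel_depth = grid$depth[i]))
    },
    fig5 = {
      grid <- expand.grid(wl = c(585, 755), depth = depths)
      d_at <- c(`585` = 3, `755` = 6)
      lapply(seq_len(nrow(grid)), function(i)
        mk(sprintf("fig5_%dnm_%dum", grid$wl[i], grid$depth[i]),
           wavelength = grid$wl[i], pigmentation = "moderate",
           dosage = unname(d_at[as.character(grid$wl[i])]),
           vessel_depth = grid$depth[i]))
    },
    fig6 = {
      grid <- expand.grid(kind = kinds, depth = depths, stringsAsFactors = FALSE)
      lapply(seq_len(nrow(grid)), function(i)
        mk(sprintf("fig6_%s_%dum", grid$kind[i], grid$depth[i]),
           wavelength = 755, pigmentation = "light", dosage = 21,
           vessel_depth = grid$depth[i],
           net = list(kind = grid$kind[i], f_nets = 0.10, mu_a_bv = 1)))
    },
    fig7 = {
      grid <- expand.grid(kind = kinds, depth = depths, mua = c(1, 3, 6),
                          stringsAsFactors = FALSE)
      lapply(seq_len(nrow(grid)), function(i)
        mk(sprintf("fig7_%s_%dum_mua%g", grid$kind[i], grid$depth[i], grid$mua[i]),
           wavelength = 755, pigmentation = "moderate", dosage = 6,
           vessel_depth = grid$depth[i],
           net = list(kind = grid$kind[i], f_nets = 0.10, mu_a_bv = grid$mua[i])))
    },
    fig8 = {
      grid <- expand.grid(kind = kinds, depth = depths, stringsAsFactors = FALSE)
      lapply(seq_len(nrow(grid)), function(i)
        mk(sprintf("fig8_%s_%dum", grid$kind[i], grid$depth[i]),
           wavelength = 755, pigmentation = "heavy", dosage = 3,
           vessel_depth = grid$depth[i],
           net = list(kind = grid$kind[i], f_nets = 0.25, mu_a_bv = 18)))
    })
  out
}
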