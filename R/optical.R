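#' Optical property triplet
#'
#' Bundle of the absorption coefficient, scattering coefficient and
#' scattering anisotropy describing one material at one wavelength.
#'
#' @param mu_a Absorption coefficient (mm^-1), >= 0.
#' @param mu_s Scattering coefficient (mm^-1), >= 0.
#' @param g Scattering anisotropy (dimensionless, in [-1, 1]).
#' @return An object of class `optical_properties`.
#' @export
optical_properties <- function(mu_a, mu_s, g) {
  stopifnot(is.numeric(mu_a), is.numeric(mu_s), is.numeric(g))
  if (mu_a < 0) stop("mu_a must be non-negative")
  if (mu_s < 0) stop("mu_s must be non-negative")
  if (g < -1 || g > 1) stop("g must lie in [-1, 1]")
  structure(list(mu_a = mu_a, mu_s = mu_s, g = g),
            class = "optical_properties")
}

#' @export
print.optical_properties <- function(x, ...) {
  cat(sprintf("optical properties: mu_a = %.4g mm^-1, mu_s = %.4g mm^-1, g = %.4g\n",
              x$mu_a, x$mu_s, x$g))
  invisible(x)
}

#' Skin pigmentation level
#'
#' Pigmentation is modeled as the melanosome volume fraction `fmel` of the
#' basal epidermal layer. The named levels are light (4%), moderate (15%)
#' and heavy (50%); arbitrary fractions in (0, 1) are accepted for custom
#' use.
#'
#' @param level `"light"`, `"moderate"`, `"heavy"`, or a numeric melanosome
#'   volume fraction in (0, 1).
#' @return List with fields `fmel` and `label`.
#' @export
pigmentation <- function(level = "light") {
  named <- c(light = 0.04, moderate = 0.15, heavy = 0.50)
  if (is.character(level)) {
    level <- match.arg(level, names(named))
    out <- list(fmel = unname(named[level]), label = level)
  } else {
    stopifnot(is.numeric(level), length(level) == 1L)
    if (level <= 0 || level >= 1) stop("fmel must lie in (0, 1)")
    lab <- names(named)[match(level, named)]
    out <- list(fmel = level, label = if (is.na(lab)) "custom" else lab)
  }
  class(out) <- "pigmentation"
  out
}

.check_wavelength <- function(wavelength) {
  stopifnot(is.numeric(wavelength), length(wavelength) >= 1L)
  if (any(wavelength < 400 | wavelength > 1100))
    stop("wavelength must lie in [400, 1100] nm")
  invisible(wavelength)
}

#' Baseline absorption of melaninless epidermis and bloodless dermis
#'
#' Empirical wavelength dependence
#' `mu_a = 0.0244 + 8.53 * exp(-(lambda - 154) / 66.2)` (mm^-1).
#'
#' @param wavelength Wavelength in nm, in [400, 1100].
#' @return Absorption coefficient (mm^-1).
#' @export
mu_a_baseline <- function(wavelength) {
  .check_wavelength(wavelength)
  0.0244 + 8.53 * exp(-(wavelength - 154) / 66.2)
}

#' Absorption coefficient of a single melanosome
#'
#' Power law `mu_a = 6.6e10 * lambda^-3.33` (mm^-1).
#'
#' @inheritParams mu_a_baseline
#' @return Absorption coefficient (mm^-1).
#' @export
mu_a_melanosome <- function(wavelength) {
  .check_wavelength(wavelength)
  6.6e10 * wavelength^-3.33
}

#' Absorption coefficient of the basal epidermal layer
#'
#' Volume-weighted mixture of melanosome and baseline absorption:
#' `fmel * mu_a_mel + (1 - fmel) * mu_a_base`.
#'
#' @inheritParams mu_a_baseline
#' @param fmel Melanosome volume fraction in [0, 1].
#' @return Absorption coefficient (mm^-1).
#' @export
mu_a_basal <- function(wavelength, fmel) {
  stopifnot(is.numeric(fmel))
  if (any(fmel < 0 | fmel > 1)) stop("fmel must lie in [0, 1]")
  fmel * mu_a_melanosome(wavelength) + (1 - fmel) * mu_a_baseline(wavelength)
}

#' Default skin scattering anisotropy
#'
#' The model's skin anisotropy is 0.80 in the pulsed-dye-laser band and
#' 0.91 in the near infrared; the crossover is placed at 650 nm.
#'
#' @inheritParams mu_a_baseline
#' @return Anisotropy factor g.
#' @export
skin_anisotropy <- function(wavelength) {
  .check_wavelength(wavelength)
  ifelse(wavelength <= 650, 0.80, 0.91)
}

#' Scattering coefficient of skin (epidermis, basal layer and dermis)
#'
#' Two-term power law for the reduced scattering, divided by (1 - g):
#' `mu_s = (2e4 * lambda^-1.5 + 2e11 * lambda^-4) / (1 - g)`.
#'
#' @inheritParams mu_a_baseline
#' @param g Scattering anisotropy, strictly less than 1.  Defaults to
#'   [skin_anisotropy()] at the requested wavelength.
#' @return Scattering coefficient (mm^-1).
#' @export
mu_s_skin <- function(wavelength, g = skin_anisotropy(wavelength)) {
  .check_wavelength(wavelength)
  if (any(g >= 1)) stop("g must be < 1 (mu_s diverges as g -> 1)")
  (2e4 * wavelength^-1.5 + 2e11 * wavelength^-4) / (1 - g)
}

#' Blood optical properties at the two treatment wavelengths
#'
#' Literature values for whole blood at 45% hematocrit and 70% oxygen
#' saturation.  Only 585 nm and 755 nm are tabulated; other wavelengths
#' are out of scope.
#'
#' @param wavelength 585 or 755 (nm).
#' @return An [optical_properties()] object.
#' @export
blood_properties <- function(wavelength) {
  tab <- list(`585` = c(17.91, 76.05, 0.970),
              `755` = c(0.44, 79.85, 0.983))
  key <- as.character(wavelength)
  if (!key %in% names(tab))
    stop("blood optical properties are tabulated only at 585 and 755 nm")
  v <- tab[[key]]
  optical_properties(v[1], v[2], v[3])
}

# Scattering constants of the erythrocyte-derived particles at 755 nm:
# micron-sized (~4 um mean diameter) scatter strongly forward, nano-sized
# (~92 nm) weakly.
.net_scatter <- list(micro = c(mu_s = 2.20, g = 0.99),
                     nano  = c(mu_s = 0.06, g = 0.55))

# Slope of the linear relation between ICG concentration in the
# fabrication buffer (uM) and the particle absorption coefficient (mm^-1).
.icg_slope <- 17.8

#' ICG-loaded erythrocyte-derived particle formulation
#'
#' Describes a suspension of NIR erythrocyte-derived transducers (NETs)
#' inside a vessel: the particle size class (`micro` ~ 4 um, `nano` ~ 92 nm),
#' their volume fraction in the vessel, and their absorption coefficient.
#' The absorption may be given directly (`mu_a_nets`), through the ICG
#' concentration of the fabrication buffer (`icg_conc`, via the linear
#' calibration `[ICG] = 17.8 * mu_a_NETs`), or through a target effective
#' vessel absorption (`target_mu_a_bv`, inverted through the volume-mixing
#' rule against the blood absorption at `wavelength`).
#'
#' @param kind `"micro"` or `"nano"`.
#' @param f_nets Volume fraction of particles in the vessel (0 to 1);
#'   the study uses 0.10 or 0.25.
#' @param mu_a_nets Particle absorption coefficient (mm^-1), or `NULL`.
#' @param icg_conc ICG concentration in the fabrication buffer (uM), or `NULL`.
#' @param target_mu_a_bv Desired effective vessel absorption (mm^-1), or `NULL`.
#' @param wavelength Wavelength (nm) used to resolve `target_mu_a_bv`;
#'   default 755.
#' @return List of class `net_formulation` with fields `kind`, `f_nets`,
#'   `mu_a_nets`, `mu_s_nets`, `g_nets`, `icg_conc`.
#' @export
net_formulation <- function(kind = c("micro", "nano"), f_nets = 0.10,
                            mu_a_nets = NULL, icg_conc = NULL,
                            target_mu_a_bv = NULL, wavelength = 755) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(f_nets), length(f_nets) == 1L)
  if (f_nets < 0 || f_nets > 1) stop("f_nets must lie in [0, 1]")
  n_given <- sum(!is.null(mu_a_nets), !is.null(icg_conc), !is.null(target_mu_a_bv))
  if (n_given != 1L)
    stop("give exactly one of mu_a_nets, icg_conc, target_mu_a_bv")
  if (!is.null(target_mu_a_bv)) {
    blood <- blood_properties(wavelength)
    icg_conc <- icg_for_target_mu_a(target_mu_a_bv, f_nets, blood$mu_a)
    mu_a_nets <- icg_conc / .icg_slope
  } else if (!is.null(icg_conc)) {
    mu_a_nets <- icg_conc / .icg_slope
  } else {
    icg_conc <- .icg_slope * mu_a_nets
  }
  if (mu_a_nets < 0) stop("mu_a_nets must be non-negative")
  sc <- .net_scatter[[kind]]
  structure(list(kind = kind, f_nets = f_nets, mu_a_nets = mu_a_nets,
                 mu_s_nets = unname(sc["mu_s"]), g_nets = unname(sc["g"]),
                 icg_conc = icg_conc),
            class = "net_formulation")
}

#' @export
print.net_formulation <- function(x, ...) {
  cat(sprintf("%s-sized NETs: f = %.0f%%, mu_a,NETs = %.3g mm^-1 ([ICG] = %.0f uM), mu_s = %.3g mm^-1, g = %.2f\n",
              x$kind, 100 * x$f_nets, x$mu_a_nets, x$icg_conc, x$mu_s_nets, x$g_nets))
  invisible(x)
}

#' Optical screening correction of a blood vessel
#'
#' Correction factor for the reduced effectiveness of blood absorption in
#' vessels of finite radius:
#' `C = 0.039 + 0.486*exp(-mu_a*r/0.193) + 0.468*exp(-mu_a*r/0.914)`.
#'
#' Unit convention: the product is formed with `mu_a_blood` in mm^-1 and
#' `r_um` in micrometers; this is the convention under which the printed
#' constants reproduce the tabulated depth-resolved dermal absorption
#' values, and it is the one adopted throughout the package.
#'
#' @param mu_a_blood Blood absorption coefficient (mm^-1), >= 0.
#' @param r_um Mean vessel radius (um), > 0.
#' @return Dimensionless screening factor in (0, 1).
#' @export
vessel_screening_factor <- function(mu_a_blood, r_um) {
  stopifnot(is.numeric(mu_a_blood), is.numeric(r_um))
  if (any(mu_a_blood < 0)) stop("mu_a_blood must be non-negative")
  if (any(r_um <= 0)) stop("r_um must be positive")
  x <- mu_a_blood * r_um
  0.039 + 0.486 * exp(-x / 0.193) + 0.468 * exp(-x / 0.914)
}

#' Depth-binned vessel statistics for the adjusted dermis
#'
#' Mean vessel radius and fractional blood-vessel volume of the PWS
#' plexus per subsurface depth bin, used to adjust the dermal absorption
#' of the simulated layered geometry.
#'
#' @return Data frame with columns `z_min`, `z_max` (um), `r_um` (um),
#'   `f_frac` (dimensionless).
#' @export
dermis_depth_bins <- function() {
  data.frame(
    z_min = c(60, 260, 460, 660, 860, 1060),
    z_max = c(260, 460, 660, 860, 1060, 2000),
    r_um  = c(25, 37, 34, 27, 24, 24),
    f_frac = c(0.052, 0.080, 0.038, 0.025, 0.020, 0.015)
  )
}

#' Adjusted dermal absorption for one depth bin
#'
#' Screening-corrected mixture
#' `mu_a,der = f_i * C_i * mu_a,blood + (1 - f_i) * mu_a,base`,
#' accounting for attenuation by the remaining plexus vessels within the
#' bin.
#'
#' @inheritParams mu_a_baseline
#' @param bin One row of [dermis_depth_bins()] (or any list with `r_um`
#'   and `f_frac`).
#' @param blood [optical_properties()] of blood at `wavelength`; defaults
#'   to [blood_properties()].
#' @return Absorption coefficient (mm^-1).
#' @export
mu_a_dermis_adjusted <- function(wavelength, bin,
                                 blood = blood_properties(wavelength)) {
  stopifnot(!is.null(bin$r_um), !is.null(bin$f_frac))
  if (bin$f_frac < 0 || bin$f_frac >= 1) stop("f_frac must lie in [0, 1)")
  ci <- vessel_screening_factor(blood$mu_a, bin$r_um)
  bin$f_frac * ci * blood$mu_a + (1 - bin$f_frac) * mu_a_baseline(wavelength)
}

#' Dermal absorption for imported (OCT-style) geometries
#'
#' Plain volume mixture `f_blood * mu_a,blood + (1 - f_blood) * mu_a,base`
#' with the healthy-dermis capillary blood fraction (default 0.2%).  No
#' screening adjustment is applied because the resolved vessels are
#' represented explicitly in imported geometries.
#'
#' @inheritParams mu_a_dermis_adjusted
#' @param f_blood Volume fraction of blood in healthy dermis, default 0.002.
#' @return Absorption coefficient (mm^-1).
#' @export
mu_a_dermis_oct <- function(wavelength, f_blood = 0.002,
                            blood = blood_properties(wavelength)) {
  stopifnot(is.numeric(f_blood))
  if (f_blood < 0 || f_blood > 1) stop("f_blood must lie in [0, 1]")
  if (f_blood == 0) return(mu_a_baseline(wavelength))  # no blood term to look up
  f_blood * blood$mu_a + (1 - f_blood) * mu_a_baseline(wavelength)
}

#' Effective optical properties of a vessel containing particles
#'
#' Each of mu_a, mu_s and g of the blood/particle mixture is a volume-
#' fraction-weighted linear combination of the pure-blood and pure-particle
#' values.
#'
#' @param blood [optical_properties()] of blood.
#' @param net A [net_formulation()], or `NULL` for plain blood.
#' @return An [optical_properties()] object.
#' @export
vessel_effective_properties <- function(blood, net = NULL) {
  stopifnot(inherits(blood, "optical_properties"))
  if (is.null(net)) return(blood)
  stopifnot(inherits(net, "net_formulation"))
  f <- net$f_nets
  optical_properties(
    mu_a = (1 - f) * blood$mu_a + f * net$mu_a_nets,
    mu_s = (1 - f) * blood$mu_s + f * net$mu_s_nets,
    g    = (1 - f) * blood$g    + f * net$g_nets
  )
}

#' ICG concentration needed for a target vessel absorption
#'
#' Inverts the volume-mixing rule for the particle absorption required to
#' reach a target effective vessel absorption and maps it to the ICG
#' concentration of the fabrication buffer through the linear calibration:
#' `[ICG] = 17.8 * (mu_a,BV - (1 - f) * mu_a,blood) / f` (uM).
#'
#' @param target_mu_a_bv Desired effective vessel absorption (mm^-1).
#' @param f_nets Particle volume fraction in the vessel, in (0, 1].
#' @param mu_a_blood Blood absorption coefficient (mm^-1).
#' @return ICG concentration (uM).
#' @export
icg_for_target_mu_a <- function(target_mu_a_bv, f_nets, mu_a_blood) {
  stopifnot(is.numeric(target_mu_a_bv), is.numeric(f_nets), is.numeric(mu_a_blood))
  if (f_nets <= 0 || f_nets > 1) stop("f_nets must lie in (0, 1]")
  floor_mu_a <- (1 - f_nets) * mu_a_blood
  if (target_mu_a_bv < floor_mu_a)
    stop(sprintf(paste0("target mu_a,BV = %.3g mm^-1 is infeasible: particles only add ",
                        "absorption, so the minimum achievable mu_a,BV is ",
                        "(1 - f) * mu_a,blood = %.3g mm^-1"),
                 target_mu_a_bv, floor_mu_a))
  .icg_slope * (target_mu_a_bv - floor_mu_a) / f_nets
}

#' Tabulate computed optical properties at one wavelength
#'
#' Convenience table (one row per material) of the model's skin, blood
#' and vessel optical properties, as used to parameterize a simulation.
#'
#' @inheritParams mu_a_baseline
#' @param pigmentation A [pigmentation()] level.
#' @param net Optional [net_formulation()] for the vessel contents.
#' @return Data frame with columns `material`, `mu_a`, `mu_s`, `g`.
#' @export
skin_optical_table <- function(wavelength, pigmentation = pwstherm::pigmentation("light"),
                               net = NULL) {
  g <- skin_anisotropy(wavelength)
  mus <- mu_s_skin(wavelength, g)
  blood <- blood_properties(wavelength)
  bv <- vessel_effective_properties(blood, net)
  data.frame(
    material = c("melaninless epidermis", "basal layer", "dermis", "blood", "vessel contents"),
    mu_a = c(mu_a_baseline(wavelength), mu_a_basal(wavelength, pigmentation$fmel),
             mu_a_dermis_oct(wavelength, blood = blood), blood$mu_a, bv$mu_a),
    mu_s = c(mus, mus, mus, blood$mu_s, bv$mu_s),
    g = c(g, g, g, blood$g, bv$g)
  )
}
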