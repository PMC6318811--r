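# Photon transport: R-facing interface over the compiled voxel Monte
# Carlo kernel, plus normalization of raw deposition tallies into a
# volumetric energy-deposition field per unit incident radiant exposure.

#' Laser beam description
#'
#' @param wavelength Wavelength (nm); 585 or 755 in the study scenarios.
#' @param diameter_mm Flat-top beam diameter (mm); 6 for the simulated
#'   layered geometry, 8 for imported (OCT-style) geometries.
#' @param radiant_exposure Incident dosage D (J/cm^2), or `NULL` if set
#'   later.
#' @param pulse_duration Pulse duration (s), default 3 ms.
#' @return List of class `beam`.
#' @export
beam <- function(wavelength, diameter_mm = 6, radiant_exposure = NULL,
                 pulse_duration = 3e-3) {
  .check_wavelength(wavelength)
  stopifnot(diameter_mm > 0, pulse_duration > 0)
  if (!is.null(radiant_exposure) && radiant_exposure <= 0)
    stop("radiant_exposure must be positive")
  structure(list(wavelength = wavelength, diameter_mm = diameter_mm,
                 radiant_exposure = radiant_exposure,
                 pulse_duration = pulse_duration, profile = "flattop"),
            class = "beam")
}

# label -> property lookup tables, 0-based for the kernel
.prop_luts <- function(model) {
  maxlab <- max(model$props$label)
  mua <- mus <- g <- numeric(maxlab + 1L)
  mua[model$props$label + 1L] <- model$props$mu_a
  mus[model$props$label + 1L] <- model$props$mu_s
  g[model$props$label + 1L] <- model$props$g
  list(mua = mua, mus = mus, g = g)
}

# area of the disk of radius R intersected with |x|<=hx, |y|<=hy (mm^2)
.launch_area <- function(R, hx, hy) {
  xm <- min(R, hx)
  xs <- seq(-xm, xm, length.out = 4097L)
  chord <- 2 * pmin(hy, sqrt(pmax(0, R^2 - xs^2)))
  sum((chord[-1] + chord[-length(chord)]) / 2 * diff(xs))
}

#' Monte Carlo photon transport and energy deposition
#'
#' Launches photons with normal incidence, uniformly over the flat-top
#' beam disk, and propagates them with exponential free-path sampling
#' against the local extinction, Henyey-Greenstein deflection with the
#' local anisotropy, implicit-capture weight deposition (a fraction
#' mu_a/mu_t of the packet weight at every interaction) and Russian
#' roulette termination.  The tissue label map is edge-clamped laterally
#' (skin continues beyond the scored window), so photons only escape
#' through the top surface (diffuse reflection, Fresnel-weighted when
#' `fresnel = TRUE`) or the bottom of the domain.
#'
#' Scoring estimators:
#' \describe{
#'   \item{`"slab"`}{(default for 2-D models with vessels) deposit into
#'     the (x, z) grid when the photon lies within `|y| <= slab_half_mm`;
#'     unbiased estimate of the center-plane deposition density.}
#'   \item{`"planar"`}{(default for laterally homogeneous 2-D models)
#'     photons launch at the beam axis and deposit into depth bins when
#'     their radial displacement is within the beam radius; this is the
#'     exact center-axis deposition under a flat-top disk beam and has
#'     far lower variance in thin layers.}
#'   \item{`"ysum"`}{deposit into the (x, z) grid regardless of y
#'     (deposition per unit y length); mainly for energy bookkeeping.}
#'   \item{`"xyz"`}{full 3-D scoring for 3-D models; photon launch is
#'     restricted to the beam-disk intersection with the scored window
#'     padded by `launch_margin_mm`, and the incident energy is
#'     normalized to that restricted launch area.}
#' }
#'
#' The returned field `S` is the deposition density per unit incident
#' radiant exposure, in mm^-1: multiplying by D (J/mm^2) gives the
#' volumetric energy deposition (J/mm^3).
#'
#' @param model A `tissue_model` whose optical properties are at the beam
#'   wavelength.
#' @param beam A [beam()].
#' @param n_photons Number of photon packets (default 1e5, the reduced
#'   "fast" setting; 1e6 for full fidelity).
#' @param seed Integer seed; runs are exactly reproducible.
#' @param mode Scoring mode (see Details), or `"auto"`.
#' @param slab_half_mm Half-thickness of the central scoring slab (mm).
#' @param fresnel Apply specular/internal Fresnel reflection at the
#'   air-tissue surface (refractive index `n_tissue` vs 1)?
#' @param n_tissue Tissue refractive index, default 1.37.
#' @param launch_margin_mm Launch-window padding for `"xyz"` mode (mm).
#' @return Object of class `source_grid`: fields `S` (see above; a
#'   `nz x nx` matrix, a length-`nz` vector for planar scoring, or a 3-D
#'   array), `stats` (absorbed/reflected/transmitted weight fractions),
#'   `mode`, `grid`, `beam`, `n_photons`, `seed`.
#' @export
run_mc <- function(model, beam, n_photons = 1e5, seed = 1L,
                   mode = c("auto", "slab", "planar", "ysum", "xyz"),
                   slab_half_mm = 0.5, fresnel = TRUE, n_tissue = 1.37,
                   launch_margin_mm = 1.5) {
  stopifnot(inherits(model, "tissue_model"), inherits(beam, "beam"))
  if (model$wavelength != beam$wavelength)
    stop("model optical properties and beam wavelength disagree")
  mode <- match.arg(mode)
  lab <- model$labels
  is3d <- length(dim(lab)) == 3L
  if (mode == "auto") {
    if (is3d) mode <- "xyz"
    else if (all(lab == lab[, 1])) mode <- "planar"
    else mode <- "slab"
  }
  if (is3d && mode != "xyz") stop("3-D models require mode = 'xyz'")
  if (!all(unique(as.integer(lab)) %in% model$props$label))
    stop("label map contains labels with no optical properties")
  luts <- .prop_luts(model)
  g <- model$grid
  ze_mm <- g$z_edges / 1000
  dx_mm <- g$dx / 1000
  x0_mm <- g$x_edges[1] / 1000
  Rb <- beam$diameter_mm / 2
  hx <- hy <- Inf
  y0_mm <- 0; dy_mm <- 1
  if (mode == "planar") {
    kl <- as.integer(lab[, 1]); kd <- c(g$nz, 1L)
  } else if (mode == "xyz") {
    kl <- as.integer(lab); kd <- dim(lab)
    y0_mm <- g$y_edges[1] / 1000
    dy_mm <- g$dy / 1000
    hx <- g$nx * dx_mm / 2 + launch_margin_mm
    hy <- g$ny * dy_mm / 2 + launch_margin_mm
  } else {
    kl <- as.integer(lab); kd <- dim(lab)
  }
  kmode <- switch(mode, planar = 1L, xyz = 2L, 0L)
  res <- .mc_kernel(kl, as.integer(kd), kmode, luts$mua, luts$mus, luts$g,
                    ze_mm, x0_mm, dx_mm, y0_mm, dy_mm, Rb,
                    as.integer(n_photons), as.double(seed),
                    fresnel, n_tissue,
                    if (mode == "slab") slab_half_mm else Inf,
                    hx, hy, 1e-4, 0.1)
  dz_mm <- g$dz / 1000
  A_launch <- .launch_area(Rb, hx, hy)
  N <- n_photons
  if (mode == "planar") {
    S <- res$dep / (N * dz_mm)
  } else if (mode == "slab") {
    S <- matrix(res$dep, g$nz, g$nx) * A_launch /
      (N * dx_mm * dz_mm * 2 * slab_half_mm)
  } else if (mode == "ysum") {
    S <- matrix(res$dep, g$nz, g$nx) * A_launch / (N * dx_mm * dz_mm)
  } else {
    S <- array(res$dep, dim(lab)) * A_launch /
      (N * dx_mm * dy_mm * dz_mm)
  }
  structure(list(S = S, mode = mode,
                 stats = list(absorbed = res$absorbed_total,
                              absorbed_scored = res$absorbed_scored,
                              reflected = res$reflected,
                              transmitted = res$transmitted,
                              roulette_lost = res$roulette_lost),
                 grid = g, beam = beam, n_photons = n_photons, seed = seed,
                 slab_half_mm = slab_half_mm, launch_area_mm2 = A_launch,
                 fresnel = fresnel, n_tissue = n_tissue),
            class = "source_grid")
}

#' @export
print.source_grid <- function(x, ...) {
  cat(sprintf("MC source grid (%s scoring, %g photons, seed %s)\n",
              x$mode, x$n_photons, format(x$seed)))
  cat(sprintf("  absorbed %.4f | reflected %.4f | transmitted %.4f | roulette %.1e\n",
              x$stats$absorbed, x$stats$reflected, x$stats$transmitted,
              x$stats$roulette_lost))
  invisible(x)
}

#' Convert a deposition field to a volumetric power density
#'
#' Multiplies the per-unit-dosage deposition density by the incident
#' radiant exposure and divides by the pulse duration, yielding the heat
#' source term S (W m^-3) of the bioheat equation.  Planar (depth-only)
#' sources are expanded across `nx` columns when requested.
#'
#' @param source A `source_grid` from [run_mc()].
#' @param radiant_exposure Incident dosage (J/cm^2); defaults to the
#'   beam's.
#' @param pulse_duration Pulse duration (s); defaults to the beam's.
#' @param nx Number of columns to expand a planar source to (default 1).
#' @return Matrix (or array) of power density in W m^-3.
#' @export
source_to_power_density <- function(source, radiant_exposure = NULL,
                                    pulse_duration = NULL, nx = NULL) {
  stopifnot(inherits(source, "source_grid"))
  D <- if (is.null(radiant_exposure)) source$beam$radiant_exposure else radiant_exposure
  tau <- if (is.null(pulse_duration)) source$beam$pulse_duration else pulse_duration
  if (is.null(D)) stop("radiant exposure not set")
  stopifnot(D > 0, tau > 0)
  S <- source$S
  if (source$mode == "planar") {
    nx <- if (is.null(nx)) 1L else nx
    S <- matrix(S, length(S), nx)
  }
  # S [mm^-1] * D [J/cm^2 = 1e4 J/m^2] * 1e3 [mm^-1 -> m^-1] / tau
  S * D * 1e7 / tau
}
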