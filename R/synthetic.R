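# Synthetic inputs: an OCT-like vascular plexus volume (ground-truth
# binary mask plus a noisy intensity rendering) and the canonical
# single-vessel treatment scenarios.

# separable Gaussian blur along each axis of a 3-D array (sigma in voxels)
.gauss_blur3 <- function(a, sigma) {
  if (sigma <= 0) return(a)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2)); k <- k / sum(k)
  for (ax in 1:3) {
    perm <- switch(ax, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
    b <- aperm(a, perm); d <- dim(b)
    m <- matrix(b, d[1], d[2] * d[3])
    # zero-padded FIR along columns
    out <- matrix(0, d[1], ncol(m))
    for (j in seq_along(k)) {
      sh <- j - r - 1L
      src <- seq_len(d[1]) + sh
      ok <- src >= 1L & src <= d[1]
      out[ok, ] <- out[ok, ] + k[j] * m[src[ok], ]
    }
    a <- aperm(array(out, d), order(perm))
  }
  a
}

#' Generate a synthetic vascular plexus volume
#'
#' Emulates the statistical structure of a dermal PWS plexus as imaged
#' by OCT angiography: straight tubes running predominantly along y with
#' random oblique tilts, diameters drawn from a log-normal centered on
#' `diameter_mode` and clipped to `diameter_range`, and vessel centers
#' no deeper than `depth_max`.  The intensity rendering is the
#' ground-truth mask blurred by a small Gaussian PSF, carried on a dim
#' background, multiplied by gamma-distributed speckle (mean 1, shape
#' `speckle_shape`) and offset by an additive slow row drift (bulk-motion
#' surrogate, constant along x and slowly varying along y).
#'
#' Defaults give a 2 x 2 x 1.4 mm volume at 10 um pitch that builds in
#' seconds.  Vessels that would exit the volume are clipped at its faces.
#'
#' @param extent_um Length-3 physical extent (um) in (x, y, z).
#' @param pitch_um Isotropic voxel pitch (um), default 10.
#' @param n_vessels Number of tubes, default 8 (with the default extent
#'   and diameter distribution this gives a vessel volume fraction around
#'   10-15%, a dense dermal plexus).
#' @param diameter_range Allowed diameter band (um), default c(60, 650).
#' @param diameter_mode Mode of the diameter distribution (um), default 200.
#' @param depth_max Maximum vessel-axis depth (um), default 1000.
#' @param max_tilt_deg Maximum oblique tilt of a tube from the y axis.
#' @param psf_sigma_vox Gaussian PSF sigma (voxels), default 0.8.
#' @param speckle_shape Gamma shape of the multiplicative speckle.
#' @param background Background intensity level, default 0.05.
#' @param drift_amp Amplitude of the additive row drift, default 0.15.
#' @param seed Integer seed; generation is bit-reproducible.
#' @return List with `intensity` (array, `(x, y, z)`), `mask`
#'   (ground-truth 0/1 array), `pitch_um`, and `params` (the vessel
#'   table: center, direction, diameter).
#' @export
make_plexus_volume <- function(extent_um = c(2000, 2000, 1400), pitch_um = 10,
                               n_vessels = 8, diameter_range = c(60, 650),
                               diameter_mode = 200, depth_max = 1000,
                               max_tilt_deg = 25, psf_sigma_vox = 0.8,
                               speckle_shape = 4, background = 0.05,
                               drift_amp = 0.15, seed = 1L) {
  stopifnot(length(extent_um) == 3L, pitch_um > 0, n_vessels >= 0)
  set.seed(seed)
  nd <- pmax(1L, round(extent_um / pitch_um))
  nx <- nd[1]; ny <- nd[2]; nz <- nd[3]
  cx <- (seq_len(nx) - 0.5) * pitch_um
  cy <- (seq_len(ny) - 0.5) * pitch_um
  cz <- (seq_len(nz) - 0.5) * pitch_um
  mask <- array(0L, nd)
  vess <- NULL
  if (n_vessels > 0) {
    diam <- stats::rlnorm(n_vessels, log(diameter_mode), 0.35)
    diam <- pmin(pmax(diam, diameter_range[1]), diameter_range[2])
    tilt <- (max_tilt_deg * pi / 180) * stats::runif(n_vessels)
    azim <- stats::runif(n_vessels, 0, 2 * pi)
    x0 <- stats::runif(n_vessels, 0, extent_um[1])
    z0 <- stats::runif(n_vessels, pmin(diam / 2, depth_max / 2),
                       pmax(diam / 2, depth_max - diam / 2))
    y0 <- extent_um[2] / 2
    # direction: mostly +y, tilted into x and z
    dirs <- cbind(sin(tilt) * cos(azim), cos(tilt), sin(tilt) * sin(azim))
    X <- array(rep(cx, ny * nz), nd)
    Y <- array(rep(rep(cy, each = nx), nz), nd)
    Z <- array(rep(cz, each = nx * ny), nd)
    for (i in seq_len(n_vessels)) {
      a <- c(x0[i], y0, z0[i]); d <- dirs[i, ]
      px <- X - a[1]; py <- Y - a[2]; pz <- Z - a[3]
      t <- px * d[1] + py * d[2] + pz * d[3]
      d2 <- (px - t * d[1])^2 + (py - t * d[2])^2 + (pz - t * d[3])^2
      mask[d2 <= (diam[i] / 2)^2] <- 1L
    }
    vess <- data.frame(x0 = x0, y0 = y0, z0 = z0,
                       dx = dirs[, 1], dy = dirs[, 2], dz = dirs[, 3],
                       diameter = diam)
  }
  clean <- .gauss_blur3(array(as.numeric(mask), nd), psf_sigma_vox)
  speckle <- array(stats::rgamma(prod(nd), shape = speckle_shape,
                                 rate = speckle_shape), nd)
  drift_y <- drift_amp * sin(2 * pi * 3 * seq_len(ny) / ny +
                             stats::runif(1, 0, 2 * pi))
  drift <- array(rep(rep(drift_y, each = nx), nz), nd)
  intensity <- (clean + background) * speckle + pmax(drift, 0)
  list(intensity = intensity, mask = mask, pitch_um = rep(pitch_um, 3),
       params = list(vessels = vess, seed = seed,
                     speckle_shape = speckle_shape, background = background,
                     drift_amp = drift_amp, psf_sigma_vox = psf_sigma_vox))
}

#' Canonical single-vessel treatment scenario
#'
#' Builds the standard layered-skin model with one 200-um-class vessel
#' running along y at the beam center: the geometry used throughout the
#' simulated-vessel damage studies (vessel top at 500 or 800 um).
#'
#' @param depth Depth of the vessel top below the surface (um).
#' @param diameter Vessel diameter (um), default 200.
#' @param pigmentation A [pigmentation()] level or its name.
#' @param net Optional [net_formulation()] for the vessel contents.
#' @param wavelength Wavelength (nm).
#' @param width_x Lateral domain width (um), default 3000.
#' @param dx,dz_dermis Grid pitch (um).
#' @return A 2-D `tissue_model`.
#' @export
make_single_vessel_case <- function(depth = 500, diameter = 200,
                                    pigmentation = "light", net = NULL,
                                    wavelength = 585, width_x = 3000,
                                    dx = 10, dz_dermis = 10) {
  if (is.character(pigmentation)) pigmentation <- pwstherm::pigmentation(pigmentation)
  build_layered_model(width_x = width_x, dx = dx, dz_dermis = dz_dermis,
                      pigmentation = pigmentation,
                      vessels = list(cyl_vessel(depth, diameter)),
                      wavelength = wavelength, use_adjusted_dermis = TRUE,
                      net = net)
}
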