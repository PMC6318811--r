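# Arrhenius rate-process quantification of thermal damage and the
# threshold-dosage search for epidermal injury.

#' Arrhenius damage integral
#'
#' Computes the damage index `Omega(x, z) = A int exp(-E / (R T(t))) dt`
#' per node (temperatures converted to kelvin in the integrand), using
#' the material parameters of each node's tissue class: bulk-skin
#' parameters for all non-vessel tissue, blood parameters for vessel
#' lumen.  `Omega = 1` corresponds to irreversible damage of 63% of the
#' tissue.
#'
#' By default the integrals accumulated trapezoidally during the heat
#' solve are used.  If the field retains its full history
#' (`store_history = TRUE`), custom parameters can be supplied via
#' `params_by_class` and the integral is recomputed from the stored
#' temperatures (trapezoid on the integrand) over the field's damage
#' window.
#'
#' @param field A `temperature_field` from [solve_heat()].
#' @param model The `tissue_model` the field was solved on.
#' @param params_by_class Optional list like [arrhenius_params()] with
#'   elements `skin` and `blood` (requires stored history).
#' @return Object of class `damage_field`: `omega` matrix, logical
#'   `mask` (`omega >= 1`), and the label map used.
#' @export
damage_integral <- function(field, model, params_by_class = NULL) {
  stopifnot(inherits(field, "temperature_field"), inherits(model, "tissue_model"))
  lab <- model$labels
  if (length(dim(lab)) != 2L) stop("damage_integral expects a 2-D model")
  if (!all(dim(lab) == dim(field$T_final)))
    stop("temperature field and model grids disagree")
  cls <- matrix(.label_class(as.integer(lab)), nrow(lab), ncol(lab))
  vessel <- cls == "vessel"
  if (is.null(params_by_class)) {
    omega <- field$arr$skin
    omega[vessel] <- field$arr$blood[vessel]
  } else {
    if (is.null(field$history))
      stop("custom Arrhenius parameters require a field solved with store_history = TRUE")
    R_gas <- arrhenius_params()$R_gas
    tms <- field$history_times_ms
    win <- field$damage_window_ms
    keep <- which(tms >= win[1] - 1e-9 & tms <= win[2] + 1e-9)
    integ <- function(p) {
      acc <- 0
      for (i in seq_along(keep)[-1]) {
        f1 <- p$A * exp(-p$E / (R_gas * (field$history[[keep[i - 1]]] + 273.15)))
        f2 <- p$A * exp(-p$E / (R_gas * (field$history[[keep[i]]] + 273.15)))
        acc <- acc + 0.5 * (f1 + f2) * (tms[keep[i]] - tms[keep[i - 1]]) / 1000
      }
      matrix(acc, nrow(lab), ncol(lab))
    }
    omega <- integ(params_by_class$skin)
    if (any(vessel)) omega[vessel] <- integ(params_by_class$blood)[vessel]
  }
  structure(list(omega = omega, mask = omega >= 1, labels = lab,
                 grid = field$grid),
            class = "damage_field")
}

#' @export
print.damage_field <- function(x, ...) {
  cat(sprintf("damage field: max Omega = %.3g, %d/%d nodes with Omega >= 1\n",
              max(x$omega), sum(x$mask), length(x$mask)))
  invisible(x)
}

#' Percent photothermal damage of the vessel cross-section
#'
#' Fraction (in percent) of vessel-lumen nodes whose damage index
#' reaches 1, i.e. damaged cross-sectional area over total vessel
#' cross-sectional area; optionally restricted to vessels above a depth
#' limit.
#'
#' @param damage A `damage_field`.
#' @param model The matching `tissue_model`.
#' @param depth_limit_um Only count vessel nodes with depth
#'   `z <= depth_limit_um` (e.g. 1000), or `NULL` for all.
#' @return Percent damage (0-100); `NA` if the model has no vessel nodes.
#' @export
percent_vessel_damage <- function(damage, model, depth_limit_um = NULL) {
  stopifnot(inherits(damage, "damage_field"))
  lab <- model$labels
  vessel <- lab == tissue_labels()[["vessel"]]
  if (!is.null(depth_limit_um))
    vessel <- vessel & (model$grid$z <= depth_limit_um)
  if (!any(vessel)) return(NA_real_)
  100 * sum(damage$mask & vessel) / sum(vessel)
}

#' Is any epidermal node thermally damaged?
#'
#' `TRUE` iff any node of the melaninless epidermis or the basal layer
#' reaches `Omega >= 1`.
#'
#' @inheritParams percent_vessel_damage
#' @return Logical flag.
#' @export
epidermis_damaged <- function(damage, model) {
  stopifnot(inherits(damage, "damage_field"))
  cls <- .label_class(as.integer(model$labels))
  epi <- cls %in% c("epidermis", "basal")
  any(damage$mask[epi])
}

#' Threshold incident dosage for epidermal damage
#'
#' Finds the threshold dosage D_th for the onset of epidermal thermal
#' damage in a vessel-free layered skin, defined as the largest dosage
#' on a regular grid (default 1 J/cm^2 steps) for which no epidermal
#' node reaches `Omega = 1`.  The Monte Carlo source is computed once
#' (planar estimator, the geometry is laterally homogeneous) and scaled
#' linearly with dosage; the thermal and damage stages re-run per
#' candidate dosage, with a bisection over the dosage grid (Omega is
#' monotone in dosage for a fixed source).
#'
#' @param wavelength Wavelength (nm).
#' @param pigmentation A [pigmentation()] level.
#' @param beam A [beam()]; the radiant exposure field is ignored.
#' @param n_photons Photon packets for the one-off source computation.
#' @param seed Monte Carlo seed.
#' @param step_j_cm2 Dosage grid step (J/cm^2), default 1.
#' @param d_max Largest dosage considered (J/cm^2), default 64.
#' @param dx,dz_dermis Grid pitch (um) of the narrow solver column.
#' @param ... Further arguments passed to [solve_heat()].
#' @return List of class `dth_result`: `d_th` (J/cm^2; 0 with a warning
#'   if even the first grid point damages the epidermis), `source`, and
#'   `max_omega_at` (named vector of epidermal max Omega per probed
#'   dosage).
#' @export
find_threshold_dosage <- function(wavelength, pigmentation,
                                  beam = pwstherm::beam(wavelength),
                                  n_photons = 1e5, seed = 1L,
                                  step_j_cm2 = 1, d_max = 64,
                                  dx = 10, dz_dermis = 10, ...) {
  nxcol <- 4L
  model <- build_layered_model(width_x = nxcol * dx, dx = dx,
                               dz_dermis = dz_dermis,
                               pigmentation = pigmentation,
                               vessels = list(), wavelength = wavelength,
                               use_adjusted_dermis = TRUE)
  src <- run_mc(model, beam, n_photons = n_photons, seed = seed,
                mode = "planar")
  if (max(src$S) == 0) stop("no energy is absorbed: threshold dosage undefined")
  probe <- new.env(); probe$max_omega <- c()
  damaged_at <- function(d) {
    sw <- source_to_power_density(src, radiant_exposure = d,
                                  pulse_duration = beam$pulse_duration,
                                  nx = model$grid$nx)
    fld <- solve_heat(model, sw, ...)
    dmg <- damage_integral(fld, model)
    cls <- .label_class(as.integer(model$labels))
    epi <- cls %in% c("epidermis", "basal")
    probe$max_omega <- c(probe$max_omega,
                         stats::setNames(max(dmg$omega[epi]), format(d)))
    epidermis_damaged(dmg, model)
  }
  # exponential bracket, then bisection on the integer-step grid
  kmax <- floor(d_max / step_j_cm2)
  if (damaged_at(step_j_cm2)) {
    warning("epidermal damage already at the smallest grid dosage; returning 0")
    d_th <- 0
  } else {
    k_lo <- 1L  # largest known-safe multiple
    k_hi <- NA  # smallest known-damaging multiple
    k <- 2L
    while (k <= kmax) {
      if (damaged_at(k * step_j_cm2)) { k_hi <- k; break }
      k_lo <- k
      k <- min(kmax, k * 2L)
      if (k_lo == kmax) break
    }
    if (is.na(k_hi)) {
      if (k_lo == kmax)
        warning("no damaging dosage up to d_max; threshold censored at d_max")
      d_th <- k_lo * step_j_cm2
    } else {
      while (k_hi - k_lo > 1L) {
        k_mid <- (k_lo + k_hi) %/% 2L
        if (damaged_at(k_mid * step_j_cm2)) k_hi <- k_mid else k_lo <- k_mid
      }
      d_th <- k_lo * step_j_cm2
    }
  }
  structure(list(d_th = d_th, wavelength = wavelength,
                 pigmentation = pigmentation, source = src,
                 max_omega_at = probe$max_omega),
            class = "dth_result")
}

#' @export
print.dth_result <- function(x, ...) {
  cat(sprintf("threshold dosage: %g J/cm^2 (%g nm, fmel = %g%%)\n",
              x$d_th, x$wavelength, 100 * x$pigmentation$fmel))
  invisible(x)
}
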