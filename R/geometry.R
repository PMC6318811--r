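# Voxelized skin geometries.
#
# Conventions: z increases downward from the skin surface (z = 0), voxel
# intervals are half-open [edge_k, edge_{k+1}), and x = 0 is the beam
# center (symmetric lateral domain).  Internally, 2-D label maps are
# (nz x nx) matrices and 3-D label maps are (nz x nx x ny) arrays; user
# facing volumes (masks, intensities) use (x, y, z) axis order.

#' Tissue label codes
#'
#' Integer labels used in voxelized models: 1 melaninless epidermis,
#' 2 basal (melanosome-containing) layer, 3 dermis, 4 vessel lumen, and
#' 11-16 for the depth-binned adjusted dermis of simulated geometries.
#'
#' @return Named integer vector.
#' @export
tissue_labels <- function() {
  c(epidermis = 1L, basal = 2L, dermis = 3L, vessel = 4L)
}

.label_class <- function(label) {
  cls <- character(length(label))
  cls[label == 1L] <- "epidermis"
  cls[label == 2L] <- "basal"
  cls[label == 3L | (label >= 11L & label <= 16L)] <- "dermis"
  cls[label == 4L] <- "vessel"
  if (any(cls == "")) stop("unknown tissue label(s): ",
                           paste(unique(label[cls == ""]), collapse = ", "))
  cls
}

#' Thermal properties by tissue class
#'
#' All tissues share density 1200 kg m^-3 and specific heat
#' 3600 J kg^-1 C^-1; thermal conductivity is 0.26 W m^-1 C^-1 for the
#' epidermis (both layers) and 0.53 W m^-1 C^-1 for dermis and vessels.
#'
#' @return Data frame with columns `class`, `rho`, `C`, `kappa`.
#' @export
thermal_properties_table <- function() {
  data.frame(class = c("epidermis", "basal", "dermis", "vessel"),
             rho = 1200, C = 3600,
             kappa = c(0.26, 0.26, 0.53, 0.53))
}

#' Cylindrical vessel primitive
#'
#' A blood vessel modeled as a circular cylinder running parallel to the
#' y axis for the whole geometry length.
#'
#' @param top_depth Depth of the vessel top below the surface (um).
#' @param diameter Vessel diameter (um), > 0.
#' @param cx Lateral position of the vessel axis (um); default 0 (beam
#'   center).
#' @return List of class `cyl_vessel`.
#' @export
cyl_vessel <- function(top_depth, diameter, cx = 0) {
  stopifnot(is.numeric(top_depth), is.numeric(diameter), diameter > 0)
  structure(list(top_depth = top_depth, diameter = diameter, cx = cx),
            class = "cyl_vessel")
}

# z bin edges: dz_epi through the epidermis (default 5 um resolves the
# 15-um basal layer), dz_dermis below.
.make_z_edges <- function(depth_z, dz_epi = 5, dz_dermis = 10,
                          epi_total = 60) {
  stopifnot(depth_z > epi_total)
  c(seq(0, epi_total, by = dz_epi),
    seq(epi_total + dz_dermis, depth_z, by = dz_dermis))
}

.grid_from_edges <- function(width_x, dx, z_edges) {
  nx <- round(width_x / dx)
  x_edges <- seq(-width_x / 2, width_x / 2, length.out = nx + 1L)
  list(x = (x_edges[-1] + x_edges[-(nx + 1L)]) / 2, x_edges = x_edges,
       dx = dx, nx = nx,
       z_edges = z_edges, z = (z_edges[-1] + z_edges[-length(z_edges)]) / 2,
       dz = diff(z_edges), nz = length(z_edges) - 1L)
}

# Optical property rows for the labels present in a model.
.build_props <- function(labels_present, wavelength, pigmentation,
                         use_adjusted_dermis, f_blood, vessel_props) {
  g <- skin_anisotropy(wavelength)
  mus <- mu_s_skin(wavelength, g)
  bins <- dermis_depth_bins()
  blood <- blood_properties(wavelength)
  rows <- lapply(sort(labels_present), function(lab) {
    cls <- .label_class(lab)
    if (lab == 1L) mua <- mu_a_baseline(wavelength)
    else if (lab == 2L) mua <- mu_a_basal(wavelength, pigmentation$fmel)
    else if (lab == 3L) mua <- mu_a_dermis_oct(wavelength, f_blood, blood)
    else if (lab >= 11L) mua <- mu_a_dermis_adjusted(wavelength, bins[lab - 10L, ], blood)
    else if (lab == 4L) mua <- vessel_props$mu_a
    data.frame(label = lab, class = cls,
               mu_a = mua,
               mu_s = if (lab == 4L) vessel_props$mu_s else mus,
               g = if (lab == 4L) vessel_props$g else g)
  })
  do.call(rbind, rows)
}

.finish_model <- function(labels, grid, wavelength, pigmentation,
                          use_adjusted_dermis, f_blood, net, meta = list()) {
  blood <- blood_properties(wavelength)
  vessel_props <- vessel_effective_properties(blood, net)
  props <- .build_props(unique(as.integer(labels)), wavelength, pigmentation,
                        use_adjusted_dermis, f_blood, vessel_props)
  props <- merge(props, thermal_properties_table(), by = "class", sort = FALSE)
  props <- props[order(props$label),
                 c("label", "class", "mu_a", "mu_s", "g", "rho", "C", "kappa")]
  rownames(props) <- NULL
  structure(list(labels = labels, grid = grid, props = props,
                 wavelength = wavelength, pigmentation = pigmentation,
                 net = net, meta = meta),
            class = "tissue_model")
}

#' @export
print.tissue_model <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("tissue model (%s): %s voxels, %g x %g um lateral pitch, depth %g um, %g nm, fmel = %g%%\n",
              if (length(d) == 3L) "3-D" else "2-D x-z",
              paste(d, collapse = " x "), x$grid$dx,
              min(x$grid$dz), max(x$grid$z_edges), x$wavelength,
              100 * x$pigmentation$fmel))
  tab <- table(factor(.label_class(as.integer(x$labels)),
                      levels = c("epidermis", "basal", "dermis", "vessel")))
  cat("  voxel counts:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Build the simulated layered PWS skin model
#'
#' Constructs the canonical x-z cross-section: a 45-um melaninless
#' epidermis over a 15-um basal layer over dermis down to `depth_z`,
#' with optional cylindrical vessels (axes parallel to y, so the model is
#' y-invariant).  Dermal absorption is either depth-binned (screening-
#' adjusted for the unresolved plexus, the default for simulated
#' geometries) or the uniform capillary mixture used for imported
#' geometries.
#'
#' @param width_x Lateral extent (um); the domain spans `[-width_x/2, width_x/2]`.
#' @param depth_z Total depth (um), default 2000 (60 um epidermis +
#'   1940 um dermis).
#' @param dx Lateral voxel pitch (um), default 10.
#' @param dz_epi,dz_dermis Axial voxel pitch in the epidermis (default 5,
#'   so the 15-um basal layer is resolved) and below it (default 10).
#' @param pigmentation A [pigmentation()] level.
#' @param vessels List of [cyl_vessel()] objects (possibly empty).
#' @param wavelength Wavelength (nm), 585 or 755 for the tabulated blood.
#' @param use_adjusted_dermis If `TRUE` (default) use the depth-binned
#'   screening-adjusted dermal absorption.
#' @param net Optional [net_formulation()] describing the vessel contents.
#' @param f_blood Capillary blood fraction for the uniform dermis mixture.
#' @return A `tissue_model` object.
#' @export
build_layered_model <- function(width_x, depth_z = 2000, dx = 10,
                                dz_epi = 5, dz_dermis = 10,
                                pigmentation = pwstherm::pigmentation("light"),
                                vessels = list(), wavelength = 585,
                                use_adjusted_dermis = TRUE, net = NULL,
                                f_blood = 0.002) {
  if (inherits(vessels, "cyl_vessel")) vessels <- list(vessels)
  grid <- .grid_from_edges(width_x, dx, .make_z_edges(depth_z, dz_epi, dz_dermis))
  zc <- grid$z
  lab_z <- integer(grid$nz)
  lab_z[zc < 45] <- 1L
  lab_z[zc >= 45 & zc < 60] <- 2L
  derm <- zc >= 60
  if (use_adjusted_dermis) {
    bins <- dermis_depth_bins()
    idx <- findInterval(zc[derm], c(bins$z_min[1], bins$z_max))
    idx[idx < 1L] <- 1L; idx[idx > nrow(bins)] <- nrow(bins)
    lab_z[derm] <- 10L + idx
  } else lab_z[derm] <- 3L
  labels <- matrix(lab_z, grid$nz, grid$nx)
  for (v in vessels) {
    if (v$top_depth < 60)
      stop("vessel lies outside the dermis (top above 60 um)")
    if (v$top_depth + v$diameter > depth_z)
      stop("vessel extends below the bottom of the dermis")
    r <- v$diameter / 2
    zc0 <- v$top_depth + r
    d2 <- outer(zc - zc0, grid$x - v$cx, function(a, b) a^2 + b^2)
    labels[d2 <= r^2] <- 4L
  }
  .finish_model(labels, grid, wavelength, pigmentation, use_adjusted_dermis,
                f_blood, net,
                meta = list(kind = "layered", vessels = vessels))
}

#' Build a 3-D model from a binary vessel mask
#'
#' Takes a binary vessel volume in `(x, y, z)` axis order (z = depth below
#' the top of the imaged dermis) and assembles a full tissue model: a
#' 60-um epidermis (45 um melaninless + 15 um basal) is prepended above
#' the volume, mask voxels become vessel lumen, and everything else is
#' dermis with the uniform capillary absorption mixture.
#'
#' @param mask Logical or 0/1 3-D array, axes `(x, y, z)`.
#' @param dx,dy,dz Voxel pitch per axis (um); all required.
#' @param pigmentation A [pigmentation()] level.
#' @param wavelength Wavelength (nm).
#' @param net Optional [net_formulation()] for the vessel contents.
#' @param f_blood Capillary blood fraction of the dermis, default 0.002.
#' @return A 3-D `tissue_model` (labels are `(nz x nx x ny)`).
#' @export
import_vessel_mask <- function(mask, dx, dy, dz,
                               pigmentation = pwstherm::pigmentation("light"),
                               wavelength = 585, net = NULL, f_blood = 0.002) {
  if (length(dim(mask)) != 3L) stop("mask must be a 3-D array (x, y, z)")
  if (missing(dx) || missing(dy) || missing(dz))
    stop("voxel pitch (dx, dy, dz) must be supplied")
  nx <- dim(mask)[1]; ny <- dim(mask)[2]; nzm <- dim(mask)[3]
  epi_edges <- seq(0, 60, by = 5)
  z_edges <- c(epi_edges, 60 + dz * seq_len(nzm))
  nz <- length(z_edges) - 1L
  zc <- (z_edges[-1] + z_edges[-(nz + 1L)]) / 2
  labels <- array(3L, dim = c(nz, nx, ny))
  labels[zc < 45, , ] <- 1L
  labels[zc >= 45 & zc < 60, , ] <- 2L
  m <- aperm(array(as.integer(mask != 0), dim(mask)), c(3, 1, 2))  # -> (z, x, y)
  labels[-seq_len(length(epi_edges) - 1L), , ][m == 1L] <- 4L
  x_edges <- seq(-nx * dx / 2, nx * dx / 2, length.out = nx + 1L)
  y_edges <- seq(-ny * dy / 2, ny * dy / 2, length.out = ny + 1L)
  grid <- list(x = (x_edges[-1] + x_edges[-(nx + 1L)]) / 2, x_edges = x_edges,
               dx = dx, nx = nx,
               y = (y_edges[-1] + y_edges[-(ny + 1L)]) / 2, y_edges = y_edges,
               dy = dy, ny = ny,
               z_edges = z_edges, z = zc, dz = diff(z_edges), nz = nz)
  .finish_model(labels, grid, wavelength, pigmentation,
                use_adjusted_dermis = FALSE, f_blood, net,
                meta = list(kind = "imported_mask"))
}

#' Extract the central x-z cross-section of a 3-D model
#'
#' Returns a 2-D `tissue_model` on the same x/z grid, taking the label
#' map at the central y slice.  Used to couple 3-D photon transport to
#' the 2-D thermal solver.
#'
#' @param model A 3-D `tissue_model`.
#' @return A 2-D `tissue_model`.
#' @export
central_slice_model <- function(model) {
  stopifnot(inherits(model, "tissue_model"), length(dim(model$labels)) == 3L)
  iy <- ceiling(dim(model$labels)[3] / 2)
  out <- model
  out$labels <- model$labels[, , iy]
  out$meta$kind <- paste0(out$meta$kind, "_central_slice")
  out
}

# ---- array containers: multi-page TIFF + JSON sidecar --------------------

#' Write a volume as a multi-page TIFF with a JSON sidecar
#'
#' One TIFF page per z slice (page rows = y, columns = x); voxel pitch and
#' axis order are recorded in `<path>.json`.  Integer-valued arrays (label
#' maps, binary masks) are stored losslessly at 8 bits, intensities as
#' 32-bit float.
#'
#' @param vol 3-D array in `(x, y, z)` axis order.
#' @param path Output TIFF path.
#' @param pitch Numeric length-3 voxel pitch (um) for the sidecar.
#' @return `path`, invisibly.
#' @export
write_volume_tiff <- function(vol, path, pitch = c(1, 1, 1)) {
  stopifnot(length(dim(vol)) == 3L)
  integer_valued <- all(vol == round(vol)) && max(vol) <= 255 && min(vol) >= 0
  pages <- lapply(seq_len(dim(vol)[3]), function(k) {
    pg <- t(vol[, , k])  # rows = y, cols = x
    if (integer_valued) pg / 255 else pg
  })
  tiff::writeTIFF(pages, path,
                  bits.per.sample = if (integer_valued) 8L else 32L)
  jsonlite::write_json(list(axes = "xyz", dims = dim(vol), pitch_um = pitch,
                            encoding = if (integer_valued) "uint8x255" else "float32"),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a volume written by [write_volume_tiff()]
#'
#' @param path TIFF path (the `.json` sidecar must sit next to it).
#' @return List with `vol` (array, `(x, y, z)`) and `pitch_um`.
#' @export
read_volume_tiff <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  vol <- array(0, dim = meta$dims)
  for (k in seq_along(pages)) {
    pg <- pages[[k]]
    if (identical(meta$encoding, "uint8x255")) pg <- round(pg * 255)
    vol[, , k] <- t(pg)
  }
  list(vol = vol, pitch_um = meta$pitch_um)
}

#' Export the label map of a model as a multi-page TIFF
#'
#' Labels are written losslessly (8-bit); for 2-D models the single x-z
#' plane is written as a one-page y-extrusion.
#'
#' @param model A `tissue_model`.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
export_model_labels <- function(model, path) {
  lab <- model$labels
  if (length(dim(lab)) == 2L) lab <- array(lab, c(dim(lab), 1L))
  vol <- aperm(lab, c(2, 3, 1))  # (z,x,y) -> (x,y,z)
  write_volume_tiff(vol, path,
                    pitch = c(model$grid$dx,
                              if (!is.null(model$grid$dy)) model$grid$dy else model$grid$dx,
                              mean(model$grid$dz)))
  invisible(path)
}
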