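# Preprocessing chain for OCT-angiography-style intensity volumes:
# optional frequency-domain motion-artifact filtering of en-face (x-y)
# sections, global or Otsu thresholding, and 3-D median despeckling.

#' Frequency-domain motion-artifact filter for one en-face section
#'
#' Applies a separable hard (no taper) rectangular pass mask in
#' normalized spatial frequency to a 2-D x-y section: horizontal
#' (x, along matrix rows' index 1 dimension) frequencies with magnitude
#' in `band_h` and vertical (y) frequencies in `band_v` are retained;
#' everything else is zeroed.  Frequencies are normalized so 1.0 is the
#' Nyquist frequency.  The defaults (`[0.1, 1]` horizontal,
#' `[0, 0.01]` vertical) target slowly varying row artifacts from bulk
#' tissue motion.
#'
#' Note the mask is aggressive: structures wider than about
#' `1/band_h[1]` pixels lose most of their in-plane energy, so the filter
#' is intended for stripe-artifact suppression, not as a mandatory stage
#' before segmentation (see the methods vignette).
#'
#' @param slice2d Numeric matrix; rows index x (horizontal), columns y
#'   (vertical).  The axis assignment is configurable by transposing.
#' @param band_h,band_v Length-2 pass bands in normalized frequency.
#' @return Filtered real-valued matrix of the same size.
#' @export
remove_motion_artifact <- function(slice2d, band_h = c(0.1, 1.0),
                                   band_v = c(0.0, 0.01)) {
  if (!is.matrix(slice2d)) stop("slice2d must be a 2-D matrix")
  n1 <- nrow(slice2d); n2 <- ncol(slice2d)
  # normalized frequency magnitude per axis (1 = Nyquist)
  f1 <- .fft_freq_norm(n1)
  f2 <- .fft_freq_norm(n2)
  keep <- outer(f1 >= band_h[1] & f1 <= band_h[2],
                f2 >= band_v[1] & f2 <= band_v[2])
  Re(stats::fft(stats::fft(slice2d) * keep, inverse = TRUE)) / (n1 * n2)
}

# |frequency| per DFT bin, normalized so Nyquist = 1.
.fft_freq_norm <- function(n) {
  k <- 0:(n - 1)
  k[k > n / 2] <- k[k > n / 2] - n
  abs(k) / (n / 2)
}

#' Apply the motion-artifact filter to every en-face section of a volume
#'
#' @param vol 3-D array `(x, y, z)`; the filter runs on each `(x, y)`
#'   section independently.
#' @inheritParams remove_motion_artifact
#' @return Filtered volume.
#' @export
remove_motion_artifact_volume <- function(vol, band_h = c(0.1, 1.0),
                                          band_v = c(0.0, 0.01)) {
  stopifnot(length(dim(vol)) == 3L)
  out <- vol
  for (k in seq_len(dim(vol)[3]))
    out[, , k] <- remove_motion_artifact(vol[, , k], band_h, band_v)
  out
}

#' Threshold an intensity volume into a binary mask
#'
#' @param vol Numeric array (any dimensionality).
#' @param threshold A numeric global threshold, or an automatic method:
#'   `"isodata"` (default; Ridler-Calvard iteration on class medians,
#'   robust to the skewed class histograms produced by multiplicative
#'   speckle) or `"otsu"` (256-level between-class variance).  Otsu is
#'   biased toward the brighter class under gamma speckle and erodes
#'   vessel boundaries by about half a voxel; see the methods vignette.
#' @return List with `mask` (integer array of 0/1, voxels strictly above
#'   the threshold) and `threshold` (the value used).
#' @export
binarize <- function(vol, threshold = "isodata") {
  if (identical(threshold, "isodata")) {
    rng <- range(vol)
    if (rng[1] == rng[2]) {
      threshold <- rng[1]
    } else {
      thr <- mean(rng)
      for (i in 1:50) {
        lo <- stats::median(vol[vol < thr])
        hi <- stats::median(vol[vol >= thr])
        if (is.na(lo) || is.na(hi)) break
        nt <- (lo + hi) / 2
        if (abs(nt - thr) < 1e-8 * diff(rng)) { thr <- nt; break }
        thr <- nt
      }
      threshold <- thr
    }
  } else if (identical(threshold, "otsu")) {
    rng <- range(vol)
    if (rng[1] == rng[2]) {
      threshold <- rng[1]  # constant image: nothing exceeds it
    } else {
      scaled <- (vol - rng[1]) / (rng[2] - rng[1])
      threshold <- rng[1] + (rng[2] - rng[1]) *
        EBImage::otsu(matrix(as.numeric(scaled), ncol = 1L), range = c(0, 1))
    }
  }
  stopifnot(is.numeric(threshold), length(threshold) == 1L)
  mask <- array(as.integer(vol > threshold), dim(vol))
  list(mask = mask, threshold = threshold)
}

#' 3-D median filter for binary masks
#'
#' Median filtering of a 0/1 mask over an odd box window equals a
#' majority vote over the window, computed here with separable running
#' box sums (edges are zero-padded).
#'
#' @param mask Binary 3-D array.
#' @param window Odd window size per axis (scalar or length 3), default 3.
#' @return Filtered binary array (integer 0/1).
#' @export
despeckle <- function(mask, window = 3L) {
  stopifnot(length(dim(mask)) == 3L)
  window <- rep(as.integer(window), length.out = 3L)
  if (any(window %% 2L == 0L)) stop("window must be odd along every axis")
  s <- array(as.numeric(mask != 0), dim(mask))
  for (ax in 1:3) s <- .box_sum_axis(s, window[ax], ax)
  array(as.integer(s > prod(window) / 2), dim(mask))
}

# running sum of length w along axis ax, zero padded
.box_sum_axis <- function(a, w, ax) {
  if (w == 1L) return(a)
  perm <- switch(ax, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
  b <- aperm(a, perm)
  d <- dim(b)
  m <- matrix(b, d[1], d[2] * d[3])
  cs <- rbind(0, apply(m, 2, cumsum))
  h <- (w - 1L) %/% 2L
  idx_hi <- pmin(seq_len(d[1]) + h, d[1]) + 1L
  idx_lo <- pmax(seq_len(d[1]) - h - 1L, 0L) + 1L
  out <- cs[idx_hi, , drop = FALSE] - cs[idx_lo, , drop = FALSE]
  aperm(array(out, d), order(perm))
}

#' Default OCT preprocessing chain
#'
#' Converts a raw intensity volume into a binary vessel mask:
#' optional motion-artifact filtering of each en-face section, global or
#' Otsu thresholding, then 3-D median despeckling.  Motion filtering is
#' opt-in because the hard band mask also removes the bulk in-plane
#' energy of vessels wider than ~10 voxels (see vignette).
#'
#' @param vol 3-D intensity array `(x, y, z)`; must be finite.
#' @param threshold Passed to [binarize()].
#' @param window Passed to [despeckle()].
#' @param motion_filter Apply [remove_motion_artifact_volume()] first?
#' @param band_h,band_v Pass bands for the motion filter.
#' @return List with `mask` (binary array) and `threshold`.
#' @export
preprocess_oct_volume <- function(vol, threshold = "isodata", window = 3L,
                                  motion_filter = FALSE,
                                  band_h = c(0.1, 1.0), band_v = c(0.0, 0.01)) {
  stopifnot(length(dim(vol)) == 3L)
  if (!all(is.finite(vol))) stop("intensity volume must be finite")
  if (motion_filter) vol <- remove_motion_artifact_volume(vol, band_h, band_v)
  b <- binarize(vol, threshold)
  list(mask = despeckle(b$mask, window), threshold = b$threshold)
}
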