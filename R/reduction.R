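#' Detector images
#'
#' A raw acquisition is a 2D intensity array plus the geometry needed to map
#' pixels to scattering vectors: beam-centre pixel coordinates, pixel size
#' (mm), sample-detector distance (mm) and X-ray wavelength (nm), with an
#' optional logical mask of invalid pixels (`TRUE` = masked).
#'
#' @param intensity Numeric matrix of pixel intensities (>= 0 outside the
#'   mask).
#' @param center_px Length-2 beam centre in pixel units (row, column).
#' @param pixel_mm Pixel edge length in mm.
#' @param distance_mm Sample-detector distance in mm.
#' @param wavelength_nm X-ray wavelength in nm.
#' @param mask Logical matrix, same shape; `TRUE` marks invalid pixels.
#' @return An object of class `detector_image`.
#' @export
detector_image <- function(intensity, center_px, pixel_mm, distance_mm,
                           wavelength_nm, mask = NULL) {
  if (!is.matrix(intensity)) abort("`intensity` must be a matrix.")
  if (is.null(mask)) mask <- matrix(FALSE, nrow(intensity), ncol(intensity))
  if (!identical(dim(mask), dim(intensity))) abort("`mask` shape must match `intensity`.")
  if (any(intensity[!mask] < 0, na.rm = TRUE)) {
    abort("intensities must be >= 0 outside the mask.")
  }
  if (any(c(pixel_mm, distance_mm, wavelength_nm) <= 0)) {
    abort("geometry parameters must be positive.")
  }
  if (length(center_px) != 2) abort("`center_px` must be length 2 (row, col).")
  structure(
    list(
      intensity = intensity, center_px = as.numeric(center_px),
      pixel_mm = pixel_mm, distance_mm = distance_mm,
      wavelength_nm = wavelength_nm, mask = mask
    ),
    class = "detector_image"
  )
}

# q (nm^-1) of every pixel centre: q = (4 pi / lambda) sin(theta / 2),
# theta the full scattering angle from pixel radius and detector distance
pixel_q <- function(image) {
  nr <- nrow(image$intensity)
  nc <- ncol(image$intensity)
  r_px <- sqrt(
    outer(
      (seq_len(nr) - image$center_px[1])^2,
      (seq_len(nc) - image$center_px[2])^2, `+`
    )
  )
  theta <- atan(r_px * image$pixel_mm / image$distance_mm)
  (4 * pi / image$wavelength_nm) * sin(theta / 2)
}

#' Azimuthal (ring) integration of a detector image
#'
#' Maps every unmasked pixel to its scattering-vector modulus and averages
#' pixel intensities in `n_bins` equal-width q rings. The per-ring mean (not
#' sum) is used so partially masked rings are unbiased; empty rings are
#' dropped. Ring q values are bin centres.
#'
#' @param image A [detector_image()].
#' @param n_bins Number of q bins (>= 2).
#' @return A [scattering_curve()] tibble.
#' @export
integrate_rings <- function(image, n_bins = 100) {
  if (n_bins < 2) abort("`n_bins` must be >= 2.")
  ctr <- image$center_px
  if (ctr[1] < 1 || ctr[1] > nrow(image$intensity) ||
    ctr[2] < 1 || ctr[2] > ncol(image$intensity)) {
    abort("beam centre lies outside the image.")
  }
  qpix <- pixel_q(image)
  ok <- !image$mask & is.finite(image$intensity)
  if (!any(ok)) abort("no valid pixels: image is fully masked.")
  qv <- qpix[ok]
  iv <- image$intensity[ok]
  edges <- seq(min(qv), max(qv), length.out = n_bins + 1)
  bin <- findInterval(qv, edges, rightmost.closed = TRUE)
  means <- vapply(split(iv, bin), mean, numeric(1))
  centres <- (edges[-1] + edges[-length(edges)]) / 2
  keep <- as.integer(names(means))
  scattering_curve(centres[keep], unname(means))
}

#' Normalise a curve to unit mean over a q window
#'
#' Divides the curve by its mean intensity inside `[qmin, qmax]`, so that the
#' window mean becomes exactly 1. The default window, 14-16 nm^-1, is the
#' water-structure region conventionally used to put solution scattering
#' acquisitions on a common scale; the operation is idempotent.
#'
#' @param curve A [scattering_curve()] tibble.
#' @param qmin,qmax Normalisation window in nm^-1.
#' @return The rescaled curve.
#' @export
normalize_window <- function(curve, qmin = 14, qmax = 16) {
  idx <- window_idx(curve$q, qmin, qmax)
  if (length(idx) == 0) abort("normalisation window contains no grid points.")
  m <- mean(curve$I[idx])
  if (m == 0) abort("window mean is zero: cannot normalise.")
  out <- curve
  out$I <- curve$I / m
  if ("sigma" %in% names(out)) out$sigma <- curve$sigma / abs(m)
  out
}

#' Laser-off reference subtraction
#'
#' Removes slow drifts (radiation damage, beam decay) from a pumped
#' acquisition by subtracting the average of the laser-off acquisitions
#' recorded immediately before and after it:
#' `dS = on - (pre + post) / 2`. A drift that is linear in acquisition index
#' cancels exactly.
#'
#' @param pre,on,post Scattering curves on a common grid: the preceding
#'   laser-off, the laser-on, and the following laser-off acquisition.
#' @return A difference-curve tibble.
#' @export
subtract_laser_off <- function(pre, on, post) {
  check_same_grid(pre, on)
  check_same_grid(on, post)
  new_difference_curve(on$q, on$I - (pre$I + post$I) / 2)
}

#' Merge small-angle and wide-angle detector curves
#'
#' Scales the wide-angle curve onto the small-angle curve over their q
#' overlap and splices the two at the overlap midpoint. The scale is the
#' least-squares scalar `c` minimising `sum (I_small - c I_wide)^2` over the
#' overlap, with the coarser curve interpolated onto the finer grid there
#' (matching by scaling, not per-point blending). The merged curve keeps
#' small-angle points up to the overlap midpoint and scaled wide-angle points
#' above it.
#'
#' @param small_angle,wide_angle Scattering curves with overlapping q ranges
#'   (>= 2 overlapping points).
#' @return A merged [scattering_curve()] tibble; the applied scale is
#'   attached as attribute `scale`.
#' @export
merge_detectors <- function(small_angle, wide_angle) {
  lo <- max(min(small_angle$q), min(wide_angle$q))
  hi <- min(max(small_angle$q), max(wide_angle$q))
  if (lo >= hi) abort("detector q ranges do not overlap.")
  s_in <- small_angle[small_angle$q >= lo & small_angle$q <= hi, ]
  w_in <- wide_angle[wide_angle$q >= lo & wide_angle$q <= hi, ]
  if (nrow(s_in) < 2 || nrow(w_in) < 2) {
    abort("need at least 2 overlapping points on each detector.")
  }
  if (nrow(s_in) >= nrow(w_in)) { # interpolate the coarser (wide) onto fine
    ref <- s_in$I
    other <- approx(wide_angle$q, wide_angle$I, xout = s_in$q)$y
  } else {
    ref <- approx(small_angle$q, small_angle$I, xout = w_in$q)$y
    other <- w_in$I
  }
  denom <- sum(other^2)
  if (denom == 0) abort("wide-angle curve is zero in the overlap; cannot scale.")
  sc <- sum(ref * other) / denom
  mid <- (lo + hi) / 2
  keep_s <- small_angle[small_angle$q <= mid, ]
  keep_w <- wide_angle[wide_angle$q > mid, ]
  out <- scattering_curve(
    c(keep_s$q, keep_w$q),
    c(keep_s$I, sc * keep_w$I)
  )
  attr(out, "scale") <- sc
  out
}

#' Subtract the solvent heating signal from a difference curve
#'
#' Laser excitation deposits heat in the solvent, whose thermal-expansion
#' difference signal contaminates the structural signal. Given a measured
#' heat pattern, its least-squares multiple over a fit window is removed:
#' `dS - c h`, with `c = sum_w(dS h) / sum_w(h^2)`. After subtraction the
#' residual is orthogonal to the heat pattern over the window. The default
#' window 1-2 nm^-1 targets the region where the thermal signal dominates in
#' aqueous solution scattering; it is a tunable choice, not a measured
#' constant.
#'
#' @param curve Difference curve to clean.
#' @param heat_pattern Measured heat difference curve on the same grid.
#' @param qmin,qmax Fit window in nm^-1.
#' @return The heat-subtracted difference curve; the fitted coefficient is
#'   attached as attribute `heat_coef`.
#' @export
subtract_heat <- function(curve, heat_pattern, qmin = 1, qmax = 2) {
  check_same_grid(curve, heat_pattern)
  idx <- window_idx(curve$q, qmin, qmax)
  if (length(idx) == 0) abort("heat fit window contains no grid points.")
  h <- heat_pattern$dS[idx]
  hh <- sum(h^2)
  if (hh == 0) abort("heat pattern is zero over the fit window.")
  cc <- sum(curve$dS[idx] * h) / hh
  out <- curve
  out$dS <- curve$dS - cc * heat_pattern$dS
  attr(out, "heat_coef") <- cc
  out
}
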