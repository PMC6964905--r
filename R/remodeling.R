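# ECM remodeling quantification: FFT orientation-tensor anisotropy in square
# ROIs, Tsai moment-preserving binarization, peri-cellular "doughnut" band
# ROIs, and collagen densification as the fiber-pixel fraction.

#' FFT orientation-tensor anisotropy index of a square patch
#'
#' Quantifies fiber alignment on the 0 (isotropic) to 1 (fully aligned)
#' scale. The patch is mean-subtracted, Hann-windowed and Fourier
#' transformed; spectral power in a radial frequency band is reduced to the
#' 2x2 second-moment orientation tensor over angle (axial, period pi), and
#' the index is the normalized eigenvalue contrast
#' `alpha = (l1 - l2) / (l1 + l2)`. The dominant real-space orientation is
#' the leading eigenvector rotated by 90 degrees (spectral power lies
#' perpendicular to the stripes that produce it). A featureless patch (no
#' off-DC power) returns `alpha = 0` by convention.
#'
#' @param window square 2D patch (matrix, or single-z [image_stack()]),
#'   side >= 32 px.
#' @param f_lo,f_hi radial band in cycles/px; `f_lo = NULL` uses `4/side`
#'   (excludes DC and low-frequency illumination), default `f_hi = 0.45`
#'   avoids the Nyquist corner.
#' @return list: `alpha` in [0,1], `orientation` in `[0, pi)` radians
#'   (real-space fiber direction), `band_power`.
#' @export
anisotropy_index <- function(window, f_lo = NULL, f_hi = 0.45) {
  vol <- .as_vol(window)
  if (dim(vol$values)[3] != 1L) stop("anisotropy_index expects a 2D patch")
  m <- vol$values[, , 1]
  if (nrow(m) != ncol(m)) stop("patch must be square")
  n <- nrow(m)
  if (n < 32L) stop("patch side must be >= 32 px")
  if (is.null(f_lo)) f_lo <- 4 / n
  w <- (m - mean(m)) * .hann2d(n)
  P <- Mod(stats::fft(w))^2
  fr <- c(0:(n %/% 2), -((n - (n %/% 2 + 1)):1)) / n # DFT frequencies
  FY <- matrix(fr, n, n)        # frequency along rows (y)
  FX <- matrix(fr, n, n, byrow = TRUE) # frequency along columns (x)
  R <- sqrt(FX^2 + FY^2)
  sel <- R >= f_lo & R <= f_hi
  pw <- P[sel]
  tot <- sum(pw)
  if (tot < .Machine$double.eps * sum(P) || tot == 0)
    return(list(alpha = 0, orientation = NA_real_, band_power = 0))
  ux <- FX[sel] / R[sel]; uy <- FY[sel] / R[sel]
  Mxx <- sum(pw * ux * ux) / tot
  Mxy <- sum(pw * ux * uy) / tot
  Myy <- sum(pw * uy * uy) / tot
  e <- eigen(matrix(c(Mxx, Mxy, Mxy, Myy), 2, 2), symmetric = TRUE)
  l1 <- e$values[1]; l2 <- e$values[2]
  alpha <- (l1 - l2) / (l1 + l2)
  v <- e$vectors[, 1]
  orient <- (atan2(v[2], v[1]) + pi / 2) %% pi
  list(alpha = alpha, orientation = orient, band_power = tot)
}

#' Tsai moment-preserving threshold
#'
#' Selects the threshold such that the binary image preserves the first
#' three gray-level moments of the input: the two representative levels
#' `(z0, z1)` and the background fraction `p0` solve the moment-preserving
#' equations; the threshold is the smallest gray level at which the
#' cumulative fraction of pixels reaches `p0`.
#'
#' @param img numeric vector, matrix, array or [image_stack()] with >= 2
#'   distinct gray levels.
#' @return list of class `moments_threshold`: `threshold`, `z0`, `z1`, `p0`
#'   and the input moments `m1`, `m2`, `m3`. Pixels strictly above
#'   `threshold` are foreground.
#' @export
moments_threshold <- function(img) {
  v <- if (is.numeric(img) && is.null(dim(img))) img else .as_vol(img)$values
  v <- as.vector(v)
  if (length(unique(v)) < 2L) stop("constant image: no threshold exists")
  m1 <- mean(v); m2 <- mean(v^2); m3 <- mean(v^3)
  det <- m2 - m1^2 # m0 = 1
  c0 <- (m1 * m3 - m2^2) / det
  c1 <- (m1 * m2 - m3) / det
  disc <- sqrt(pmax(c1^2 - 4 * c0, 0))
  z0 <- (-c1 - disc) / 2
  z1 <- (-c1 + disc) / 2
  p0 <- if (z1 == z0) 0.5 else (z1 - m1) / (z1 - z0)
  p0 <- min(1, max(0, p0))
  # smallest gray level g with cumulative fraction >= p0
  sv <- sort(v)
  k <- ceiling(p0 * length(v))
  thr <- if (k < 1L) sv[1] - 1 else sv[k]
  structure(list(threshold = thr, z0 = z0, z1 = z1, p0 = p0,
                 m1 = m1, m2 = m2, m3 = m3),
            class = "moments_threshold")
}

#' @export
print.moments_threshold <- function(x, ...) {
  cat(sprintf("<moments_threshold> t = %.6g (z0 %.4g, z1 %.4g, p0 %.4f)\n",
              x$threshold, x$z0, x$z1, x$p0))
  invisible(x)
}

#' Peri-cellular band ("doughnut") ROI around a cell mask
#'
#' Dilates the cell mask by a physical radius and removes the cell itself,
#' producing an annular band of the requested thickness clipped at the image
#' border. Dilation uses the Euclidean distance transform with anisotropic
#' spacing, i.e. a disc (2D) or spacing-corrected ellipsoid (3D)
#' structuring element. A thickness below one voxel yields a 1-voxel rim.
#' Bands of touching cells are computed independently and may overlap.
#'
#' @param cell_mask a non-empty [binary_mask()].
#' @param thickness_um band thickness, um (> 0). The compaction assay this
#'   supports uses 7 um.
#' @return a [binary_mask()] of the band.
#' @export
make_band_roi <- function(cell_mask, thickness_um = 7) {
  stopifnot(inherits(cell_mask, "binary_mask"))
  if (thickness_um <= 0) stop("'thickness_um' must be > 0")
  if (!any(cell_mask$values)) stop("empty cell mask")
  sp <- cell_mask$spacing
  eff <- max(thickness_um, min(sp[1:2])) # clamp: at least one voxel of rim
  d <- distance_transform(cell_mask$values, sp)
  band <- d > 0 & d <= eff + 1e-9
  binary_mask(band, sp)
}

#' Collagen fiber density within a region of interest
#'
#' Binarizes the whole image with the Tsai moments threshold (one global
#' threshold, so densities of different ROIs of the same image are
#' comparable) and returns the fraction of ROI pixels classified as fiber.
#'
#' @param img an [image_stack()] (or array).
#' @param roi a [binary_mask()] congruent with `img`, or a window spec
#'   `list(x, y, side)` (1-based corner, square side, z = 1).
#' @param threshold optional precomputed [moments_threshold()] (reuse one
#'   threshold across the control / alignment / band ROIs of an image).
#' @return fraction in [0, 1].
#' @export
fiber_density <- function(img, roi, threshold = NULL) {
  vol <- .as_vol(img)
  if (is.null(threshold)) threshold <- moments_threshold(vol$values)
  fg <- vol$values > threshold$threshold
  if (inherits(roi, "binary_mask") || is.array(roi) || is.matrix(roi)) {
    rm_ <- .as_vol(roi)$values
    storage.mode(rm_) <- "logical"
    if (!any(rm_)) stop("empty ROI")
    mean(fg[rm_])
  } else {
    side <- roi$side
    ys <- roi$y:(roi$y + side - 1L); xs <- roi$x:(roi$x + side - 1L)
    if (min(ys) < 1 || min(xs) < 1 || max(ys) > dim(fg)[1] ||
        max(xs) > dim(fg)[2]) stop("ROI window outside the image")
    mean(fg[ys, xs, 1])
  }
}

#' Automatic control / alignment ROI placement
#'
#' Reproducible stand-in for manual ROI placement: the control window is the
#' `roi_px` square (searched on a coarse grid) with minimal overlap with the
#' dilated cell mask; the alignment window is centred on the midpoint
#' between the two nearest cell centroids.
#'
#' @param cell_mask a [binary_mask()] with >= 2 cells (connected components)
#'   for the alignment window; 1 cell yields only a control window.
#' @param roi_px window side, px.
#' @param dilate_um margin around cells excluded from the control window, um.
#' @return list of window specs `list(x, y, side)` with elements `control`
#'   and (when defined) `alignment`.
#' @export
place_rois <- function(cell_mask, roi_px = 100L, dilate_um = 5) {
  stopifnot(inherits(cell_mask, "binary_mask"))
  sp <- cell_mask$spacing
  d <- dim(cell_mask$values)
  if (roi_px > min(d[1], d[2])) stop("ROI larger than image")
  avoid <- .dilate_um(cell_mask$values, dilate_um, sp)
  step <- max(1L, roi_px %/% 4L)
  best <- NULL; best_ov <- Inf
  for (y in seq(1L, d[1] - roi_px + 1L, by = step))
    for (x in seq(1L, d[2] - roi_px + 1L, by = step)) {
      ov <- sum(avoid[y:(y + roi_px - 1L), x:(x + roi_px - 1L), 1])
      if (ov < best_ov) { best_ov <- ov; best <- list(x = x, y = y, side = roi_px) }
    }
  out <- list(control = best)
  lab <- .label_components(cell_mask$values)
  ncell <- max(lab)
  if (ncell >= 2L) {
    cents <- t(vapply(seq_len(ncell), function(l) {
      w <- which(lab == l, arr.ind = TRUE)
      c(mean(w[, 2]), mean(w[, 1]))
    }, numeric(2)))
    dm <- as.matrix(stats::dist(cents)); diag(dm) <- Inf
    ij <- which(dm == min(dm), arr.ind = TRUE)[1, ]
    mid <- (cents[ij[1], ] + cents[ij[2], ]) / 2
    x0 <- min(max(1L, round(mid[1]) - roi_px %/% 2L), d[2] - roi_px + 1L)
    y0 <- min(max(1L, round(mid[2]) - roi_px %/% 2L), d[1] - roi_px + 1L)
    out$alignment <- list(x = x0, y = y0, side = roi_px)
  }
  out
}
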