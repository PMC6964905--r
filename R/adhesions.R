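# Focal-adhesion detection and measurement: the 2D immunofluorescence
# pipeline (median -> background subtraction -> CLAHE -> EXP -> contrast
# stretch -> LoG -> in-mask threshold -> closing -> particle analysis) and
# the 3D pipeline (3D median -> per-slice rolling ball -> gamma -> fixed
# threshold -> EDM watershed -> perinuclear exclusion).

#' Parameters of the 2D focal-adhesion pipeline
#'
#' Defaults are the published processing settings of the 2D vinculin
#' quantification: median radius 2, CLAHE blocksize 19 / 256 bins / slope 6,
#' 0.35 % contrast saturation, LoG sigma (5, 5) px, particle size filter
#' 50-Inf px^2 and circularity range 0-1.0. The rolling-ball background
#' radius (not published) defaults to 50 px.
#'
#' @param median_radius median filter radius, px.
#' @param background_radius rolling-ball (morphological opening) radius, px.
#' @param clahe_block,clahe_bins,clahe_slope CLAHE tile size, histogram bins
#'   and clip slope.
#' @param contrast_saturation percent of pixels saturated per tail in the
#'   linear stretch.
#' @param log_sigma LoG sigma `(sx, sy)`, px.
#' @param min_size minimum particle area, px^2.
#' @param circularity inclusive circularity range `(lo, hi)`;
#'   `4*pi*A/P^2`, clamped at 1.
#' @return list of class `fa2d_params`.
#' @export
fa2d_params <- function(median_radius = 2L, background_radius = 50L,
                        clahe_block = 19L, clahe_bins = 256L, clahe_slope = 6,
                        contrast_saturation = 0.35, log_sigma = c(5, 5),
                        min_size = 50, circularity = c(0, 1.0)) {
  structure(as.list(environment()), class = "fa2d_params")
}

#' Parameters of the 3D focal-adhesion pipeline
#'
#' Published settings: 3D median of 1-voxel radius, rolling-ball background
#' subtraction with 10 px radius, gamma 2.1, fixed intensity threshold,
#' EDM watershed with adjustable splitting sensitivity, and a 5 um
#' perinuclear exclusion band.
#'
#' @param median_radius_vox 3D median radius, voxels.
#' @param rollball_radius_px per-slice background radius, px.
#' @param gamma gamma value; applied as `v^(1/gamma)` on [0,1] intensities
#'   to enhance the bright FA tail before fixed thresholding.
#' @param threshold fixed intensity threshold on the post-gamma [0,1] scale,
#'   or `NULL` to use `threshold_quantile`.
#' @param threshold_quantile quantile of the post-gamma stack used when no
#'   fixed threshold is given (selects the hyperintense tail).
#' @param watershed_dynamic h-maxima depth (um of EDM height) below which
#'   touching maxima are merged rather than split.
#' @param perinuclear_band_um width of the exclusion band around the
#'   nucleus, um.
#' @return list of class `fa3d_params`.
#' @export
fa3d_params <- function(median_radius_vox = 1L, rollball_radius_px = 10L,
                        gamma = 2.1, threshold = NULL,
                        threshold_quantile = 0.99, watershed_dynamic = 1,
                        perinuclear_band_um = 5) {
  stopifnot(gamma > 0, perinuclear_band_um >= 0)
  structure(as.list(environment()), class = "fa3d_params")
}

.fa_set <- function(fa, dims, spacing) {
  structure(list(fa = fa, n = nrow(fa), dims = dims, spacing = spacing,
                 mean_size = if (nrow(fa)) mean(fa$size_px) else NA_real_),
            class = "focal_adhesion_set")
}

#' @export
print.focal_adhesion_set <- function(x, ...) {
  unit <- if (x$dims == 2L) "px^2" else "vox"
  cat(sprintf("<focal_adhesion_set> %dD: %d FAs, mean size %.4g %s\n",
              x$dims, x$n, x$mean_size, unit))
  invisible(x)
}

#' Detect focal adhesions in a 2D vinculin image
#'
#' Runs the fixed-order 2D pipeline (see [fa2d_params()]) inside a coarse
#' cell mask and measures the surviving particles. An image with no
#' detections returns an empty set (count 0), not an error.
#'
#' @param img 2D [image_stack()] (z = 1).
#' @param cell_mask non-empty [binary_mask()] delimiting the search area.
#' @param params a [fa2d_params()] list.
#' @return a `focal_adhesion_set` whose `fa` data.frame has one row per FA:
#'   centroid (um and px), `size_px` (area px^2), `size_um` (um^2),
#'   `circularity`.
#' @export
detect_fa_2d <- function(img, cell_mask, params = fa2d_params()) {
  vol <- .as_vol(img)
  if (dim(vol$values)[3] != 1L) stop("detect_fa_2d expects a 2D image")
  stopifnot(inherits(params, "fa2d_params"))
  cm <- .as_vol(cell_mask)$values[, , 1]
  storage.mode(cm) <- "logical"
  if (!any(cm)) stop("empty cell mask")
  rk_log_image("detect_fa_2d", vol)
  sp <- vol$spacing

  m <- .norm01(vol$values[, , 1])
  m <- as.matrix(EBImage::medianFilter(m, params$median_radius))
  bg <- EBImage::opening(m, EBImage::makeBrush(2L * params$background_radius + 1L,
                                               "disc"))
  m <- pmax(m - as.matrix(bg), 0)
  m <- .clahe(.norm01(m), params$clahe_block, params$clahe_bins,
              params$clahe_slope)
  ge <- log(256)
  m <- (exp(ge * .norm01(m)) - 1) / (exp(ge) - 1)
  m <- .stretch(m, params$contrast_saturation)
  resp <- as.matrix(EBImage::filter2(m, .log_kernel(params$log_sigma),
                                     boundary = "replicate"))
  # noise floor: the automatic threshold must clear the background response
  # tail, or a featureless image would still be split into two classes
  rin <- resp[cm]
  thr <- max(.intermeans_threshold(rin),
             stats::median(rin) + 8 * stats::mad(rin))
  bin <- resp > thr & cm
  bin <- as.matrix(EBImage::closing(bin * 1, EBImage::makeBrush(3L, "box"))) > 0.5
  bin <- bin & cm
  lab <- .label_components(array(bin, c(dim(bin), 1L)))[, , 1]
  n <- max(lab)
  if (n == 0L)
    return(.fa_set(data.frame(label = integer(0), x_um = numeric(0),
                              y_um = numeric(0), x_px = numeric(0),
                              y_px = numeric(0), size_px = numeric(0),
                              size_um = numeric(0), circularity = numeric(0)),
                   2L, sp))
  shp <- EBImage::computeFeatures.shape(lab)
  area <- shp[, "s.area"]
  per <- shp[, "s.perimeter"]
  circ <- pmin(1, 4 * pi * area / pmax(per, 1e-9)^2)
  cent <- t(vapply(seq_len(n), function(l) {
    w <- which(lab == l, arr.ind = TRUE)
    c(mean(w[, 2]), mean(w[, 1]))
  }, numeric(2)))
  keep <- area >= params$min_size & circ >= params$circularity[1] &
    circ <= params$circularity[2]
  fa <- data.frame(label = seq_len(n), x_um = (cent[, 1] - 1) * sp[1],
                   y_um = (cent[, 2] - 1) * sp[2],
                   x_px = cent[, 1], y_px = cent[, 2],
                   size_px = area, size_um = area * sp[1] * sp[2],
                   circularity = circ)[keep, , drop = FALSE]
  rownames(fa) <- NULL
  rk_log("detect_fa_2d: %d particles, %d after size/circularity filter", n,
         nrow(fa))
  .fa_set(fa, 2L, sp)
}

# Watershed split of a binary mask on the negated EDM, with h-maxima
# merging: maxima whose dynamic (EDM height, um) is below `h` do not
# generate separate objects. Returns an integer label array covering the
# mask.
.edm_watershed <- function(mask, spacing, h) {
  D <- distance_transform(!mask, spacing)
  D[!mask] <- 0
  hm <- .reconstruct_dilate(D - h, D)     # h-maxima transform of the EDM
  seeds <- .regional_maxima(hm, mask = mask, positive = FALSE)
  lab <- .label_components(seeds)
  off <- .neighbor_offsets(dim(mask)[3] > 1L)
  repeat {
    bestD <- array(-.INF, dim = dim(mask))
    bestL <- array(0L, dim = dim(mask))
    for (r in seq_len(nrow(off))) {
      shL <- .shift3(lab, off$dy[r], off$dx[r], off$dz[r], fill = 0)
      shD <- .shift3(D, off$dy[r], off$dx[r], off$dz[r], fill = -.INF)
      upd <- shL > 0 & shD > bestD
      bestD[upd] <- shD[upd]
      bestL[upd] <- shL[upd]
    }
    sel <- mask & lab == 0 & bestL > 0
    if (!any(sel)) break
    lab[sel] <- bestL[sel]
  }
  storage.mode(lab) <- "integer"
  lab
}

#' Detect focal adhesions in a 3D vinculin stack
#'
#' Runs the fixed-order 3D pipeline (see [fa3d_params()]): 3D median,
#' per-slice rolling-ball background subtraction, gamma enhancement, fixed
#' threshold, EDM-watershed splitting of touching clusters, and removal of
#' perinuclear vinculin (Golgi/reticulum signal) via a fixed-width band
#' around the nucleus.
#'
#' @param stack 3D [image_stack()].
#' @param nucleus_mask [binary_mask()]; an empty mask disables the
#'   perinuclear exclusion.
#' @param params a [fa3d_params()] list.
#' @return a `focal_adhesion_set` with per-FA volumes (`size_px` in voxels,
#'   `size_um` in um^3) and centroids.
#' @export
detect_fa_3d <- function(stack, nucleus_mask = NULL, params = fa3d_params()) {
  vol <- .as_vol(stack)
  stopifnot(inherits(params, "fa3d_params"))
  rk_log_image("detect_fa_3d", vol)
  sp <- vol$spacing
  d <- dim(vol$values)

  v <- .norm01(vol$values)
  if (params$median_radius_vox > 0) v <- .median_ball1(v)
  brush <- EBImage::makeBrush(2L * params$rollball_radius_px + 1L, "disc")
  for (k in seq_len(d[3])) {
    sl <- v[, , k]
    v[, , k] <- pmax(sl - as.matrix(EBImage::opening(sl, brush)), 0)
  }
  v <- .norm01(v)^(1 / params$gamma)
  if (!is.null(params$threshold)) {
    # fixed manual threshold: used exactly as given
    thr <- params$threshold
  } else {
    # automatic quantile cut, with a noise floor: a stack with no
    # hyperintense tail has no FAs, even though range-normalization always
    # puts some voxels above any quantile
    thr <- max(stats::quantile(v, params$threshold_quantile, names = FALSE),
               stats::median(v) + 8 * stats::mad(v))
  }
  if (thr < 0) stop("threshold outside the [0,1] intensity range")
  mask <- v > thr
  if (!any(mask))
    return(.fa_set(data.frame(label = integer(0), x_um = numeric(0),
                              y_um = numeric(0), z_um = numeric(0),
                              size_px = numeric(0), size_um = numeric(0)),
                   3L, sp))
  lab <- .edm_watershed(mask, sp, params$watershed_dynamic)
  n <- max(lab)
  vox <- prod(sp)
  cent <- matrix(0, n, 3L)
  vols <- integer(n)
  for (l in seq_len(n)) {
    w <- which(lab == l, arr.ind = TRUE)
    vols[l] <- nrow(w)
    cent[l, ] <- colMeans(w) # (y, x, z) voxel
  }
  fa <- data.frame(label = seq_len(n),
                   x_um = (cent[, 2] - 1) * sp[1],
                   y_um = (cent[, 1] - 1) * sp[2],
                   z_um = (cent[, 3] - 1) * sp[3],
                   size_px = vols, size_um = vols * vox)
  if (!is.null(nucleus_mask) && any(.as_vol(nucleus_mask)$values)) {
    nd <- distance_transform(.as_vol(nucleus_mask)$values, sp)
    ci <- cbind(pmin(pmax(round(cent[, 1]), 1), d[1]),
                pmin(pmax(round(cent[, 2]), 1), d[2]),
                pmin(pmax(round(cent[, 3]), 1), d[3]))
    fa <- fa[nd[ci] > params$perinuclear_band_um, , drop = FALSE]
    rownames(fa) <- NULL
  }
  rk_log("detect_fa_3d: threshold %.4g, %d FAs after watershed, %d kept",
         thr, n, nrow(fa))
  .fa_set(fa, 3L, sp)
}

#' Summarize a focal-adhesion set
#'
#' @param set a `focal_adhesion_set`.
#' @param probs size-distribution percentiles to report.
#' @return list: `count`, `mean_size`, `median_size`, `size_percentiles`
#'   (native units: px^2 in 2D, voxels in 3D), and `mean_size_um` (um^2 or
#'   um^3). Empty sets report count 0 and `NA` sizes.
#' @export
fa_summary <- function(set, probs = c(0.05, 0.25, 0.5, 0.75, 0.95)) {
  stopifnot(inherits(set, "focal_adhesion_set"))
  if (set$n == 0L)
    return(list(count = 0L, mean_size = NA_real_, median_size = NA_real_,
                size_percentiles = setNames(rep(NA_real_, length(probs)),
                                            paste0(probs * 100, "%")),
                mean_size_um = NA_real_))
  list(count = set$n,
       mean_size = mean(set$fa$size_px),
       median_size = stats::median(set$fa$size_px),
       size_percentiles = stats::quantile(set$fa$size_px, probs),
       mean_size_um = mean(set$fa$size_um))
}
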