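# DQ-collagen degradation volumetry: Tsai-threshold binarization, 3D closing
# and median cleanup, then foreground volume per cell.

#' Segment DQ-collagen signal in a 3D stack
#'
#' Fixed pipeline order: Tsai moments threshold on the whole stack, then
#' morphological closing, then a binary median filter. By default the
#' closing uses a physically isotropic ball: the in-plane radius is
#' `closing_r_px` pixels and the z radius is scaled by `dx/dz`, so strongly
#' anisotropic stacks are closed with the same physical reach in every
#' direction. `per_slice = TRUE` instead applies 2D discs slice by slice.
#'
#' @param stack a 3D [image_stack()].
#' @param closing_r_px closing radius, in-plane pixels (0 disables).
#' @param median_r_px binary median radius, voxels (0 disables).
#' @param per_slice logical; 2D slice-wise morphology.
#' @return a [binary_mask()].
#' @export
dq_segment <- function(stack, closing_r_px = 2L, median_r_px = 1L,
                       per_slice = FALSE) {
  vol <- .as_vol(stack)
  rk_log_image("dq_segment", vol)
  thr <- moments_threshold(vol$values)
  m <- vol$values > thr$threshold
  sp <- vol$spacing
  if (closing_r_px > 0) {
    r_um <- closing_r_px * sp[1]
    if (per_slice) {
      for (k in seq_len(dim(m)[3]))
        m[, , k] <- .close_um(array(m[, , k], c(dim(m)[1:2], 1L)), r_um,
                              c(sp[1:2], 1))[, , 1]
    } else {
      m <- .close_um(m, r_um, sp)
    }
  }
  if (median_r_px > 0) {
    if (per_slice) {
      for (k in seq_len(dim(m)[3]))
        m[, , k] <- .binary_median(array(m[, , k], c(dim(m)[1:2], 1L)),
                                   median_r_px)[, , 1]
    } else {
      m <- .binary_median(m, median_r_px)
    }
  }
  rk_log("dq_segment: threshold %.4g, %d foreground voxels", thr$threshold,
         sum(m))
  binary_mask(m, sp)
}

#' Degraded-matrix volume per cell
#'
#' Total foreground volume (voxel count times voxel volume), number of
#' 26-connected components, and volume per cell.
#'
#' @param mask a [binary_mask()] from [dq_segment()].
#' @param n_cells number of cells in the field (>= 1), from a cell-channel
#'   count or given explicitly.
#' @return list of class `degradation_result`: `total_volume_um3`,
#'   `volume_per_cell_um3`, `n_cells`, `n_components`.
#' @export
dq_volume <- function(mask, n_cells) {
  stopifnot(inherits(mask, "binary_mask"))
  if (length(n_cells) != 1L || !is.finite(n_cells) || n_cells < 1)
    stop("'n_cells' must be >= 1")
  vox <- prod(mask$spacing)
  total <- sum(mask$values) * vox
  ncomp <- if (any(mask$values)) max(.label_components(mask$values)) else 0L
  res <- structure(list(total_volume_um3 = total,
                        volume_per_cell_um3 = total / n_cells,
                        n_cells = n_cells, n_components = ncomp),
                   class = "degradation_result")
  rk_log("dq_volume: %.4g um^3 total, %d components, %.4g um^3/cell",
         total, ncomp, res$volume_per_cell_um3)
  res
}

#' @export
print.degradation_result <- function(x, ...) {
  cat(sprintf("<degradation_result> %.4g um^3 in %d components; %.4g um^3/cell (%d cells)\n",
              x$total_volume_um3, x$n_components, x$volume_per_cell_um3,
              x$n_cells))
  invisible(x)
}

#' Count cells from a cell-channel mask
#'
#' Connected-component count of a binary cell mask, for the per-cell
#' normalization of [dq_volume()].
#'
#' @param cell_mask a [binary_mask()].
#' @return integer component count.
#' @export
count_cells <- function(cell_mask) {
  stopifnot(inherits(cell_mask, "binary_mask"))
  if (!any(cell_mask$values)) return(0L)
  max(.label_components(cell_mask$values))
}
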