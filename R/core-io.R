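# Image containers, TIFF/CSV I/O, physical-units bookkeeping, configuration.

#' Construct an image stack with physical voxel spacing
#'
#' The universal input container of the package: a scalar intensity grid
#' (2D image or 3D stack) plus the physical size of a voxel in micrometres.
#' Values are stored as a 3D array indexed `[y, x, z]`; a 2D image has a
#' single z-plane. Voxel indices are 0-based in physical terms: the centre of
#' voxel `(i, j, k)` (1-based array indices) sits at
#' `((j-1)*dx, (i-1)*dy, (k-1)*dz)` micrometres.
#'
#' @param values numeric matrix (2D) or 3D array of non-negative, finite
#'   intensities.
#' @param spacing numeric length-3, voxel pitch `(dx, dy, dz)` in um/voxel.
#'   All components must be positive. Typical confocal acquisitions used with
#'   this package have strongly anisotropic spacing, e.g.
#'   `c(0.099, 0.099, 0.42)` or `c(0.312, 0.312, 0.49)`.
#' @param bit_depth integer, nominal bit depth of the source data (8, 16, or
#'   32 for floating point).
#' @param channel free-text channel label (e.g. `"TAMRA"`, `"DQ"`).
#' @param time_index optional integer frame index for time-lapse data.
#' @return an object of class `image_stack`.
#' @examples
#' img <- image_stack(matrix(runif(64 * 64), 64, 64),
#'                    spacing = c(0.312, 0.312, 0.49))
#' dim(img$values)
#' @export
image_stack <- function(values, spacing = c(1, 1, 1), bit_depth = 16L,
                        channel = "", time_index = NULL) {
  if (is.matrix(values)) values <- array(values, dim = c(dim(values), 1L))
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("'values' must be a matrix or a 3D array")
  if (any(!is.finite(values)))
    stop("image values must be finite")
  if (any(values < 0))
    stop("image values must be >= 0")
  spacing <- as.numeric(spacing)
  if (length(spacing) == 2L) spacing <- c(spacing, 1)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be three positive numbers (dx, dy, dz) in um/voxel")
  structure(
    list(values = values, spacing = spacing, bit_depth = as.integer(bit_depth),
         channel = channel, time_index = time_index),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<image_stack> %d x %d x %d (y,x,z), spacing %.4g x %.4g x %.4g um, %d-bit%s\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              x$bit_depth,
              if (nzchar(x$channel)) paste0(", channel '", x$channel, "'") else ""))
  invisible(x)
}

#' Construct a binary mask congruent with an image stack
#'
#' @param values logical matrix or 3D array.
#' @param spacing voxel pitch `(dx, dy, dz)` in um/voxel, normally inherited
#'   from the source [image_stack()].
#' @return object of class `binary_mask`.
#' @export
binary_mask <- function(values, spacing = c(1, 1, 1)) {
  if (is.matrix(values)) values <- array(values, dim = c(dim(values), 1L))
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("'values' must be a matrix or a 3D array")
  storage.mode(values) <- "logical"
  if (any(is.na(values))) stop("mask values must not be NA")
  spacing <- as.numeric(spacing)
  if (length(spacing) == 2L) spacing <- c(spacing, 1)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("'spacing' must be three positive numbers")
  structure(list(values = values, spacing = spacing), class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<binary_mask> %d x %d x %d, %d foreground voxels (%.1f%%)\n",
              d[1], d[2], d[3], sum(x$values), 100 * mean(x$values)))
  invisible(x)
}

# Accept image_stack / binary_mask / bare array, return list(values, spacing).
.as_vol <- function(x, spacing = NULL) {
  if (inherits(x, "image_stack") || inherits(x, "binary_mask")) {
    list(values = x$values, spacing = x$spacing)
  } else {
    v <- if (is.matrix(x)) array(x, dim = c(dim(x), 1L)) else x
    if (!is.array(v) || length(dim(v)) != 3L)
      stop("expected an image_stack, binary_mask, matrix or 3D array")
    if (is.null(spacing)) spacing <- c(1, 1, 1)
    if (length(spacing) == 2L) spacing <- c(spacing, 1)
    list(values = v, spacing = as.numeric(spacing))
  }
}

#' Read a TIFF image or stack
#'
#' Reads a single- or multi-page TIFF into an [image_stack()]. Integer images
#' are read at their native levels (not normalized); floating-point TIFFs are
#' read as-is. Pixel spacing is not parsed from TIFF tags: supply it
#' explicitly (micrometres per voxel), as acquisition metadata rarely
#' survives export.
#'
#' @param path TIFF file path.
#' @param spacing voxel pitch `(dx, dy, dz)` in um/voxel.
#' @param channel,time_index passed to [image_stack()].
#' @return an `image_stack`; a single-page TIFF becomes a z = 1 stack.
#' @seealso [write_image()]
#' @export
read_image <- function(path, spacing = c(1, 1, 1), channel = "",
                       time_index = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  info <- tryCatch(tiff::readTIFF(path, payload = FALSE, all = TRUE),
                   error = function(e) stop("not a readable TIFF: ", path,
                                            " (", conditionMessage(e), ")"))
  bits <- info$bits.per.sample[1]
  if (is.null(bits) || !bits %in% c(8L, 16L)) bits <- 32L
  # integer TIFFs are read at native levels; 32-bit data as stored floats
  pages <- tiff::readTIFF(path, all = TRUE, as.is = bits < 32L)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1] # drop extra channels
    p
  })
  d <- dim(pages[[1]])
  vals <- array(unlist(pages, use.names = FALSE), dim = c(d[1], d[2], length(pages)))
  image_stack(vals, spacing = spacing, bit_depth = bits, channel = channel,
              time_index = time_index)
}

#' Write an image stack to TIFF
#'
#' Integer stacks (bit depth 8 or 16) are written losslessly at their native
#' levels; other data are written as 32-bit float.
#'
#' @param img an [image_stack()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  stopifnot(inherits(img, "image_stack"))
  v <- img$values
  nz <- dim(v)[3]
  pages <- lapply(seq_len(nz), function(k) v[, , k])
  if (img$bit_depth %in% c(8L, 16L)) {
    mx <- 2^img$bit_depth - 1
    if (max(v) > mx) stop("values exceed the stated bit depth")
    pages <- lapply(pages, function(p) p / mx)
    tiff::writeTIFF(pages, path, bits.per.sample = img$bit_depth)
  } else {
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  }
  invisible(path)
}

#' Write measurement rows to CSV
#'
#' Writes keyed measurement records as a CSV with a header row, full float
#' precision and deterministic row order (input order).
#'
#' @param records a data.frame, or a list of identically-named lists/vectors.
#'   An empty list is allowed if `columns` gives the header.
#' @param path output CSV path.
#' @param columns character vector of column names, required only when
#'   `records` is empty.
#' @return `path`, invisibly.
#' @export
write_results <- function(records, path, columns = NULL) {
  if (is.data.frame(records)) {
    df <- records
  } else if (length(records) == 0L) {
    if (is.null(columns)) stop("empty records need explicit 'columns'")
    df <- as.data.frame(setNames(rep(list(numeric(0)), length(columns)), columns))
  } else {
    keys <- names(records[[1]])
    if (is.null(keys)) stop("records must be named")
    ok <- vapply(records, function(r) identical(names(r), keys), logical(1))
    if (!all(ok)) stop("records have heterogeneous keys")
    df <- do.call(rbind, lapply(records, function(r) as.data.frame(r)))
  }
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Convert a physical length to a voxel count
#'
#' Rounds `length_um / spacing` to the nearest integer, clamped below at one
#' voxel, e.g. for turning the 7 um peri-cellular band thickness or the 5 um
#' perinuclear exclusion band into pixel radii.
#'
#' @param length_um physical length in micrometres (> 0).
#' @param spacing voxel pitch along the relevant axis, um/voxel (> 0).
#' @return integer voxel count >= 1.
#' @examples
#' um_to_px(7, 0.312) # 22
#' @export
um_to_px <- function(length_um, spacing) {
  if (!is.finite(length_um) || length_um <= 0) stop("'length_um' must be > 0")
  if (!is.finite(spacing) || spacing <= 0) stop("'spacing' must be > 0")
  max(1L, as.integer(round(length_um / spacing)))
}

# ---- configuration ---------------------------------------------------------

#' Default analysis configuration
#'
#' One named parameter block per pipeline. Every parameter has a default;
#' defaults follow the published acquisition/processing settings where those
#' are stated (2D focal-adhesion block) and documented package choices
#' elsewhere. See the methods vignette for the rationale behind each value.
#'
#' @return nested named list with blocks `fiber`, `remodeling`,
#'   `degradation`, `fa2d`, `fa3d`, `motility`.
#' @export
default_config <- function() {
  list(
    fiber = list(
      window_px = 65L,          # local-Otsu window side (~6.4 um at 0.099 um/px)
      prefilter_sigma = 1,      # Gaussian prefilter, voxels
      min_fiber_um = 2,         # discard traced fibers shorter than this
      max_turn_deg = 40,        # junction continuation angle limit
      noise_floor_mads = 2      # window dynamic-range guard, in background MADs
    ),
    remodeling = list(
      roi_px = 100L,            # anisotropy / density ROI side
      f_lo_cycles = NA,         # NA: use 4/side
      f_hi_cycles = 0.45,       # radial band upper limit, cycles/px
      band_um = 7               # doughnut ROI thickness
    ),
    degradation = list(
      closing_r_px = 2L,
      median_r_px = 1L,
      per_slice = FALSE         # TRUE: 2D slice-wise morphology
    ),
    fa2d = list(
      median_radius = 2L,
      background_radius = 50L,  # rolling-ball radius, px
      clahe_block = 19L, clahe_bins = 256L, clahe_slope = 6,
      contrast_saturation = 0.35,  # % saturated per tail
      log_sigma = c(5, 5),
      min_size = 50,            # px^2
      circularity = c(0, 1.0)
    ),
    fa3d = list(
      median_radius_vox = 1L,
      rollball_radius_px = 10L,
      gamma = 2.1,
      threshold_quantile = 0.99,   # used when no fixed threshold given
      watershed_dynamic = 1,       # h-maxima depth, um of EDM height
      perinuclear_band_um = 5
    ),
    motility = list(
      clahe_block = 64L, clahe_bins = 256L, clahe_slope = 3,
      min_area_px = 20L,
      max_disp_um = 30,
      dt_min = 15,
      min_track_fraction = 0.75
    )
  )
}

#' Load an analysis configuration from YAML
#'
#' Reads a YAML file with any subset of the blocks of [default_config()] and
#' merges it over the defaults. Unknown blocks or unknown keys within a block
#' are rejected.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @param overrides optional nested list applied after the file (e.g. from
#'   command-line flags).
#' @return full configuration list.
#' @export
load_config <- function(path = NULL, overrides = NULL) {
  cfg <- default_config()
  apply_layer <- function(cfg, layer, origin) {
    if (is.null(layer)) return(cfg)
    if (!is.list(layer)) stop("configuration ", origin, " must be a named list")
    bad <- setdiff(names(layer), names(cfg))
    if (length(bad))
      stop("unknown configuration block(s) in ", origin, ": ",
           paste(bad, collapse = ", "))
    for (blk in names(layer)) {
      badk <- setdiff(names(layer[[blk]]), names(cfg[[blk]]))
      if (length(badk))
        stop("unknown key(s) in block '", blk, "' (", origin, "): ",
             paste(badk, collapse = ", "))
      cfg[[blk]] <- utils::modifyList(cfg[[blk]], layer[[blk]])
    }
    cfg
  }
  if (!is.null(path)) cfg <- apply_layer(cfg, yaml::read_yaml(path), path)
  cfg <- apply_layer(cfg, overrides, "overrides")
  cfg
}

# ---- logging ---------------------------------------------------------------

# INFO-level audit log: input geometry, parameter block, summary outputs.
# Silenced with options(remodelkit.verbose = FALSE).
rk_log <- function(fmt, ...) {
  if (isTRUE(getOption("remodelkit.verbose", TRUE)))
    message(sprintf(paste0("INFO [remodelkit] ", fmt), ...))
  invisible(NULL)
}

rk_log_image <- function(what, vol) {
  d <- dim(vol$values)
  rk_log("%s: %d x %d x %d voxels, spacing (%.4g, %.4g, %.4g) um", what,
         d[1], d[2], d[3], vol$spacing[1], vol$spacing[2], vol$spacing[3])
}
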