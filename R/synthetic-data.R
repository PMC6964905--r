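# Ground-truthed synthetic scene generators.
#
# Every pipeline in the package is validated against scenes produced here:
# persistent-random-walk fiber meshes, cell + focal-adhesion scenes (2D/3D),
# DQ-degradation blob stacks, and moving-cell time-lapses. All ground-truth
# quantities are computed from the generating geometry before rasterization
# and noise, never from the rendered image. Separation constraints (between
# punctae, blobs and cells) are enforced so that recovery tests have
# unambiguous expected values.

# Run code under a fixed seed without disturbing the caller's RNG stream.
.with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

# Von Mises sampler (Best & Fisher rejection scheme). kappa = 0 falls back to
# the circular uniform; kappa >= 1e6 is treated as the point-mass limit.
.rvonmises <- function(n, mu = 0, kappa = 1) {
  if (n == 0L) return(numeric(0))
  if (kappa < 1e-12) return(((stats::runif(n, -pi, pi) + mu + pi) %% (2 * pi)) - pi)
  if (kappa >= 1e6) return(rep(mu, n))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(0)
  while (length(out) < n) {
    m <- n - length(out)
    z <- cos(pi * stats::runif(m))
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    u2 <- stats::runif(m)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    vals <- f[ok]
    if (length(vals)) {
      th <- sign(stats::runif(length(vals)) - 0.5) * acos(pmin(1, pmax(-1, vals)))
      out <- c(out, th)
    }
  }
  ((out[seq_len(n)] + mu + pi) %% (2 * pi)) - pi
}

# Axial orientation sample on [0, pi): von Mises on the doubled angle.
.raxial <- function(n, theta0 = 0, kappa = 0) {
  (0.5 * .rvonmises(n, 2 * theta0, kappa)) %% pi
}

# Rasterize polylines (um coordinates) into an intensity image with a
# Gaussian cross-profile of half-width radius_px: mark centerline voxels,
# then intensity = exp(-d_px^2 / (2 radius_px^2)) from the pixel EDT.
.rasterize_polylines <- function(polys, shape_yx, spacing, radius_px) {
  center <- array(FALSE, dim = c(shape_yx[1], shape_yx[2], 1L))
  dx <- spacing[1]; dy <- spacing[2]
  ds <- 0.4 * min(dx, dy)
  for (p in polys) {
    if (nrow(p) < 2L) next
    for (s in seq_len(nrow(p) - 1L)) {
      a <- p[s, ]; b <- p[s + 1L, ]
      len <- sqrt(sum((b - a)^2))
      tt <- seq(0, 1, length.out = max(2L, ceiling(len / ds) + 1L))
      xs <- a[1] + tt * (b[1] - a[1])
      ys <- a[2] + tt * (b[2] - a[2])
      j <- round(xs / dx) + 1L
      i <- round(ys / dy) + 1L
      keep <- i >= 1L & i <= shape_yx[1] & j >= 1L & j <= shape_yx[2]
      center[cbind(i[keep], j[keep], 1L)] <- TRUE
    }
  }
  if (!any(center)) return(array(0, dim = dim(center)))
  dpx <- distance_transform(center, spacing = c(1, 1, 1))
  img <- exp(-dpx^2 / (2 * radius_px^2))
  img[dpx > 4 * radius_px] <- 0 # finite support: far field is truly empty
  img
}

.add_noise <- function(v, gaussian_sigma = 0, poisson_scale = 0) {
  if (poisson_scale > 0)
    v <- array(stats::rpois(length(v), pmax(v, 0) * poisson_scale) / poisson_scale,
               dim = dim(v))
  if (gaussian_sigma > 0)
    v <- v + array(stats::rnorm(length(v), 0, gaussian_sigma), dim = dim(v))
  pmax(v, 0)
}

#' Parameters for the synthetic fiber-field generator
#'
#' Fibers are persistent random walks: the initial orientation of each fiber
#' is axial von Mises about `theta0` with concentration `kappa_orient`
#' (0 = isotropic network), and each subsequent step of length `step_um`
#' turns by a von Mises angle with concentration `kappa_step` (larger =
#' straighter fibers, i.e. longer persistence length).
#'
#' @param n_fibers number of fibers.
#' @param step_um step length of the generating walk, um.
#' @param kappa_step von Mises concentration of per-step turning.
#' @param kappa_orient von Mises concentration of initial orientations about
#'   `theta0`; 0 gives an isotropic network.
#' @param theta0 mean fiber orientation, radians (axial, modulo pi).
#' @param fiber_length_um length-2 range; per-fiber contour length is drawn
#'   uniformly from it.
#' @param radius_px rasterized fiber half-width, pixels (>= 1).
#' @param shape image dimensions `(ny, nx)`, pixels.
#' @param spacing voxel pitch in um; default matches a 63x confocal
#'   acquisition (0.099 um/px in-plane).
#' @param noise `(gaussian_sigma, poisson_scale)`; the Gaussian component is
#'   on the [0,1] intensity scale (default SNR ~ 10), `poisson_scale = 0`
#'   disables shot noise.
#' @param seed integer RNG seed.
#' @return parameter list of class `fiber_field_params`.
#' @export
fiber_field_params <- function(n_fibers = 150L, step_um = 0.5, kappa_step = 30,
                               kappa_orient = 0, theta0 = 0,
                               fiber_length_um = c(6, 14), radius_px = 1,
                               shape = c(256L, 256L),
                               spacing = c(0.099, 0.099, 0.42),
                               noise = c(0.1, 0), seed = 1L) {
  stopifnot(n_fibers >= 0, kappa_orient >= 0, kappa_step >= 0, radius_px >= 1,
            step_um > 0, length(fiber_length_um) == 2L,
            all(fiber_length_um > 0))
  structure(as.list(environment()), class = "fiber_field_params")
}

#' Generate a synthetic fiber-network image with ground truth
#'
#' Emulates a fluorescently labeled (e.g. TAMRA) collagen mesh: persistent
#' random-walk fibers rasterized with a Gaussian cross-profile, plus read
#' noise. Ground-truth polylines are returned in micrometre coordinates,
#' computed before rasterization.
#'
#' @param params a [fiber_field_params()] list.
#' @return list with `image` (an [image_stack()]) and `truth`: list of
#'   polyline matrices (columns `x`, `y`, um), initial orientations
#'   `theta` (radians in `[0, pi)`), and contour lengths `length_um`.
#' @export
generate_fiber_image <- function(params) {
  stopifnot(inherits(params, "fiber_field_params"))
  p <- params
  .with_seed(p$seed, {
    ext <- c(p$shape[2] * p$spacing[1], p$shape[1] * p$spacing[2]) # (x, y) um
    thetas <- .raxial(p$n_fibers, p$theta0, p$kappa_orient)
    lens <- stats::runif(p$n_fibers, p$fiber_length_um[1], p$fiber_length_um[2])
    polys <- vector("list", p$n_fibers)
    for (f in seq_len(p$n_fibers)) {
      n_steps <- max(1L, round(lens[f] / p$step_um))
      # random +/- direction along the axial orientation
      dir0 <- thetas[f] + sample(c(0, pi), 1L)
      turns <- .rvonmises(n_steps - 1L, 0, p$kappa_step)
      angs <- dir0 + cumsum(c(0, turns))
      start <- c(stats::runif(1, 0, ext[1]), stats::runif(1, 0, ext[2]))
      xy <- rbind(start,
                  cbind(start[1] + cumsum(p$step_um * cos(angs)),
                        start[2] + cumsum(p$step_um * sin(angs))))
      colnames(xy) <- c("x", "y")
      rownames(xy) <- NULL
      polys[[f]] <- xy
    }
    img <- .rasterize_polylines(polys, p$shape, p$spacing, p$radius_px)
    img <- .add_noise(img, p$noise[1], if (length(p$noise) > 1) p$noise[2] else 0)
    list(image = image_stack(img, spacing = p$spacing, bit_depth = 32L,
                             channel = "fibers"),
         truth = list(polylines = polys, theta = thetas,
                      length_um = vapply(polys, function(m)
                        sum(sqrt(rowSums(diff(m)^2))), numeric(1))))
  })
}

#' Parameters for the synthetic focal-adhesion scene generator
#'
#' @param shape image dimensions: `(ny, nx)` for 2D, `(ny, nx, nz)` for 3D.
#' @param spacing voxel pitch, um; default 0.1 um/px in-plane for 2D scenes
#'   and `c(0.25, 0.25, 0.5)` for 3D stacks.
#' @param cell_semiaxes ellipse (2D) or ellipsoid (3D) semi-axes of the cell
#'   body, in voxels, centred in the image.
#' @param nucleus_radius_um nucleus radius, um (sphere/disc at the cell
#'   centre); default 3 um in 2D, 2 um in 3D.
#' @param n_fa number of focal adhesions to place inside the cell mask.
#' @param fa_size range of per-FA footprint (area px^2 in 2D, volume voxels
#'   in 3D, measured at half-maximum), drawn uniformly.
#' @param min_gap_px minimum edge-to-edge separation between FA footprints,
#'   pixels (>= 3 enforced so detections are unambiguous).
#' @param avoid_perinuclear_band_um if set, FA centres are additionally kept
#'   more than this physical distance from the nucleus, e.g. to build scenes
#'   with every FA outside the perinuclear exclusion band.
#' @param fa_peak,cell_level,background intensity levels on [0,1].
#' @param noise_sigma Gaussian read-noise sd (default gives SNR ~ 10 for the
#'   FA peak over the cell body).
#' @param seed RNG seed.
#' @return parameter list of class `fa_scene_params`.
#' @export
fa_scene_params <- function(shape = c(300L, 300L), spacing = NULL,
                            cell_semiaxes = NULL, nucleus_radius_um = NULL,
                            n_fa = 12L, fa_size = c(60, 120), min_gap_px = 3,
                            avoid_perinuclear_band_um = NULL,
                            fa_peak = 1, cell_level = 0.2, background = 0.05,
                            noise_sigma = 0.08, seed = 1L) {
  stopifnot(n_fa >= 0, min_gap_px >= 3, length(fa_size) == 2L)
  three_d <- length(shape) == 3L && shape[3] > 1L
  if (is.null(spacing))
    spacing <- if (three_d) c(0.25, 0.25, 0.5) else c(0.1, 0.1, 0.5)
  if (is.null(nucleus_radius_um)) nucleus_radius_um <- if (three_d) 2 else 3
  if (is.null(cell_semiaxes))
    cell_semiaxes <- if (three_d) c(0.42, 0.33, 0.42) * shape else 0.4 * shape[1:2]
  structure(as.list(environment()), class = "fa_scene_params")
}

#' Generate a synthetic cell with focal-adhesion punctae (2D or 3D)
#'
#' Renders a diffusely labeled cell body (ellipse/ellipsoid), a nuclear
#' mask, and `n_fa` Gaussian punctae whose half-maximum footprint matches
#' the requested size, all placed inside the cell mask with enforced
#' pairwise separation. Placement failure after bounded retries is an error.
#'
#' @param params a [fa_scene_params()] list.
#' @return list with `image`, `truth` (data.frame: id, centre um and voxel
#'   indices, size at half-max, `perinuclear` flag = centre within 5 um of
#'   the nucleus), `cell_mask`, `nucleus_mask`.
#' @export
generate_fa_scene <- function(params) {
  stopifnot(inherits(params, "fa_scene_params"))
  p <- params
  three_d <- p$three_d
  shp <- if (three_d) p$shape else c(p$shape[1:2], 1L)
  .with_seed(p$seed, {
    d <- shp
    iy <- array(rep(seq_len(d[1]), times = d[2] * d[3]), dim = d)
    ix <- array(rep(rep(seq_len(d[2]), each = d[1]), times = d[3]), dim = d)
    iz <- array(rep(seq_len(d[3]), each = d[1] * d[2]), dim = d)
    cen <- (d + 1) / 2
    ax <- p$cell_semiaxes
    if (length(ax) == 2L) ax <- c(ax, Inf)
    cell <- ((iy - cen[1]) / ax[1])^2 + ((ix - cen[2]) / ax[2])^2 +
      (if (three_d) ((iz - cen[3]) / ax[3])^2 else 0) <= 1
    # nucleus: physical sphere/disc at the cell centre
    r2_um <- ((iy - cen[1]) * p$spacing[2])^2 + ((ix - cen[2]) * p$spacing[1])^2 +
      (if (three_d) ((iz - cen[3]) * p$spacing[3])^2 else 0)
    nucleus <- r2_um <= p$nucleus_radius_um^2
    nucleus <- nucleus & cell

    # FA sizes -> Gaussian sd (voxel units) from the half-maximum footprint
    sizes <- stats::runif(p$n_fa, p$fa_size[1], p$fa_size[2])
    sds <- if (three_d) (sizes * 3 / (4 * pi))^(1 / 3) / sqrt(2 * log(2))
           else sqrt(sizes / (2 * pi * log(2)))
    radii <- sds * sqrt(2 * log(2)) # half-max footprint radius, voxels

    centers <- matrix(NA_real_, p$n_fa, 3L)
    allowed <- cell & !nucleus
    if (!is.null(p$avoid_perinuclear_band_um) && any(nucleus)) {
      ndist <- distance_transform(nucleus, p$spacing)
      allowed <- allowed & ndist > p$avoid_perinuclear_band_um
    }
    inside <- which(allowed)
    if (p$n_fa > 0L && !length(inside)) stop("cell mask too small for FAs")
    for (k in seq_len(p$n_fa)) {
      placed <- FALSE
      for (try in seq_len(5000L)) {
        v <- inside[sample.int(length(inside), 1L)]
        pos <- c(iy[v], ix[v], iz[v])
        if (k > 1L) {
          prev <- centers[seq_len(k - 1L), , drop = FALSE]
          sep <- sqrt((prev[, 1] - pos[1])^2 + (prev[, 2] - pos[2])^2 +
                        (prev[, 3] - pos[3])^2)
          if (any(sep < radii[k] + radii[seq_len(k - 1L)] + p$min_gap_px)) next
        }
        # keep the footprint inside the cell
        if (pos[1] - radii[k] < 1 || pos[1] + radii[k] > d[1] ||
            pos[2] - radii[k] < 1 || pos[2] + radii[k] > d[2]) next
        centers[k, ] <- pos
        placed <- TRUE
        break
      }
      if (!placed) stop("could not place ", p$n_fa,
                        " non-overlapping focal adhesions; reduce n_fa or sizes")
    }

    img <- array(p$background, dim = d)
    img[cell] <- p$cell_level
    for (k in seq_len(p$n_fa)) {
      g <- exp(-((iy - centers[k, 1])^2 + (ix - centers[k, 2])^2 +
                   (iz - centers[k, 3])^2) / (2 * sds[k]^2))
      img <- pmax(img, p$cell_level + (p$fa_peak - p$cell_level) * g)
    }
    img <- .add_noise(img, p$noise_sigma, 0)

    nuc_d <- if (any(nucleus)) distance_transform(nucleus, p$spacing) else
      array(Inf, dim = d)
    truth <- data.frame(
      id = seq_len(p$n_fa),
      y_vox = centers[, 1], x_vox = centers[, 2], z_vox = centers[, 3],
      x_um = (centers[, 2] - 1) * p$spacing[1],
      y_um = (centers[, 1] - 1) * p$spacing[2],
      z_um = (centers[, 3] - 1) * p$spacing[3],
      size = sizes,
      perinuclear = if (p$n_fa) nuc_d[centers] <= 5 else logical(0)
    )
    list(image = image_stack(img, spacing = p$spacing, bit_depth = 32L,
                             channel = "vinculin"),
         truth = truth,
         cell_mask = binary_mask(cell, p$spacing),
         nucleus_mask = binary_mask(nucleus, p$spacing))
  })
}

#' Generate a synthetic DQ-collagen degradation scene
#'
#' Places `n_blobs` compact clusters of exactly `blob_vox_each` voxels each
#' (near-cubic, raster-filled), pairwise separated by more than
#' `separation_um`, on a dim background. The ground-truth degraded volume is
#' `n_blobs * blob_vox_each * dx*dy*dz`, fixed by construction.
#'
#' @param n_blobs number of degradation blobs.
#' @param blob_vox_each voxels per blob (exact).
#' @param n_cells cell count carried into the truth (per-cell normalization).
#' @param shape stack dimensions `(ny, nx, nz)`.
#' @param spacing voxel pitch, um.
#' @param separation_um minimum gap between blob bounding boxes, um; keep it
#'   above the closing diameter used in segmentation so blobs never merge.
#' @param background,noise_sigma background level and Gaussian noise sd.
#' @param seed RNG seed.
#' @return list with `image`, `truth` (list: `total_volume_um3`, `n_blobs`,
#'   `n_cells`, `blob_mask`).
#' @export
generate_dq_scene <- function(n_blobs = 5L, blob_vox_each = 1000L,
                              n_cells = 2L, shape = c(96L, 96L, 32L),
                              spacing = c(0.312, 0.312, 0.49),
                              separation_um = 3, background = 0.05,
                              noise_sigma = 0.02, seed = 1L) {
  stopifnot(n_blobs >= 0, blob_vox_each >= 1, n_cells >= 1)
  .with_seed(seed, {
    d <- shape
    side <- ceiling(blob_vox_each^(1 / 3))
    # raster-fill `blob_vox_each` voxels of a side^3 cube (connected, compact)
    fill <- arrayInd(seq_len(blob_vox_each), c(side, side, side))
    mask <- array(FALSE, dim = d)
    placed <- matrix(NA_real_, 0L, 3L)
    margin_vox <- ceiling(separation_um / spacing) # (x, y, z) gaps in voxels
    need <- side + c(margin_vox[2], margin_vox[1], margin_vox[3])
    for (b in seq_len(n_blobs)) {
      ok <- FALSE
      for (try in seq_len(5000L)) {
        org <- c(sample.int(d[1] - side, 1L), sample.int(d[2] - side, 1L),
                 sample.int(max(1L, d[3] - side), 1L))
        if (nrow(placed)) {
          gap_ok <- all(rowSums(abs(sweep(placed, 2, org)) >=
                                  matrix(need, nrow(placed), 3L, byrow = TRUE)) > 0)
          if (!gap_ok) next
        }
        ok <- TRUE
        placed <- rbind(placed, org)
        mask[cbind(fill[, 1] + org[1] - 1L, fill[, 2] + org[2] - 1L,
                   fill[, 3] + org[3] - 1L)] <- TRUE
        break
      }
      if (!ok) stop("could not place ", n_blobs, " separated blobs; ",
                    "reduce n_blobs or blob size")
    }
    img <- array(background, dim = d)
    img[mask] <- 1
    img <- .add_noise(img, noise_sigma, 0)
    vox_um3 <- prod(spacing)
    list(image = image_stack(img, spacing = spacing, bit_depth = 32L,
                             channel = "DQ"),
         truth = list(total_volume_um3 = n_blobs * blob_vox_each * vox_um3,
                      n_blobs = n_blobs, n_cells = n_cells,
                      blob_mask = binary_mask(mask, spacing)))
  })
}

#' Parameters for the synthetic time-lapse generator
#'
#' Defaults emulate the migration acquisitions the tracking pipeline targets:
#' one frame every 15 minutes for 12 hours (49 frames).
#'
#' @param n_cells number of cells.
#' @param n_frames frames per video (>= 2).
#' @param dt_min minutes between frames.
#' @param step_um per-frame displacement: a single value (fixed step) or a
#'   length-2 range sampled uniformly per frame.
#' @param drift `(dx, dy)` deterministic drift, um/frame; when non-zero and
#'   `step_um = 0` the motion is pure drift.
#' @param cell_radius_px rendered cell disc radius, pixels.
#' @param shape frame dimensions `(ny, nx)`.
#' @param spacing pixel pitch `(dx, dy)`, um (5x objective scale by default).
#' @param background,noise_sigma rendering levels.
#' @param seed RNG seed.
#' @return parameter list of class `track_sim_params`.
#' @export
track_sim_params <- function(n_cells = 5L, n_frames = 49L, dt_min = 15,
                             step_um = c(1, 3), drift = c(0, 0),
                             cell_radius_px = 4L, shape = c(256L, 256L),
                             spacing = c(2.5, 2.5), background = 0.05,
                             noise_sigma = 0.03, seed = 1L) {
  stopifnot(n_frames >= 2L, dt_min > 0, n_cells >= 0)
  structure(as.list(environment()), class = "track_sim_params")
}

#' Generate a synthetic migration time-lapse with ground-truth tracks
#'
#' Cells are bright discs, blurred by a 1-pixel Gaussian point-spread
#' function so that their rendered boundary moves continuously with
#' sub-pixel motion, performing a uniform-direction random walk plus
#' optional drift, reflected at the field borders (step lengths preserved).
#' No two cells come closer than `4 * cell_radius` at any frame, which
#' guarantees unambiguous nearest-neighbour linking; if the constraint
#' cannot be met the generator errors. The ground-truth accumulated distance
#' of each cell is the sum of its realized per-frame step lengths.
#'
#' @param params a [track_sim_params()] list.
#' @return list with `frames` (list of [image_stack()]), `truth` (a
#'   [track_set()]), and `accumulated_um` (per-cell ground truth).
#' @export
generate_timelapse <- function(params) {
  stopifnot(inherits(params, "track_sim_params"))
  p <- params
  .with_seed(p$seed, {
    ext <- c(p$shape[2] * p$spacing[1], p$shape[1] * p$spacing[2]) # x, y um
    min_sep <- 4 * p$cell_radius_px * max(p$spacing)
    for (attempt in seq_len(200L)) {
      # start positions with margin, separated
      pos <- matrix(NA_real_, p$n_cells, 2L)
      fail <- FALSE
      for (k in seq_len(p$n_cells)) {
        okk <- FALSE
        for (try in seq_len(2000L)) {
          cand <- c(stats::runif(1, 0.1 * ext[1], 0.9 * ext[1]),
                    stats::runif(1, 0.1 * ext[2], 0.9 * ext[2]))
          if (k == 1L ||
              all(sqrt(rowSums(sweep(pos[seq_len(k - 1L), , drop = FALSE],
                                     2, cand)^2)) >= min_sep)) {
            pos[k, ] <- cand; okk <- TRUE; break
          }
        }
        if (!okk) { fail <- TRUE; break }
      }
      if (fail) next
      traj <- array(NA_real_, dim = c(p$n_cells, p$n_frames, 2L))
      traj[, 1L, ] <- pos
      for (t in seq_len(p$n_frames - 1L)) {
        steps <- if (length(p$step_um) == 2L)
          stats::runif(p$n_cells, p$step_um[1], p$step_um[2])
        else rep(p$step_um, p$n_cells)
        dirs <- stats::runif(p$n_cells, 0, 2 * pi)
        dx <- steps * cos(dirs) + p$drift[1]
        dy <- steps * sin(dirs) + p$drift[2]
        nx <- traj[, t, 1L] + dx
        ny <- traj[, t, 2L] + dy
        # reflect at borders (preserves step length)
        nx <- ifelse(nx < 0, -nx, ifelse(nx > ext[1], 2 * ext[1] - nx, nx))
        ny <- ifelse(ny < 0, -ny, ifelse(ny > ext[2], 2 * ext[2] - ny, ny))
        traj[, t + 1L, 1L] <- nx
        traj[, t + 1L, 2L] <- ny
      }
      # crowding check over all frames
      ok_sep <- TRUE
      if (p$n_cells > 1L) {
        for (t in seq_len(p$n_frames)) {
          dmat <- as.matrix(stats::dist(traj[, t, ]))
          diag(dmat) <- Inf
          if (min(dmat) < min_sep) { ok_sep <- FALSE; break }
        }
      }
      if (ok_sep) break
      if (attempt == 200L) stop("crowding constraint unsatisfiable; ",
                                "reduce n_cells or step size")
    }

    acc <- vapply(seq_len(max(p$n_cells, 1L)), function(k) {
      if (p$n_cells == 0L) return(0)
      sum(sqrt(rowSums(diff(traj[k, , , drop = TRUE])^2)))
    }, numeric(1))
    if (p$n_cells == 0L) acc <- numeric(0)

    frames <- vector("list", p$n_frames)
    d2 <- c(p$shape[1:2], 1L)
    iy <- matrix(seq_len(d2[1]), d2[1], d2[2])
    ix <- matrix(seq_len(d2[2]), d2[1], d2[2], byrow = TRUE)
    for (t in seq_len(p$n_frames)) {
      fr <- matrix(p$background, d2[1], d2[2])
      for (k in seq_len(p$n_cells)) {
        cx <- traj[k, t, 1L] / p$spacing[1] + 1
        cy <- traj[k, t, 2L] / p$spacing[2] + 1
        # area-sampled disc edge: intensity follows the true sub-pixel
        # centre continuously, as a band-limited microscope image would
        cov <- p$cell_radius_px + 0.5 - sqrt((iy - cy)^2 + (ix - cx)^2)
        cov[cov < 0] <- 0; cov[cov > 1] <- 1
        fr <- pmax(fr, p$background + (1 - p$background) * cov)
      }
      fr <- EBImage::gblur(fr, sigma = 1) # point-spread function
      fr <- .add_noise(fr, p$noise_sigma, 0)
      frames[[t]] <- image_stack(fr, spacing = c(p$spacing, 1),
                                 bit_depth = 32L, channel = "cells",
                                 time_index = t)
    }
    df <- do.call(rbind, lapply(seq_len(p$n_cells), function(k)
      data.frame(cell_id = k, frame = seq_len(p$n_frames),
                 t_min = (seq_len(p$n_frames) - 1) * p$dt_min,
                 x_um = traj[k, , 1L], y_um = traj[k, , 2L])))
    if (is.null(df)) df <- data.frame(cell_id = integer(0), frame = integer(0),
                                      t_min = numeric(0), x_um = numeric(0),
                                      y_um = numeric(0))
    list(frames = frames, truth = track_set(df, p$dt_min),
         accumulated_um = acc)
  })
}
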