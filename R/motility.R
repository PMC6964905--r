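# Time-lapse cell motility: frame enhancement, mean-intensity segmentation,
# constrained nearest-neighbour track linking, and accumulated-distance /
# speed statistics.

#' Construct a track set
#'
#' Per-cell time-stamped positions. Frame indices must be strictly
#' increasing within a track, and every detection belongs to at most one
#' track.
#'
#' @param tracks data.frame with columns `cell_id`, `frame`, `t_min`,
#'   `x_um`, `y_um`.
#' @param dt_min minutes between consecutive frames.
#' @return object of class `track_set`.
#' @export
track_set <- function(tracks, dt_min) {
  need <- c("cell_id", "frame", "t_min", "x_um", "y_um")
  if (!all(need %in% names(tracks)))
    stop("tracks need columns: ", paste(need, collapse = ", "))
  if (dt_min <= 0) stop("'dt_min' must be > 0")
  for (id in unique(tracks$cell_id)) {
    fr <- tracks$frame[tracks$cell_id == id]
    if (any(diff(fr) <= 0))
      stop("frame indices must be strictly increasing within track ", id)
  }
  structure(list(tracks = tracks, dt_min = dt_min), class = "track_set")
}

#' @export
print.track_set <- function(x, ...) {
  ids <- unique(x$tracks$cell_id)
  cat(sprintf("<track_set> %d tracks, %d detections, dt = %g min\n",
              length(ids), nrow(x$tracks), x$dt_min))
  invisible(x)
}

#' Enhance a time-lapse frame with CLAHE
#'
#' Contrast-limited adaptive histogram equalization; the output is
#' range-normalized to [0,1]. A constant frame passes through unchanged.
#'
#' @param frame 2D [image_stack()] (or matrix).
#' @param block,bins,slope CLAHE tile size (px), histogram bins and clip
#'   slope.
#' @return an [image_stack()] of the enhanced frame.
#' @export
enhance_frame <- function(frame, block = 64L, bins = 256L, slope = 3) {
  vol <- .as_vol(frame)
  if (dim(vol$values)[3] != 1L) stop("enhance_frame expects a 2D frame")
  m <- vol$values[, , 1]
  if (diff(range(m)) == 0)
    return(image_stack(m, spacing = vol$spacing, bit_depth = 32L))
  out <- .clahe(.norm01(m), block, bins, slope)
  image_stack(.norm01(out), spacing = vol$spacing, bit_depth = 32L)
}

#' Segment cells in an enhanced frame
#'
#' Two-phase piecewise-constant partition by the intermeans fixed point
#' (iterated thresholding at the midpoint of the two region means -- the
#' same mean-intensity criterion used by graph-cut cell segmenters), then
#' connected components of at least `min_area_px` pixels.
#'
#' @param frame 2D [image_stack()] (ideally from [enhance_frame()]).
#' @param min_area_px minimum component area, px.
#' @return list: `labels` (integer matrix), `centroids` (data.frame with
#'   `label`, `x_um`, `y_um`, `area_px`). An empty frame (no surviving
#'   component) is valid and yields zero rows.
#' @export
segment_cells <- function(frame, min_area_px = 20L) {
  vol <- .as_vol(frame)
  if (dim(vol$values)[3] != 1L) stop("segment_cells expects a 2D frame")
  m <- vol$values[, , 1]
  sp <- vol$spacing
  if (diff(range(m)) == 0) {
    return(list(labels = matrix(0L, nrow(m), ncol(m)),
                centroids = data.frame(label = integer(0), x_um = numeric(0),
                                       y_um = numeric(0), area_px = integer(0))))
  }
  thr <- .intermeans_threshold(as.vector(m))
  bin <- m > thr
  lab <- .label_components(array(bin, c(dim(bin), 1L)))[, , 1]
  n <- max(lab)
  if (n == 0L)
    return(list(labels = lab,
                centroids = data.frame(label = integer(0), x_um = numeric(0),
                                       y_um = numeric(0), area_px = integer(0))))
  areas <- tabulate(lab[lab > 0L], nbins = n)
  keep <- which(areas >= min_area_px)
  cents <- do.call(rbind, lapply(keep, function(l) {
    w <- which(lab == l, arr.ind = TRUE)
    # background-subtracted centre of mass: boundary pixels carry ~zero
    # weight, so the centroid moves continuously with sub-pixel motion
    # (a binary centroid flickers with boundary-pixel inclusion)
    wt <- pmax(m[w] - thr, 0)
    if (sum(wt) == 0) wt <- rep(1, length(wt))
    data.frame(label = l,
               x_um = (sum(w[, 2] * wt) / sum(wt) - 1) * sp[1],
               y_um = (sum(w[, 1] * wt) / sum(wt) - 1) * sp[2],
               area_px = nrow(w))
  }))
  if (is.null(cents))
    cents <- data.frame(label = integer(0), x_um = numeric(0),
                        y_um = numeric(0), area_px = integer(0))
  lab[!(lab %in% keep)] <- 0L
  list(labels = lab, centroids = cents)
}

#' Link per-frame detections into tracks
#'
#' Constrained mutual nearest-neighbour linking between consecutive frames:
#' a link is made only when the two detections choose each other as nearest
#' neighbour and their distance is at most `max_disp_um`. Unmatched
#' detections start new tracks; a track that loses its cell ends (no gap
#' closing), and a reappearing cell starts a new track. Ties are broken by
#' smaller distance, then lower detection label.
#'
#' @param detections list (one element per frame) of data.frames with
#'   columns `x_um`, `y_um` (e.g. `centroids` from [segment_cells()]).
#' @param max_disp_um maximum linkable displacement per frame, um.
#' @param dt_min minutes between frames.
#' @return a [track_set()].
#' @export
link_tracks <- function(detections, max_disp_um = 30, dt_min = 15) {
  if (length(detections) < 2L) stop("need >= 2 frames of detections")
  n_frames <- length(detections)
  rows <- list()
  next_id <- 1L
  # active track id per detection of the current frame
  cur <- detections[[1L]]
  cur_ids <- integer(nrow(cur))
  if (nrow(cur)) {
    cur_ids <- seq_len(nrow(cur))
    next_id <- nrow(cur) + 1L
    for (i in seq_len(nrow(cur)))
      rows[[length(rows) + 1L]] <- data.frame(
        cell_id = cur_ids[i], frame = 1L, t_min = 0,
        x_um = cur$x_um[i], y_um = cur$y_um[i])
  }
  for (t in 2L:n_frames) {
    nxt <- detections[[t]]
    n1 <- nrow(cur); n2 <- nrow(nxt)
    assigned <- integer(n2) # track id per detection in frame t (0 = new)
    if (n1 > 0L && n2 > 0L) {
      dmat <- outer(cur$x_um, nxt$x_um, "-")^2 + outer(cur$y_um, nxt$y_um, "-")^2
      dmat <- sqrt(dmat)
      # mutual nearest neighbours within the displacement gate
      nn12 <- apply(dmat, 1L, which.min) # for each prev det: best next
      nn21 <- apply(dmat, 2L, which.min) # for each next det: best prev
      pairs <- which(nn21[nn12] == seq_len(n1)) # mutual
      if (length(pairs)) {
        cand <- data.frame(i = pairs, j = nn12[pairs],
                           d = dmat[cbind(pairs, nn12[pairs])])
        cand <- cand[cand$d <= max_disp_um, , drop = FALSE]
        cand <- cand[order(cand$d, cand$i), , drop = FALSE]
        used_j <- logical(n2)
        for (r in seq_len(nrow(cand))) {
          if (used_j[cand$j[r]]) next
          assigned[cand$j[r]] <- cur_ids[cand$i[r]]
          used_j[cand$j[r]] <- TRUE
        }
      }
    }
    new_ids <- integer(n2)
    for (j in seq_len(n2)) {
      if (assigned[j] > 0L) {
        new_ids[j] <- assigned[j]
      } else {
        new_ids[j] <- next_id
        next_id <- next_id + 1L
      }
      rows[[length(rows) + 1L]] <- data.frame(
        cell_id = new_ids[j], frame = t, t_min = (t - 1) * dt_min,
        x_um = nxt$x_um[j], y_um = nxt$y_um[j])
    }
    cur <- nxt
    cur_ids <- new_ids
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cell_id = integer(0), frame = integer(0), t_min = numeric(0),
               x_um = numeric(0), y_um = numeric(0))
  df <- df[order(df$cell_id, df$frame), ]
  rownames(df) <- NULL
  track_set(df, dt_min)
}

#' Motility statistics: mean accumulated distance and speed
#'
#' Per-track accumulated distance is the summed frame-to-frame path length;
#' per-track speed divides it by the track's elapsed time in hours. The
#' mean accumulated distance (MAD) and mean speed average these over tracks
#' with at least `min_track_frames` detections (default: 75 % of the
#' longest observed span, so short fragments do not dilute the statistics).
#'
#' @param tracks a [track_set()].
#' @param min_track_frames minimum detections per qualifying track; `NULL`
#'   uses 75 % of the maximum track length, `1` keeps every track.
#' @return list of class `motility_result`: `mad_um`, `mean_speed_um_per_h`,
#'   `n_tracks`, and the per-track data.frame `per_track`.
#' @export
motility_stats <- function(tracks, min_track_frames = NULL) {
  stopifnot(inherits(tracks, "track_set"))
  df <- tracks$tracks
  if (!nrow(df)) stop("no tracks")
  ids <- unique(df$cell_id)
  per <- do.call(rbind, lapply(ids, function(id) {
    tr <- df[df$cell_id == id, ]
    n <- nrow(tr)
    ad <- if (n >= 2L) sum(sqrt(diff(tr$x_um)^2 + diff(tr$y_um)^2)) else 0
    hours <- (tr$t_min[n] - tr$t_min[1]) / 60
    data.frame(cell_id = id, n_frames = n, accumulated_um = ad,
               elapsed_h = hours,
               speed_um_per_h = if (hours > 0) ad / hours else 0)
  }))
  if (is.null(min_track_frames))
    min_track_frames <- ceiling(0.75 * max(per$n_frames))
  qual <- per[per$n_frames >= min_track_frames & per$elapsed_h > 0, ,
              drop = FALSE]
  if (!nrow(qual)) stop("no qualifying tracks (min_track_frames = ",
                        min_track_frames, ")")
  res <- structure(list(mad_um = mean(qual$accumulated_um),
                        mean_speed_um_per_h = mean(qual$speed_um_per_h),
                        n_tracks = nrow(qual), per_track = per),
                   class = "motility_result")
  rk_log("motility_stats: %d/%d tracks qualify, MAD %.4g um, speed %.4g um/h",
         nrow(qual), nrow(per), res$mad_um, res$mean_speed_um_per_h)
  res
}

#' @export
print.motility_result <- function(x, ...) {
  cat(sprintf("<motility_result> %d tracks | MAD %.4g um | speed %.4g um/h\n",
              x$n_tracks, x$mad_um, x$mean_speed_um_per_h))
  invisible(x)
}

#' Track a time-lapse end to end
#'
#' Enhance, segment and link every frame, then compute motility statistics.
#'
#' @param frames list of 2D [image_stack()] frames.
#' @param config `motility` block of [default_config()] (or full config).
#' @return list: `tracks` (a [track_set()]), `stats` (a `motility_result`).
#' @export
track_timelapse <- function(frames, config = default_config()) {
  cfg <- if (!is.null(config$motility)) config$motility else config
  dets <- lapply(frames, function(fr) {
    enh <- enhance_frame(fr, block = cfg$clahe_block, bins = cfg$clahe_bins,
                         slope = cfg$clahe_slope)
    segment_cells(enh, min_area_px = cfg$min_area_px)$centroids
  })
  ts <- link_tracks(dets, max_disp_um = cfg$max_disp_um, dt_min = cfg$dt_min)
  n_frames <- length(frames)
  st <- motility_stats(ts, min_track_frames =
                         ceiling(cfg$min_track_fraction * n_frames))
  list(tracks = ts, stats = st)
}
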