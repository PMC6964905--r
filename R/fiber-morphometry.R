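# Collagen fiber-network morphometry: local-Otsu binarization, skeleton-graph
# fiber tracing with angle continuity, and the three network metrics (mean
# fiber length, persistence length, pore size).

#' Binarize a fiber image by windowed Otsu thresholding
#'
#' Gaussian prefilter followed by Otsu thresholds computed in overlapping
#' square windows (side `window_px`) and applied blockwise. Windows whose
#' dynamic range falls below a noise floor (a multiple of the slice MAD) are
#' treated as featureless and mapped to background, so blank regions never
#' produce spurious foreground. 3D stacks are processed slice-wise.
#'
#' @param img an [image_stack()] (or matrix/array).
#' @param window_px odd window side, >= 3 and no larger than the image.
#' @param prefilter_sigma Gaussian prefilter sd, voxels (0 disables).
#' @param noise_floor_mads windows with intensity range below
#'   `noise_floor_mads * mad(slice)` are classed as background.
#' @param spacing voxel spacing, used only when `img` is a bare array.
#' @return a [binary_mask()].
#' @export
binarize_fibers <- function(img, window_px = 65L, prefilter_sigma = 1,
                            noise_floor_mads = 2, spacing = NULL) {
  vol <- .as_vol(img, spacing)
  window_px <- as.integer(window_px)
  if (window_px < 3L || window_px %% 2L == 0L)
    stop("'window_px' must be odd and >= 3")
  d <- dim(vol$values)
  if (window_px > min(d[1], d[2]))
    stop("'window_px' larger than the image plane")
  rk_log_image("binarize_fibers", vol)
  half <- window_px %/% 2L
  stride <- max(1L, half)
  out <- array(FALSE, dim = d)
  for (k in seq_len(d[3])) {
    sl <- vol$values[, , k]
    if (prefilter_sigma > 0) sl <- EBImage::gblur(sl, sigma = prefilter_sigma)
    # background noise level from the MAD of first differences: unlike the
    # raw-intensity MAD this is insensitive to how much of the slice the
    # (smooth) fiber signal covers
    floor_k <- noise_floor_mads *
      stats::mad(as.vector(sl[-1, ] - sl[-nrow(sl), ])) / sqrt(2)
    if (diff(range(sl)) == 0) next # uniform slice: all background
    nby <- ceiling(d[1] / stride); nbx <- ceiling(d[2] / stride)
    for (by in seq_len(nby)) for (bx in seq_len(nbx)) {
      ys <- ((by - 1L) * stride + 1L):min(by * stride, d[1])
      xs <- ((bx - 1L) * stride + 1L):min(bx * stride, d[2])
      cy <- round(mean(ys)); cx <- round(mean(xs))
      wy <- max(1L, cy - half):min(d[1], cy + half)
      wx <- max(1L, cx - half):min(d[2], cx + half)
      win <- sl[wy, wx]
      if (diff(range(win)) < max(floor_k, 1e-12)) next # featureless window
      thr <- .otsu_threshold(as.vector(win))
      out[ys, xs, k] <- sl[ys, xs] > thr
    }
  }
  binary_mask(out, vol$spacing)
}

# ---- skeletonization (Zhang-Suen thinning, 2D) -----------------------------

.zs_neighbors <- function(m) {
  # returns list P2..P9 (N, NE, E, SE, S, SW, W, NW) as 0/1 matrices
  sh <- function(dy, dx) {
    d <- dim(m)
    out <- matrix(0, d[1], d[2])
    ys <- max(1, 1 + dy):min(d[1], d[1] + dy)
    xs <- max(1, 1 + dx):min(d[2], d[2] + dx)
    out[ys, xs] <- m[ys - dy, xs - dx]
    out
  }
  list(P2 = sh(1, 0), P3 = sh(1, -1), P4 = sh(0, -1), P5 = sh(-1, -1),
       P6 = sh(-1, 0), P7 = sh(-1, 1), P8 = sh(0, 1), P9 = sh(1, 1))
}

#' Skeletonize a 2D binary mask
#'
#' Zhang-Suen thinning to a 1-pixel-wide, 8-connected skeleton.
#'
#' @param mask logical matrix (or `binary_mask` with z = 1).
#' @return logical matrix of skeleton pixels.
#' @export
skeletonize <- function(mask) {
  vol <- .as_vol(mask)
  if (dim(vol$values)[3] != 1L) stop("skeletonize expects a 2D mask")
  m <- vol$values[, , 1] * 1
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      p <- .zs_neighbors(m)
      seq8 <- with(p, list(P2, P3, P4, P5, P6, P7, P8, P9, P2))
      B <- Reduce(`+`, seq8[1:8])
      A <- matrix(0, nrow(m), ncol(m))
      for (i in 1:8) A <- A + (seq8[[i]] == 0) * (seq8[[i + 1]] == 1)
      cond <- m == 1 & B >= 2 & B <= 6 & A == 1
      if (sub == 1L)
        cond <- cond & (p$P2 * p$P4 * p$P6 == 0) & (p$P4 * p$P6 * p$P8 == 0)
      else
        cond <- cond & (p$P2 * p$P4 * p$P8 == 0) & (p$P2 * p$P6 * p$P8 == 0)
      if (any(cond)) { m[cond] <- 0; changed <- TRUE }
    }
    if (!changed) break
  }
  m == 1
}

# ---- fiber tracing ---------------------------------------------------------

#' Construct a fiber network from polylines
#'
#' Builds the network container directly from polyline geometry (columns
#' `x`, `y` in micrometres), e.g. from the synthetic generator's ground
#' truth, bypassing image tracing.
#'
#' @param polylines list of numeric matrices with >= 2 rows.
#' @param spacing voxel pitch the geometry refers to (bookkeeping only).
#' @return a `fiber_network`.
#' @export
fiber_network_from_polylines <- function(polylines, spacing = c(1, 1, 1)) {
  polylines <- lapply(polylines, function(m) {
    m <- as.matrix(m)[, 1:2, drop = FALSE]
    colnames(m) <- c("x", "y")
    m
  })
  if (any(vapply(polylines, nrow, integer(1)) < 2L))
    stop("every fiber needs >= 2 nodes")
  structure(list(fibers = polylines, pixels = NULL, skeleton = NULL,
                 spacing = spacing,
                 discarded_pixels = NULL),
            class = "fiber_network")
}

#' @export
print.fiber_network <- function(x, ...) {
  n <- length(x$fibers)
  cat(sprintf("<fiber_network> %d fibers, mean length %.3g um\n", n,
              if (n) mean(vapply(x$fibers, .polyline_length, numeric(1))) else NA))
  invisible(x)
}

.polyline_length <- function(m) {
  if (nrow(m) < 2L) return(0)
  sum(sqrt(rowSums(diff(m)^2)))
}

# unit direction between two points
.unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) c(1, 0) else v / n
}

# tangent at the end of a polyline (pointing outward from the interior),
# averaged over up to k terminal segments
.end_tangent <- function(m, at_end, k = 4L) {
  n <- nrow(m)
  if (at_end) idx <- max(1L, n - k):n else idx <- seq_len(min(n, k + 1L))
  seg <- m[idx, , drop = FALSE]
  v <- seg[nrow(seg), ] - seg[1, ]
  if (!at_end) v <- -v # outward at the start end
  .unit(v)
}

#' Trace fibers from a binarized image
#'
#' Skeletonizes the mask, decomposes the skeleton's pixel-adjacency graph
#' into branches between endpoints/junctions, and assembles branches into
#' fibers by angle continuity: at a junction the fiber continues along the
#' unused branch with the smallest turning angle, provided it does not
#' exceed `max_turn_deg`; otherwise the fiber terminates. Junction pixels
#' may be shared between fibers; branch pixels belong to exactly one fiber.
#' Fibers shorter than `min_fiber_um` are discarded.
#'
#' @param mask a [binary_mask()] (2D; z = 1).
#' @param min_fiber_um minimum fiber contour length to keep, um.
#' @param max_turn_deg maximum turning angle for continuing through a
#'   junction, degrees.
#' @param junction_merge_px junction-to-junction bridges up to this many
#'   pixels are absorbed into a single junction node (oblique crossings
#'   rasterize into two nearby clusters; consolidation restores the true
#'   crossing topology).
#' @return a `fiber_network`; empty mask gives an empty network.
#' @export
trace_fibers <- function(mask, min_fiber_um = 2, max_turn_deg = 40,
                         junction_merge_px = 4L) {
  stopifnot(inherits(mask, "binary_mask") || is.matrix(mask) || is.array(mask))
  vol <- .as_vol(mask)
  if (dim(vol$values)[3] != 1L)
    stop("trace_fibers expects a 2D mask; project 3D stacks first")
  sp <- vol$spacing
  skel <- skeletonize(vol$values[, , 1])
  empty <- structure(list(fibers = list(), pixels = list(), skeleton = skel,
                          spacing = sp, junction_pixels = integer(0),
                          discarded_pixels = integer(0)),
                     class = "fiber_network")
  if (!any(skel)) return(empty)

  d <- dim(skel)
  idx <- which(skel)
  pos <- arrayInd(idx, d) # rows: (y, x)
  id_of <- array(0L, dim = d); id_of[idx] <- seq_along(idx)
  off <- expand.grid(dy = -1:1, dx = -1:1)
  off <- off[!(off$dy == 0 & off$dx == 0), ]
  nb <- vector("list", length(idx))
  deg <- integer(length(idx))
  for (i in seq_along(idx)) {
    yy <- pos[i, 1] + off$dy; xx <- pos[i, 2] + off$dx
    ok <- yy >= 1 & yy <= d[1] & xx >= 1 & xx <= d[2]
    ids <- id_of[cbind(yy[ok], xx[ok])]
    nb[[i]] <- ids[ids > 0L]
    deg[i] <- length(nb[[i]])
  }
  is_junc <- deg >= 3L

  # junction nodes: components of adjacent junction pixels
  junc_node <- integer(length(idx)) # 0 = not a junction pixel
  if (any(is_junc)) {
    jidx <- which(is_junc)
    comp <- integer(length(jidx)); cur <- 0L
    lookup <- integer(length(idx)); lookup[jidx] <- seq_along(jidx)
    for (s in seq_along(jidx)) {
      if (comp[s] > 0L) next
      cur <- cur + 1L
      queue <- s
      comp[s] <- cur
      while (length(queue)) {
        v <- queue[[1]]; queue <- queue[-1]
        for (w in nb[[jidx[v]]]) {
          if (is_junc[w] && comp[lookup[w]] == 0L) {
            comp[lookup[w]] <- cur
            queue <- c(queue, lookup[w])
          }
        }
      }
    }
    junc_node[jidx] <- comp
  }

  # branch extraction: walk chains of non-junction pixels
  visited <- logical(length(idx))
  branches <- list() # each: list(px = pixel ids, j1, j2 = junction node ids or 0)
  walk <- function(start, from_junction) {
    chain <- start
    visited[start] <<- TRUE
    prev <- 0L
    cur <- start
    repeat {
      nxt <- setdiff(nb[[cur]][!is_junc[nb[[cur]]] & !visited[nb[[cur]]]], prev)
      if (!length(nxt)) break
      nxt <- nxt[1]
      visited[nxt] <<- TRUE
      chain <- c(chain, nxt)
      prev <- cur; cur <- nxt
    }
    chain
  }
  nonj <- which(!is_junc)
  # starts: chain pixels adjacent to a junction or of chain-degree <= 1
  for (i in nonj) {
    if (visited[i]) next
    chain_nb <- nb[[i]][!is_junc[nb[[i]]]]
    if (length(chain_nb) <= 1L || any(is_junc[nb[[i]]])) {
      chain <- walk(i, 0L)
      branches[[length(branches) + 1L]] <- chain
    }
  }
  for (i in nonj) { # isolated cycles: start anywhere
    if (!visited[i]) branches[[length(branches) + 1L]] <- walk(i, 0L)
  }

  # attach junction nodes at branch ends; a single-pixel chain between two
  # junction clusters attaches one end to each
  br <- lapply(branches, function(chain) {
    adj_nodes <- function(e) unique(junc_node[nb[[e]][is_junc[nb[[e]]]]])
    if (length(chain) == 1L) {
      js <- adj_nodes(chain[1])
      jn <- c(if (length(js) >= 1L) js[1] else 0L,
              if (length(js) >= 2L) js[2] else 0L)
    } else {
      jn <- c({ js <- adj_nodes(chain[1]); if (length(js)) js[1] else 0L },
              { js <- adj_nodes(chain[length(chain)])
                if (length(js)) js[1] else 0L })
    }
    list(px = chain, j1 = jn[1], j2 = jn[2])
  })

  # junction consolidation: an oblique crossing rasterizes into two junction
  # clusters connected by a pixel-scale bridge; absorbing such bridges gives
  # one junction with clean arms, so angle continuity sees the true crossing
  n_nodes <- max(junc_node, 0L)
  junction_extra_px <- integer(0) # bridge pixels absorbed into junctions
  extra_node <- integer(0)        # merged node id of each absorbed pixel
  if (n_nodes > 0L && length(br)) {
    parent <- seq_len(n_nodes)
    find_root <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    absorbed <- logical(length(br))
    abs_j1 <- integer(length(br))
    for (bi in seq_along(br)) {
      b <- br[[bi]]
      if (b$j1 > 0L && b$j2 > 0L && length(b$px) <= junction_merge_px) {
        r1 <- find_root(b$j1); r2 <- find_root(b$j2)
        if (r2 != r1) parent[r2] <- r1
        absorbed[bi] <- TRUE
        abs_j1[bi] <- b$j1
      }
    }
    roots <- vapply(seq_len(n_nodes), find_root, integer(1))
    remap <- match(roots, unique(roots))
    for (bi in which(absorbed)) {
      junction_extra_px <- c(junction_extra_px, br[[bi]]$px)
      extra_node <- c(extra_node,
                      rep(remap[roots[abs_j1[bi]]], length(br[[bi]]$px)))
    }
    junc_node[junc_node > 0L] <- remap[roots[junc_node[junc_node > 0L]]]
    br <- lapply(br[!absorbed], function(b) {
      if (b$j1 > 0L) b$j1 <- remap[roots[b$j1]]
      if (b$j2 > 0L) b$j2 <- remap[roots[b$j2]]
      b
    })
    n_nodes <- max(junc_node, 0L)
  }

  jcoord <- matrix(0, max(n_nodes, 1L), 2L)
  if (n_nodes > 0L) for (j in seq_len(n_nodes)) {
    sel <- c(which(junc_node == j), junction_extra_px[extra_node == j])
    jcoord[j, ] <- c(mean(pos[sel, 2]), mean(pos[sel, 1])) # (x, y) px
  }
  px_xy <- cbind(pos[, 2], pos[, 1]) # (x, y) pixel coords

  to_um <- function(xy) cbind(x = (xy[, 1] - 1) * sp[1], y = (xy[, 2] - 1) * sp[2])

  # branch polyline in pixel coords, junction coords appended at attached ends
  branch_xy <- function(b, forward = TRUE) {
    xy <- px_xy[b$px, , drop = FALSE]
    if (b$j1 > 0L) xy <- rbind(jcoord[b$j1, ], xy)
    if (b$j2 > 0L) xy <- rbind(xy, jcoord[b$j2, ])
    if (!forward) xy <- xy[rev(seq_len(nrow(xy))), , drop = FALSE]
    xy
  }
  # junction node at the leading end of the branch in the given direction
  lead_junc <- function(b, forward) if (forward) b$j2 else b$j1

  used <- logical(length(br))
  # incidence: junction node -> branch indices
  inc <- vector("list", max(n_nodes, 1L))
  for (bi in seq_along(br)) {
    for (j in unique(c(br[[bi]]$j1, br[[bi]]$j2))) if (j > 0L)
      inc[[j]] <- c(inc[[j]], bi)
  }

  max_turn <- max_turn_deg * pi / 180
  fibers <- list(); fiber_px <- list()
  order_b <- order(-vapply(br, function(b) length(b$px), integer(1)))
  for (bi in order_b) {
    if (used[bi]) next
    used[bi] <- TRUE
    xy <- branch_xy(br[[bi]], TRUE)
    pxs <- br[[bi]]$px
    for (enddir in c(TRUE, FALSE)) { # extend forward, then backward
      if (!enddir) { xy <- xy[rev(seq_len(nrow(xy))), , drop = FALSE]; }
      cur_b <- bi; forward <- enddir
      repeat {
        jn <- lead_junc(br[[cur_b]], forward)
        if (jn == 0L) break
        cand <- inc[[jn]][!used[inc[[jn]]]]
        if (!length(cand)) break
        arr <- .end_tangent(xy, at_end = TRUE)
        best <- 0L; best_ang <- Inf; best_fwd <- TRUE
        for (ci in cand) {
          for (fw in c(TRUE, FALSE)) {
            if ((fw && br[[ci]]$j1 != jn) || (!fw && br[[ci]]$j2 != jn)) next
            cxy <- branch_xy(br[[ci]], fw)
            dep <- -.end_tangent(cxy, at_end = FALSE) # direction into branch
            ang <- acos(pmin(1, pmax(-1, sum(arr * dep))))
            if (ang < best_ang) { best_ang <- ang; best <- ci; best_fwd <- fw }
          }
        }
        if (best == 0L || best_ang > max_turn) break
        used[best] <- TRUE
        cxy <- branch_xy(br[[best]], best_fwd)
        xy <- rbind(xy, cxy[-1, , drop = FALSE])
        pxs <- c(pxs, br[[best]]$px)
        cur_b <- best; forward <- best_fwd
      }
    }
    fibers[[length(fibers) + 1L]] <- to_um(xy)
    fiber_px[[length(fiber_px) + 1L]] <- idx[pxs]
  }

  lens <- vapply(fibers, .polyline_length, numeric(1))
  keep <- lens >= min_fiber_um
  discarded <- unlist(fiber_px[!keep], use.names = FALSE)
  net <- structure(list(fibers = fibers[keep], pixels = fiber_px[keep],
                        skeleton = skel, spacing = sp,
                        junction_pixels = c(idx[is_junc],
                                            idx[junction_extra_px]),
                        discarded_pixels = if (is.null(discarded)) integer(0) else discarded),
                   class = "fiber_network")
  rk_log("trace_fibers: %d skeleton px -> %d fibers (%d discarded < %.3g um)",
         sum(skel), sum(keep), sum(!keep), min_fiber_um)
  net
}

#' Mean fiber length
#'
#' @param net a `fiber_network` with at least one fiber.
#' @return mean polyline arc length over fibers, um.
#' @export
fiber_length_stats <- function(net) {
  stopifnot(inherits(net, "fiber_network"))
  if (!length(net$fibers)) stop("empty fiber network")
  mean(vapply(net$fibers, .polyline_length, numeric(1)))
}

#' Persistence length from pooled tangent correlations
#'
#' Pools tangent-angle correlations `<cos(theta(s') - theta(s))>` over all
#' fibers as a function of arc separation, and fits the 2D worm-like-chain
#' decay `exp(-s / (2 Lp))` by least squares on the log-correlation, using
#' separations up to half the mean fiber length. For fiber geometry traced
#' from 3D images the decay convention is `exp(-s / Lp)` (`dims = 3`).
#'
#' @param net a `fiber_network`; needs >= 10 fibers with >= 5 nodes each.
#' @param dims 2 (default) or 3; selects the decay convention.
#' @param n_bins number of arc-separation bins for the pooled correlation.
#' @return persistence length in um; `Inf` for non-decaying correlations
#'   (perfectly straight fibers).
#' @export
persistence_length <- function(net, dims = 2, n_bins = 20L) {
  stopifnot(inherits(net, "fiber_network"))
  ok <- vapply(net$fibers, function(m) nrow(m) >= 5L, logical(1))
  if (sum(ok) < 10L)
    stop("persistence_length needs >= 10 fibers with >= 5 nodes each")
  fibs <- net$fibers[ok]
  smax <- 0.5 * mean(vapply(fibs, .polyline_length, numeric(1)))
  ss <- numeric(0); cc <- numeric(0)
  for (m in fibs) {
    seg <- diff(m)
    th <- atan2(seg[, 2], seg[, 1])
    sl <- sqrt(rowSums(seg^2))
    smid <- cumsum(sl) - sl / 2
    n <- length(th)
    pr <- which(outer(smid, smid, FUN = function(a, b) b - a) > 0, arr.ind = TRUE)
    if (!nrow(pr)) next
    dsep <- smid[pr[, 2]] - smid[pr[, 1]]
    sel <- dsep <= smax
    ss <- c(ss, dsep[sel])
    cc <- c(cc, cos(th[pr[sel, 2]] - th[pr[sel, 1]]))
  }
  if (!length(ss)) stop("insufficient tangent sampling")
  bins <- cut(ss, breaks = seq(0, smax, length.out = n_bins + 1L),
              include.lowest = TRUE)
  cbar <- tapply(cc, bins, mean)
  smid_b <- tapply(ss, bins, mean)
  keep <- !is.na(cbar) & cbar > 0.01
  if (all(cbar[keep] > 0.999)) return(Inf)
  if (sum(keep) < 2L) return(Inf)
  fit <- stats::lm(log(cbar[keep]) ~ 0 + smid_b[keep])
  slope <- unname(stats::coef(fit)[1])
  if (slope >= 0) return(Inf)
  if (dims == 2) -1 / (2 * slope) else -1 / slope
}

#' Pore size from the background distance field
#'
#' Euclidean distance transform of the background (fibers as obstacles,
#' anisotropic spacing honoured); pore radii are the distance values at the
#' regional maxima of the background distance field, and the pore size is
#' twice their median -- the "largest inscribed sphere" family of pore
#' measures.
#'
#' @param mask a [binary_mask()] of the fiber phase (must contain both
#'   foreground and background).
#' @param spacing used only when `mask` is a bare array.
#' @return pore size in um.
#' @export
pore_size <- function(mask, spacing = NULL) {
  vol <- .as_vol(mask, spacing)
  m <- vol$values
  storage.mode(m) <- "logical"
  if (all(m) || !any(m)) stop("mask must contain both fiber and background")
  d <- distance_transform(m, vol$spacing)
  maxima <- .regional_maxima(d, mask = !m)
  radii <- d[maxima]
  if (!length(radii)) stop("no pore maxima found")
  2 * stats::median(radii)
}

#' Full fiber morphometry of a fiber image
#'
#' Binarize, trace and measure in one call. 3D stacks are binarized
#' slice-wise and traced on the maximum-intensity projection of the mask.
#'
#' @param img an [image_stack()].
#' @param config `fiber` block of [default_config()] (or a full config list).
#' @return list of class `morphometry_result`: `mean_fiber_length`,
#'   `persistence_length`, `pore_size` (um), `n_fibers`, and the traced
#'   `network`.
#' @export
fiber_morphometry <- function(img, config = default_config()) {
  cfg <- if (!is.null(config$fiber)) config$fiber else config
  vol <- .as_vol(img)
  mask <- binarize_fibers(img, window_px = cfg$window_px,
                          prefilter_sigma = cfg$prefilter_sigma,
                          noise_floor_mads = cfg$noise_floor_mads)
  d <- dim(mask$values)
  mask2d <- if (d[3] > 1L)
    binary_mask(apply(mask$values, c(1, 2), any), mask$spacing)
  else mask
  net <- trace_fibers(mask2d, min_fiber_um = cfg$min_fiber_um,
                      max_turn_deg = cfg$max_turn_deg)
  res <- list(
    mean_fiber_length = if (length(net$fibers)) fiber_length_stats(net) else NA_real_,
    persistence_length = tryCatch(persistence_length(net),
                                  error = function(e) NA_real_),
    pore_size = tryCatch(pore_size(mask), error = function(e) NA_real_),
    n_fibers = length(net$fibers),
    network = net
  )
  rk_log("fiber_morphometry: n=%d, mean length %.3g um, Lp %.3g um, pore %.3g um",
         res$n_fibers, res$mean_fiber_length, res$persistence_length,
         res$pore_size)
  structure(res, class = "morphometry_result")
}

#' @export
print.morphometry_result <- function(x, ...) {
  cat(sprintf(paste0("<morphometry_result> %d fibers | mean length %.4g um | ",
                     "persistence %.4g um | pore size %.4g um\n"),
              x$n_fibers, x$mean_fiber_length, x$persistence_length,
              x$pore_size))
  invisible(x)
}
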