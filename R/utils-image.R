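# Shared low-level image primitives.
#
# Anisotropic exact Euclidean distance transform, connected-component
# labeling with the connectivity conventions used throughout (8-connected in
# 2D, 26-connected in 3D), physically calibrated binary morphology, CLAHE,
# and scalar threshold selectors. EBImage supplies 2D grayscale morphology
# and convolution; the primitives here exist where physical anisotropy or
# 3D connectivity semantics are required.

.INF <- 1e30

# Shift a 3D array by (dy, dx, dz), filling vacated voxels with `fill`.
.shift3 <- function(a, dy, dx, dz, fill = 0) {
  d <- dim(a)
  out <- array(fill, dim = d)
  ys <- max(1, 1 + dy):min(d[1], d[1] + dy)
  xs <- max(1, 1 + dx):min(d[2], d[2] + dx)
  zs <- max(1, 1 + dz):min(d[3], d[3] + dz)
  if (length(ys) < 1 || length(xs) < 1 || length(zs) < 1) return(out)
  out[ys, xs, zs] <- a[ys - dy, xs - dx, zs - dz]
  out
}

# Neighborhood offsets: full (8 in-plane / 26 in 3D) or face-adjacent.
.neighbor_offsets <- function(three_d, faces_only = FALSE) {
  rng <- -1:1
  zs <- if (three_d) rng else 0L
  off <- expand.grid(dy = rng, dx = rng, dz = zs)
  off <- off[!(off$dy == 0 & off$dx == 0 & off$dz == 0), ]
  if (faces_only) off <- off[abs(off$dy) + abs(off$dx) + abs(off$dz) == 1, ]
  off
}

# 1D squared-distance transform (lower envelope of parabolas), pitch w.
.dt1 <- function(f, w) {
  n <- length(f)
  if (n == 1L) return(f)
  w2 <- w * w
  v <- integer(n); z <- numeric(n + 1L)
  k <- 1L; v[1L] <- 1L; z[1L] <- -.INF; z[2L] <- .INF
  for (q in 2:n) {
    repeat {
      p <- v[k]
      s <- ((f[q] + w2 * (q - 1)^2) - (f[p] + w2 * (p - 1)^2)) /
        (2 * w * (q - p))
      if (s <= z[k]) { k <- k - 1L; if (k < 1L) { k <- 0L; break } } else break
    }
    k <- k + 1L
    v[k] <- q
    z[k] <- if (k == 1L) -.INF else s
    z[k + 1L] <- .INF
  }
  d <- numeric(n); k <- 1L
  for (q in 1:n) {
    while (z[k + 1L] < (q - 1) * w) k <- k + 1L
    p <- v[k]
    d[q] <- w2 * (q - p)^2 + f[p]
  }
  d
}

#' Anisotropic Euclidean distance transform
#'
#' Exact distance, in micrometres, from every voxel to the nearest `TRUE`
#' voxel of `target`, honouring anisotropic voxel spacing (separable
#' lower-envelope algorithm, one pass per axis).
#'
#' @param target logical matrix or 3D array (or [binary_mask()]).
#' @param spacing voxel pitch `(dx, dy, dz)` in um/voxel; ignored if `target`
#'   is a `binary_mask` carrying its own spacing.
#' @return numeric array of distances (um), same shape; `Inf`-like large
#'   values where `target` has no `TRUE` voxel at all.
#' @export
distance_transform <- function(target, spacing = c(1, 1, 1)) {
  vol <- .as_vol(target, spacing)
  m <- vol$values
  storage.mode(m) <- "logical"
  d <- dim(m)
  sp <- vol$spacing
  g <- array(ifelse(m, 0, .INF), dim = d)
  # axis order: y (rows, dy), x (cols, dx), z (dz)
  if (d[1] > 1L) for (k in seq_len(d[3])) for (j in seq_len(d[2]))
    g[, j, k] <- .dt1(g[, j, k], sp[2])
  if (d[2] > 1L) for (k in seq_len(d[3])) for (i in seq_len(d[1]))
    g[i, , k] <- .dt1(g[i, , k], sp[1])
  if (d[3] > 1L) for (j in seq_len(d[2])) for (i in seq_len(d[1]))
    g[i, j, ] <- .dt1(g[i, j, ], sp[3])
  sqrt(g)
}

# Connected-component labeling by iterative max-propagation.
# connectivity: 8-connected in-plane; 26-connected when the array has z-depth.
.label_components <- function(mask) {
  d <- dim(mask)
  three_d <- d[3] > 1L
  off <- .neighbor_offsets(three_d)
  # seed with the linear voxel index; propagate the component max to a fixed
  # point (iterations bounded by the geodesic diameter of the largest blob)
  lab <- array(0, dim = d)
  lab[mask] <- which(mask)
  repeat {
    nxt <- lab
    for (r in seq_len(nrow(off))) {
      sh <- .shift3(lab, off$dy[r], off$dx[r], off$dz[r], fill = 0)
      nxt <- pmax(nxt, sh)
    }
    nxt[!mask] <- 0
    if (identical(nxt, lab)) break
    lab <- nxt
  }
  u <- sort(unique(lab[lab > 0]))
  if (length(u)) lab[] <- match(lab, c(0, u)) - 1L
  storage.mode(lab) <- "integer"
  lab
}

# Grayscale reconstruction by dilation of `marker` under `ceiling_`,
# iterated to a fixed point (8/26-connectivity).
.reconstruct_dilate <- function(marker, ceiling_) {
  off <- .neighbor_offsets(dim(marker)[3] > 1L)
  R <- pmin(marker, ceiling_)
  repeat {
    nxt <- R
    for (r in seq_len(nrow(off)))
      nxt <- pmax(nxt, .shift3(R, off$dy[r], off$dx[r], off$dz[r],
                               fill = -.INF))
    nxt <- pmin(nxt, ceiling_)
    if (identical(nxt, R)) break
    R <- nxt
  }
  R
}

# Regional maxima (plateau-correct): a connected plateau is a maximum only
# if no neighbour anywhere on its boundary is higher. Implemented with the
# eps-reconstruction identity: x - reconstruct(x - eps, x) > 0 exactly on
# regional maxima, which correctly rejects ridge plateaus hanging off
# higher structure (a per-voxel >= test would not).
.regional_maxima <- function(x, mask = NULL, positive = TRUE, eps = 1e-7) {
  if (!is.null(mask)) x[!mask] <- -.INF
  R <- .reconstruct_dilate(x - eps, x)
  res <- (x - R) > eps / 2
  if (positive) res <- res & (x > 0)
  if (!is.null(mask)) res <- res & mask
  res
}

# ---- physically calibrated binary morphology -------------------------------

# Dilate / erode / close with a Euclidean ball of physical radius r_um.
.dilate_um <- function(mask, r_um, spacing) {
  distance_transform(mask, spacing) <= r_um + 1e-9
}

.erode_um <- function(mask, r_um, spacing) {
  !(distance_transform(!mask, spacing) <= r_um + 1e-9)
}

.close_um <- function(mask, r_um, spacing) {
  .erode_um(.dilate_um(mask, r_um, spacing), r_um, spacing)
}

# Binary median filter with a voxel-radius ball (majority vote).
.binary_median <- function(mask, r_vox) {
  d <- dim(mask)
  rng <- -r_vox:r_vox
  zs <- if (d[3] > 1L) rng else 0L
  off <- expand.grid(dy = rng, dx = rng, dz = zs)
  off <- off[off$dy^2 + off$dx^2 + off$dz^2 <= r_vox^2 + 1e-9, ]
  acc <- array(0, dim = d)
  m <- mask * 1
  for (r in seq_len(nrow(off)))
    acc <- acc + .shift3(m, off$dy[r], off$dx[r], off$dz[r], fill = 0)
  acc > nrow(off) / 2
}

# Median filter with a 6/4-neighbor ball of radius 1 on a grayscale volume.
# Border neighbours replicate the centre voxel. The median of the (up to 7)
# values is taken with a compare-exchange sorting network, fully vectorized.
.median_ball1 <- function(v) {
  d <- dim(v)
  off <- .neighbor_offsets(d[3] > 1L, faces_only = TRUE)
  ctr <- as.vector(v)
  s <- vector("list", nrow(off) + 1L)
  s[[1L]] <- ctr
  for (r in seq_len(nrow(off))) {
    sh <- as.vector(.shift3(v, off$dy[r], off$dx[r], off$dz[r], fill = NA))
    sh[is.na(sh)] <- ctr[is.na(sh)]
    s[[r + 1L]] <- sh
  }
  if (length(s) == 5L) { # 2D: median of 5 (full 5-sorter, take the middle)
    net <- list(c(1, 2), c(4, 5), c(3, 5), c(3, 4), c(1, 4), c(1, 3),
                c(2, 5), c(2, 4), c(2, 3))
    mid <- 3L
  } else {               # 3D: median of 7 (full 7-sorter, take the middle)
    net <- list(c(2, 3), c(4, 5), c(6, 7), c(1, 3), c(4, 6), c(5, 7),
                c(1, 2), c(5, 6), c(3, 7), c(1, 5), c(2, 6), c(1, 4),
                c(3, 6), c(2, 4), c(3, 5), c(3, 4))
    mid <- 4L
  }
  for (ce in net) {
    lo <- pmin(s[[ce[1]]], s[[ce[2]]])
    s[[ce[2]]] <- pmax(s[[ce[1]]], s[[ce[2]]])
    s[[ce[1]]] <- lo
  }
  array(s[[mid]], dim = d)
}

# ---- scalar threshold selectors -------------------------------------------

# Iterative intermeans (isodata) threshold on a numeric vector.
.intermeans_threshold <- function(v, max_iter = 200L) {
  v <- v[is.finite(v)]
  if (length(unique(v)) < 2L) stop("intermeans threshold needs >= 2 levels")
  t0 <- mean(range(v))
  for (i in seq_len(max_iter)) {
    lo <- v[v <= t0]; hi <- v[v > t0]
    if (!length(lo) || !length(hi)) break
    t1 <- (mean(lo) + mean(hi)) / 2
    if (abs(t1 - t0) < 1e-10 * max(1, abs(t0))) { t0 <- t1; break }
    t0 <- t1
  }
  t0
}

# Otsu threshold from a histogram of v with `bins` bins over its range.
# Returns the bin-edge threshold maximizing between-class variance.
.otsu_threshold <- function(v, bins = 256L) {
  v <- v[is.finite(v)]
  r <- range(v)
  if (diff(r) == 0) stop("otsu threshold needs a non-constant input")
  br <- seq(r[1], r[2], length.out = bins + 1L)
  h <- tabulate(pmin(bins, pmax(1L, findInterval(v, br, rightmost.closed = TRUE))),
                nbins = bins)
  p <- h / sum(h)
  mids <- (br[-1] + br[-length(br)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[bins]
  sb <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  sb[!is.finite(sb)] <- -Inf
  k <- which.max(sb[-bins])
  br[k + 1L] # edge between class-0 bins [1..k] and the rest
}

# ---- CLAHE -----------------------------------------------------------------

# Contrast-limited adaptive histogram equalization on a 2D matrix in [0,1].
# Tile histograms are clipped at slope * (uniform level) with one-pass
# redistribution; per-pixel mappings bilinearly interpolated between tile
# centers.
.clahe <- function(m, block = 19L, bins = 256L, slope = 3) {
  stopifnot(is.matrix(m))
  if (diff(range(m)) == 0) return(m)
  h <- nrow(m); w <- ncol(m)
  nty <- max(1L, ceiling(h / block)); ntx <- max(1L, ceiling(w / block))
  # tile bounds (last tiles absorb the remainder)
  yb <- floor(seq(0, h, length.out = nty + 1L))
  xb <- floor(seq(0, w, length.out = ntx + 1L))
  bin_of <- floor(m * bins) + 1L
  bin_of[bin_of > bins] <- bins
  bin_of[bin_of < 1L] <- 1L
  maps <- array(0, dim = c(nty, ntx, bins))
  cy <- numeric(nty); cx <- numeric(ntx)
  for (ty in seq_len(nty)) for (tx in seq_len(ntx)) {
    ys <- (yb[ty] + 1L):yb[ty + 1L]; xs <- (xb[tx] + 1L):xb[tx + 1L]
    cy[ty] <- mean(ys); cx[tx] <- mean(xs)
    hist_t <- tabulate(bin_of[ys, xs], nbins = bins)
    n <- sum(hist_t)
    clip <- max(1, slope * n / bins)
    excess <- sum(pmax(hist_t - clip, 0))
    hist_t <- pmin(hist_t, clip) + excess / bins
    cdf <- cumsum(hist_t) / sum(hist_t)
    maps[ty, tx, ] <- cdf
  }
  # bilinear interpolation between tile-center mappings
  iy <- findInterval(seq_len(h), cy, all.inside = TRUE)
  ix <- findInterval(seq_len(w), cx, all.inside = TRUE)
  wy <- if (nty > 1L) pmin(1, pmax(0, (seq_len(h) - cy[iy]) / (cy[iy + 1L] - cy[iy]))) else rep(0, h)
  wx <- if (ntx > 1L) pmin(1, pmax(0, (seq_len(w) - cx[ix]) / (cx[ix + 1L] - cx[ix]))) else rep(0, w)
  IY <- matrix(iy, h, w); IX <- matrix(ix, h, w, byrow = TRUE)
  WY <- matrix(wy, h, w); WX <- matrix(wx, h, w, byrow = TRUE)
  B <- bin_of
  up <- function(dy, dx) {
    ti <- pmin(IY + dy, nty); tj <- pmin(IX + dx, ntx)
    maps[cbind(as.vector(ti), as.vector(tj), as.vector(B))]
  }
  v00 <- up(0L, 0L); v10 <- up(1L, 0L); v01 <- up(0L, 1L); v11 <- up(1L, 1L)
  out <- (1 - WY) * (1 - WX) * v00 + WY * (1 - WX) * v10 +
    (1 - WY) * WX * v01 + WY * WX * v11
  matrix(out, h, w)
}

# Normalize a matrix/array to [0,1]; constant input maps to 0.
.norm01 <- function(v) {
  r <- range(v)
  if (diff(r) == 0) return(v * 0)
  (v - r[1]) / (r[2] - r[1])
}

# Linear contrast stretch saturating `sat_pct` percent of pixels per tail.
.stretch <- function(v, sat_pct) {
  q <- stats::quantile(v, c(sat_pct / 100, 1 - sat_pct / 100), names = FALSE)
  if (q[2] <= q[1]) return(.norm01(v))
  out <- (v - q[1]) / (q[2] - q[1])
  out[out < 0] <- 0; out[out > 1] <- 1
  out
}

# Laplacian-of-Gaussian kernel (odd side, ~3.5 sigma half-width), sign
# flipped so bright blobs give positive responses.
.log_kernel <- function(sigma = c(5, 5)) {
  sx <- sigma[1]; sy <- sigma[2]
  hx <- ceiling(3.5 * sx); hy <- ceiling(3.5 * sy)
  x <- matrix(-hx:hx, 2 * hy + 1, 2 * hx + 1, byrow = TRUE)
  y <- matrix(-hy:hy, 2 * hy + 1, 2 * hx + 1)
  g <- exp(-(x^2 / (2 * sx^2) + y^2 / (2 * sy^2)))
  lg <- g * (x^2 / sx^4 + y^2 / sy^4 - 1 / sx^2 - 1 / sy^2)
  k <- -(lg - mean(lg)) # zero-sum, blob-positive
  k / sum(abs(k))
}

# 2D Hann window, n x n.
.hann2d <- function(n) {
  w <- 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1)))
  outer(w, w)
}
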