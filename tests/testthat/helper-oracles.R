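# Independent oracles and small scene builders used across the test files.

# Sinusoidal stripe patch: stripes run along direction `phi` (radians),
# intensity varies perpendicular to them.
make_stripes <- function(n = 100, phi = 0, period = 8) {
  xg <- matrix(0:(n - 1), n, n, byrow = TRUE)
  yg <- matrix(0:(n - 1), n, n)
  sin(2 * pi * (xg * cos(phi) + yg * sin(phi)) / period)^2
}

# Brute-force anisotropic EDT on small grids.
brute_edt <- function(target, spacing) {
  d <- dim(target)
  tg <- which(target, arr.ind = TRUE)
  out <- array(Inf, dim = d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3]))
    out[i, j, k] <- min(sqrt(((tg[, 2] - j) * spacing[1])^2 +
                               ((tg[, 1] - i) * spacing[2])^2 +
                               ((tg[, 3] - k) * spacing[3])^2))
  out
}

# Exhaustive Tsai oracle: for every candidate cut the class fraction is
# fixed by the cumulative histogram and (z0, z1) are solved to preserve the
# first two moments exactly; the returned cut minimizes the third-moment
# mismatch. Agrees with the closed-form solution up to the one-level
# quantization of p0.
brute_tsai_threshold <- function(v) {
  lv <- sort(unique(v))
  m1 <- mean(v); m2 <- mean(v^2); m3 <- mean(v^3)
  best <- NULL; bestmis <- Inf
  for (t in lv[-length(lv)]) {
    p <- mean(v <= t); q <- 1 - p
    if (p == 0 || q == 0) next
    disc <- m1^2 * q^2 - q * (m1^2 - p * m2)
    if (disc < 0) next
    z1 <- (m1 * q + sqrt(disc)) / q
    z0 <- (m1 - q * z1) / p
    mis <- abs(p * z0^3 + q * z1^3 - m3)
    if (mis < bestmis) { bestmis <- mis; best <- t }
  }
  best
}

# Shannon entropy of a [0,1] image, 64 bins.
image_entropy <- function(m, bins = 64) {
  h <- tabulate(pmin(bins, floor(m * bins) + 1L), nbins = bins)
  p <- h[h > 0] / sum(h)
  -sum(p * log(p))
}

# Expected worm-like-chain persistence length of the fiber generator:
# per-step tangent correlation of a von Mises turn is I1(k)/I0(k), so
# <cos dtheta(s)> = A^(s/step) = exp(-s / (2 Lp)) with
# Lp = -step / (2 log A).
wlc_true_lp <- function(kappa_step, step_um) {
  A <- besselI(kappa_step, 1) / besselI(kappa_step, 0)
  -step_um / (2 * log(A))
}

# Rotate a 2D mask/image by 90 degrees (exact, no interpolation).
rot90_mat <- function(m) t(m)[, rev(seq_len(nrow(m))), drop = FALSE]
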