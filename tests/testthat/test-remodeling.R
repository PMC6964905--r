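# Anisotropy index, Tsai threshold, band ROIs and densification.

test_that("anisotropy endpoints: featureless 0, stripes ~1 with the right
           orientation", {
  expect_equal(anisotropy_index(matrix(1, 64, 64))$alpha, 0)
  a <- anisotropy_index(make_stripes(100, phi = pi / 6, period = 8))
  expect_gte(a$alpha, 0.95)
  # stripes along phi + 90 degrees (intensity varies along phi)
  want <- (pi / 6 + pi / 2) %% pi
  expect_lt(abs(a$orientation - want) * 180 / pi, 2)
  expect_error(anisotropy_index(matrix(1, 16, 16)), ">= 32")
  expect_error(anisotropy_index(matrix(1, 64, 32)), "square")
})

test_that("anisotropy is rotation-equivariant across stripe angles", {
  angles <- seq(0, pi * 5 / 6, by = pi / 6)
  res <- lapply(angles, function(phi)
    anisotropy_index(make_stripes(120, phi = phi, period = 8)))
  alphas <- vapply(res, `[[`, numeric(1), "alpha")
  expect_lt(max(alphas) - min(alphas), 0.05)
  for (i in seq_along(angles)) {
    want <- (angles[i] + pi / 2) %% pi
    got <- res[[i]]$orientation
    dd <- min(abs(got - want), pi - abs(got - want)) # axial difference
    expect_lt(dd * 180 / pi, 3)
  }
})

test_that("alpha increases monotonically with orientation concentration", {
  kap <- c(0, 0.5, 1, 2, 4, 16)
  al <- vapply(kap, function(k) {
    mean(vapply(1:3, function(s) {
      g <- generate_fiber_image(fiber_field_params(
        n_fibers = 200, kappa_orient = k, kappa_step = 1e6,
        shape = c(128L, 128L), seed = s))
      anisotropy_index(g$image$values[15:114, 15:114, 1])$alpha
    }, numeric(1)))
  }, numeric(1))
  expect_gt(stats::cor(kap, al, method = "spearman"), 0.95)
})

test_that("Tsai threshold: binary input recovered exactly, moment residuals
           tiny, exhaustive oracle agreement", {
  v <- c(rep(10, 60), rep(200, 40))
  mt <- moments_threshold(v)
  expect_equal(mt$p0, 0.6)
  expect_equal(mt$z0, 10); expect_equal(mt$z1, 200)
  expect_true(all((v > mt$threshold) == (v == 200)))
  expect_error(moments_threshold(rep(7, 5)), "constant")

  set.seed(10)
  for (i in 1:10) {
    h <- stats::rpois(256, 20) * (stats::runif(256) < 0.7)
    v <- rep(0:255, h)
    if (length(unique(v)) < 3) next
    mt <- moments_threshold(v)
    resid <- max(abs(c(mt$p0 * mt$z0 + (1 - mt$p0) * mt$z1 - mt$m1,
                       mt$p0 * mt$z0^2 + (1 - mt$p0) * mt$z1^2 - mt$m2,
                       mt$p0 * mt$z0^3 + (1 - mt$p0) * mt$z1^3 - mt$m3) /
                     c(mt$m1, mt$m2, mt$m3)))
    expect_lt(resid, 1e-6)
    lv <- sort(unique(v))
    off <- abs(match(mt$threshold, lv) - match(brute_tsai_threshold(v), lv))
    expect_lte(off, 1) # p0 quantization can move the cut one level
  }
  # linear ramp: closed form and oracle agree exactly
  ramp <- rep(0:255, each = 4)
  expect_equal(moments_threshold(ramp)$threshold, brute_tsai_threshold(ramp))
})

test_that("band ROI is the analytic annulus and clamps thin bands", {
  cm <- array(FALSE, c(64, 64, 1))
  iy <- matrix(1:64, 64, 64); ix <- matrix(1:64, 64, 64, byrow = TRUE)
  cm[, , 1] <- (iy - 32)^2 + (ix - 32)^2 <= 10^2
  band <- make_band_roi(binary_mask(cm, c(1, 1, 1)), thickness_um = 5)
  expect_false(any(band$values & cm))
  got <- sum(band$values)
  want <- pi * (15^2 - 10^2)
  expect_lt(abs(got - want) / want, 0.05)
  # sub-voxel thickness gives a 1-voxel rim
  rim <- make_band_roi(binary_mask(cm, c(1, 1, 1)), thickness_um = 0.2)
  expect_true(any(rim$values))
  expect_false(any(rim$values & cm))
  d <- distance_transform(cm, c(1, 1, 1))
  expect_true(all(d[rim$values] <= 1 + 1e-9))
  expect_error(make_band_roi(binary_mask(array(FALSE, c(4, 4, 1)))), "empty")
})

test_that("fiber density: exact fractions and additivity over disjoint ROIs", {
  img <- matrix(0, 100, 100)
  img[, 1:50] <- 200
  img <- img + matrix(runif(1e4), 100, 100) # tiny jitter, two clear classes
  # ROI fully over the fiber block
  roi_f <- array(FALSE, c(100, 100, 1)); roi_f[30:60, 5:40, 1] <- TRUE
  expect_equal(fiber_density(img, roi_f), 1)
  # half fiber, half background
  roi_h <- array(FALSE, c(100, 100, 1)); roi_h[26:75, 26:75, 1] <- TRUE
  expect_equal(fiber_density(img, roi_h), 0.5)
  # union density is the pixel-weighted mean (exact)
  roi_a <- array(FALSE, c(100, 100, 1)); roi_a[1:20, 1:30, 1] <- TRUE
  roi_b <- array(FALSE, c(100, 100, 1)); roi_b[81:100, 41:100, 1] <- TRUE
  thr <- moments_threshold(img)
  da <- fiber_density(img, roi_a, thr); db <- fiber_density(img, roi_b, thr)
  du <- fiber_density(img, roi_a | roi_b, thr)
  na <- sum(roi_a); nb <- sum(roi_b)
  expect_equal(du, (da * na + db * nb) / (na + nb))
  expect_error(fiber_density(img, array(FALSE, c(100, 100, 1))), "empty")
})

test_that("peri-cellular compaction is detected in synthetic scenes", {
  # fibers denser inside an annulus around a central cell than far away
  set.seed(31)
  wins <- 0L
  for (s in 1:5) {
    iy <- matrix(1:128, 128, 128); ix <- matrix(1:128, 128, 128, byrow = TRUE)
    cell <- (iy - 64)^2 + (ix - 64)^2 <= 12^2
    rim <- (iy - 64)^2 + (ix - 64)^2 <= 30^2 & !cell
    img <- matrix(0, 128, 128)
    img[rim] <- 200 * (runif(sum(rim)) < 0.45)   # 3x rasterization odds
    far <- !rim & !cell
    img[far] <- 200 * (runif(sum(far)) < 0.15)
    img <- img + matrix(abs(rnorm(128^2, 0, 5)), 128, 128)
    cmask <- binary_mask(cell, c(0.312, 0.312, 1))
    band <- make_band_roi(cmask, thickness_um = 7)
    ctrl <- array(FALSE, c(128, 128, 1)); ctrl[1:30, 1:30, 1] <- TRUE
    thr <- moments_threshold(img)
    if (fiber_density(img, band, thr) > fiber_density(img, ctrl, thr))
      wins <- wins + 1L
  }
  expect_equal(wins, 5L)
})

test_that("automated ROI placement avoids cells and targets the gap", {
  cm <- array(FALSE, c(160, 160, 1))
  iy <- matrix(1:160, 160, 160); ix <- matrix(1:160, 160, 160, byrow = TRUE)
  cm[, , 1] <- ((iy - 40)^2 + (ix - 40)^2 <= 12^2) |
    ((iy - 120)^2 + (ix - 120)^2 <= 12^2)
  rois <- place_rois(binary_mask(cm, c(1, 1, 1)), roi_px = 50)
  ctrl <- rois$control
  sub <- cm[ctrl$y:(ctrl$y + 49), ctrl$x:(ctrl$x + 49), 1]
  expect_equal(sum(sub), 0L) # control window clear of cells
  ali <- rois$alignment
  ctr <- c(ali$x + 25, ali$y + 25)
  expect_lt(sqrt(sum((ctr - c(80, 80))^2)), 8) # centred between the cells
})
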