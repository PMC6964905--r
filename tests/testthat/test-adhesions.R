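# Focal-adhesion detection, 2D and 3D.

test_that("a noise-only image yields zero focal adhesions", {
  set.seed(9)
  blank <- image_stack(matrix(0.05 + abs(rnorm(300 * 300, 0, 0.02)), 300, 300),
                       spacing = c(0.1, 0.1, 0.5))
  cm <- array(FALSE, c(300, 300, 1)); cm[50:250, 50:250, 1] <- TRUE
  det <- detect_fa_2d(blank, binary_mask(cm, c(0.1, 0.1, 0.5)))
  expect_equal(det$n, 0L)
  expect_error(detect_fa_2d(blank, binary_mask(array(FALSE, c(300, 300, 1)))),
               "empty cell mask")
})

test_that("2D pipeline recovers puncta counts on synthetic cells", {
  for (s in c(5, 7)) {
    sc <- generate_fa_scene(fa_scene_params(n_fa = 12, seed = s))
    det <- detect_fa_2d(sc$image, sc$cell_mask)
    expect_lte(abs(det$n - 12L), 1L)
    # detection smooths with the sigma-5 LoG, so measured areas sit above the
    # half-maximum truth footprint but within the broadened support
    expect_gt(det$mean_size, 0.8 * mean(sc$truth$size))
    expect_lt(det$mean_size, 3.0 * mean(sc$truth$size))
    # every truth centre has a detection nearby (within the LoG scale)
    dmat <- outer(det$fa$x_px, sc$truth$x_vox, "-")^2 +
      outer(det$fa$y_px, sc$truth$y_vox, "-")^2
    expect_lt(max(apply(sqrt(dmat), 2, min)), 6)
  }
})

test_that("sub-threshold punctae are removed by the particle size filter", {
  sc <- generate_fa_scene(fa_scene_params(n_fa = 12, seed = 5))
  img <- sc$image$values[, , 1]
  # add 6 small punctae (footprint ~12 px^2 at half max) inside the cell
  d <- dim(img)
  iy <- matrix(seq_len(d[1]), d[1], d[2])
  ix <- matrix(seq_len(d[2]), d[1], d[2], byrow = TRUE)
  sds <- sqrt(12 / (2 * pi * log(2)))
  keepaway <- as.matrix(sc$truth[, c("y_vox", "x_vox")])
  cellm <- sc$cell_mask$values[, , 1]
  # pick grid positions inside the cell, clear of the true FAs and each other
  cand <- expand.grid(y = seq(80, 220, by = 14), x = seq(80, 220, by = 14))
  ok <- vapply(seq_len(nrow(cand)), function(r) {
    cellm[cand$y[r], cand$x[r]] &&
      min(sqrt((keepaway[, 1] - cand$y[r])^2 +
                 (keepaway[, 2] - cand$x[r])^2)) > 16
  }, logical(1))
  spots <- as.matrix(cand[ok, ][1:6, ])
  for (r in seq_len(nrow(spots))) {
    g <- exp(-((iy - spots[r, 1])^2 + (ix - spots[r, 2])^2) / (2 * sds^2))
    img <- pmax(img, 0.2 + 0.8 * g)
  }
  det <- detect_fa_2d(image_stack(img, spacing = sc$image$spacing),
                      sc$cell_mask)
  expect_lte(abs(det$n - 12L), 1L) # small punctae filtered out
})

test_that("raising min_size never increases the particle count", {
  sc <- generate_fa_scene(fa_scene_params(n_fa = 15, seed = 11))
  counts <- vapply(c(0, 50, 150, 400), function(ms)
    detect_fa_2d(sc$image, sc$cell_mask,
                 fa2d_params(min_size = ms))$n, integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("default-config FA counts on pinned scenes are stable", {
  # regression guard against silent pipeline re-ordering
  sc5 <- generate_fa_scene(fa_scene_params(n_fa = 12, seed = 5))
  expect_identical(detect_fa_2d(sc5$image, sc5$cell_mask)$n, 12L)
  sc2 <- generate_fa_scene(fa_scene_params(n_fa = 12, seed = 2))
  expect_identical(detect_fa_2d(sc2$image, sc2$cell_mask)$n, 11L)
})

test_that("3D pipeline: blank stack empty; separated ellipsoids recovered
           with volumes near truth at the half-max threshold", {
  set.seed(3)
  blank <- image_stack(array(0.1 + abs(rnorm(48 * 48 * 16, 0, 0.01)),
                             c(48, 48, 16)), spacing = c(0.25, 0.25, 0.5))
  expect_equal(detect_fa_3d(blank)$n, 0L) # automatic mode: noise floor holds


  sc <- generate_fa_scene(fa_scene_params(shape = c(96L, 96L, 48L), n_fa = 15,
                                          fa_size = c(80, 200),
                                          avoid_perinuclear_band_um = 6,
                                          seed = 3))
  # the generator renders Gaussian punctae; after background removal and
  # normalization their half-max isophote sits at 0.5^(1/gamma)
  det <- detect_fa_3d(sc$image, sc$nucleus_mask,
                      fa3d_params(threshold = 0.5^(1 / 2.1)))
  expect_lte(abs(det$n - 15L), 1L)
  tot <- sum(det$fa$size_px)
  expect_lt(abs(tot - sum(sc$truth$size)) / sum(sc$truth$size), 0.2)
})

test_that("EDM watershed splits a dumbbell below the neck dynamic and merges
           above it", {
  a <- array(FALSE, c(40, 20, 20))
  iy <- array(rep(1:40, 400), c(40, 20, 20))
  ix <- array(rep(rep(1:20, each = 40), 20), c(40, 20, 20))
  iz <- array(rep(1:20, each = 800), c(40, 20, 20))
  a[(iy - 12)^2 + (ix - 10)^2 + (iz - 10)^2 <= 36] <- TRUE
  a[(iy - 29)^2 + (ix - 10)^2 + (iz - 10)^2 <= 36] <- TRUE
  a[iy >= 12 & iy <= 29 & abs(ix - 10) <= 1 & abs(iz - 10) <= 1] <- TRUE
  # sphere EDM height 6, neck height ~1.4: dynamic ~4.6
  expect_equal(max(remodelkit:::.edm_watershed(a, c(1, 1, 1), h = 2)), 2L)
  expect_equal(max(remodelkit:::.edm_watershed(a, c(1, 1, 1), h = 8)), 1L)
  # the split labels cover the mask exactly
  w <- remodelkit:::.edm_watershed(a, c(1, 1, 1), h = 2)
  expect_true(all(w[a] > 0)); expect_true(all(w[!a] == 0))
})

test_that("perinuclear band removes near-nucleus FAs and keeps distal ones", {
  d <- c(64, 64, 24); sp <- c(0.25, 0.25, 0.5)
  iy <- array(rep(1:64, 64 * 24), d)
  ix <- array(rep(rep(1:64, each = 64), 24), d)
  iz <- array(rep(1:24, each = 64 * 64), d)
  nucleus <- ((iy - 32) * sp[2])^2 + ((ix - 32) * sp[1])^2 +
    ((iz - 12) * sp[3])^2 <= 2^2
  img <- array(0.05, d)
  blob <- function(cy, cx, cz, s = 2)
    exp(-((iy - cy)^2 + (ix - cx)^2 + (iz - cz)^2) / (2 * s^2))
  img <- pmax(img, blob(32, 48, 12)) # 4 um from nucleus centre: inside band
  img <- pmax(img, blob(32, 62, 12)) # 7.5 um: outside the 5 um band
  det <- detect_fa_3d(image_stack(img, spacing = sp),
                      binary_mask(nucleus, sp),
                      fa3d_params(threshold = 0.5))
  expect_equal(det$n, 1L)
  expect_gt(det$fa$x_um, 14) # the distal one survived
  det_all <- detect_fa_3d(image_stack(img, spacing = sp),
                          params = fa3d_params(threshold = 0.5))
  expect_equal(det_all$n, 2L) # no nucleus mask: no exclusion
})

test_that("fa_summary arithmetic, including the empty set", {
  fa <- data.frame(label = 1:2, x_um = c(0, 1), y_um = c(0, 1),
                   x_px = c(1, 2), y_px = c(1, 2),
                   size_px = c(100, 200), size_um = c(1, 2),
                   circularity = c(0.9, 0.8))
  s <- fa_summary(remodelkit:::.fa_set(fa, 2L, c(0.1, 0.1, 1)))
  expect_equal(s$count, 2L)
  expect_equal(s$mean_size, 150)
  empty <- fa_summary(remodelkit:::.fa_set(fa[0, ], 2L, c(0.1, 0.1, 1)))
  expect_equal(empty$count, 0L)
  expect_true(is.na(empty$mean_size))
  set.seed(1)
  sizes <- runif(1000, 50, 500)
  fa1000 <- data.frame(label = 1:1000, x_um = 0, y_um = 0, x_px = 0, y_px = 0,
                       size_px = sizes, size_um = sizes * 0.01,
                       circularity = 1)
  expect_equal(fa_summary(remodelkit:::.fa_set(fa1000, 2L, c(0.1, 0.1, 1)))$mean_size,
               mean(sizes))
})
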