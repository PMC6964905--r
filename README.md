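# remodelkit

Image quantification of cell-driven extracellular-matrix remodeling in
collagen and collagen–Matrigel hydrogels.

Cells embedded in fibrous hydrogels migrate by pulling on, aligning,
compacting and proteolytically degrading the surrounding collagen network.
Experiments that probe this biology produce multi-channel confocal images —
a labeled fiber mesh, labeled cell bodies, a dye-quenched (DQ) collagen
degradation reporter, vinculin-tagged focal adhesions, and 2D time-lapse
videos of migrating cells — and a set of standard measurements on them.
`remodelkit` implements those measurements as one tested R package, for
researchers who need the numbers rather than a chain of interactive
plugins:

| Assay | Function(s) | Output |
|---|---|---|
| Fiber-network morphometry | `fiber_morphometry()`, `trace_fibers()` | mean fiber length, persistence length, pore size (µm) |
| Fiber alignment | `anisotropy_index()` | anisotropy index α ∈ [0, 1] + dominant orientation |
| Densification | `fiber_density()`, `make_band_roi()` | fiber-pixel fraction in control / alignment / 7 µm peri-cellular band ROIs |
| Matrix degradation | `dq_segment()`, `dq_volume()` | DQ-collagen volume (µm³) per cell |
| Focal adhesions | `detect_fa_2d()`, `detect_fa_3d()` | FA count, areas (px², µm²) or volumes (µm³) per cell |
| Cell motility | `track_timelapse()`, `motility_stats()` | mean accumulated distance (µm), speed (µm/h) |

The models at the core, in the field's standard notation:

* **Anisotropy** — the 2×2 second-moment orientation tensor of FFT spectral
  power in a radial band, reduced to α = (λ₁ − λ₂)/(λ₁ + λ₂): 0 for an
  isotropic fiber network, 1 for a fully aligned one.
* **Persistence length** — the worm-like-chain tangent-correlation decay
  ⟨cos Δθ(s)⟩ = exp(−s/2Lₚ), fitted on log-correlations pooled over traced
  fiber polylines.
* **Pore size** — 2 × median of the Euclidean distance field of the
  background at its regional maxima (largest-inscribed-sphere family),
  computed with anisotropic voxel spacing.
* **Tsai moment-preserving threshold** — the binarization whose two-level
  image preserves the first three gray-level moments of the input; used for
  densification and DQ segmentation.
* **MAD and speed** — per-track accumulated distance Σₜ‖p(t+1) − p(t)‖ and
  its time-normalized mean over tracks from constrained mutual
  nearest-neighbour linking.

Because the microscopy behind such studies is rarely deposited, the package
includes a synthetic-scene generator (`generate_fiber_image()`,
`generate_fa_scene()`, `generate_dq_scene()`, `generate_timelapse()`) that
produces images with exact, geometry-derived ground truth; every pipeline
is validated against it end-to-end.

## Worked example

```r
library(remodelkit)

## a partially aligned fiber field (orientation concentration kappa = 2)
g <- generate_fiber_image(fiber_field_params(
  n_fibers = 40, kappa_orient = 2, theta0 = pi/3,
  spacing = c(0.2, 0.2, 1), shape = c(192L, 192L), seed = 11))

fiber_morphometry(g$image)
#> <morphometry_result> 37 fibers | mean length 8.969 um | persistence 6.192 um | pore size 2.912 um

a <- anisotropy_index(g$image$values[47:146, 47:146, 1])
sprintf("alpha = %.3f, orientation = %.1f deg", a$alpha, a$orientation * 180/pi)
#> "alpha = 0.330, orientation = 58.0 deg"

## focal adhesions in a synthetic vinculin image (12 punctae placed)
sc  <- generate_fa_scene(fa_scene_params(n_fa = 12, seed = 5))
det <- detect_fa_2d(sc$image, sc$cell_mask)
det
#> <focal_adhesion_set> 2D: 12 FAs, mean size 132 px^2

## a 20-frame time-lapse of five migrating cells
tl  <- generate_timelapse(track_sim_params(n_cells = 5, n_frames = 20, seed = 3))
out <- track_timelapse(tl$frames)
out$stats
#> <motility_result> 5 tracks | MAD 38.71 um | speed 8.149 um/h
mean(tl$accumulated_um)   # generator ground truth
#> 38.72
```

The traced 37 (not 40) fibers reflect short fibers dropped by the
`min_fiber_um` filter and chains merged at shallow crossings; the anisotropy
α = 0.33 sits where a κ = 2 orientation concentration should — well above
isotropic (≈ 0.1 at this noise level) and far below a grating (≥ 0.95). The
recovered MAD differs from truth by 0.03 % here; the acceptance suite bounds
the error at 2 % across seeds.

A thin command-line front end over the same functions ships in
`inst/cli/remodelkit.R` (subcommands `fibers`, `anisotropy`, `density`,
`degradation`, `fa2d`, `fa3d`, `track`, `simulate`), e.g.

```sh
Rscript inst/cli/remodelkit.R simulate fibers --seed 4 --out scene.csv
Rscript inst/cli/remodelkit.R fibers --in scene.tif --spacing 0.099,0.099,0.42 --out metrics.csv
```

## Documentation

The methods vignette (`vignettes/remodelkit-methods.Rmd`) describes each
model and its assumptions, every tunable parameter with units and defaults,
what the synthetic generator does and does not emulate, and the package's
numerical conventions and known limitations.
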