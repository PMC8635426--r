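# histoquant

Quantitative image analysis for histology and fluorescence micrographs in
wound-healing and graft-remodeling studies. The package turns the
image-quantification steps such studies usually script ad hoc into tested,
reusable R functions:

- **Trichrome colour deconvolution** — Beer–Lambert unmixing of Masson's
  trichrome RGB images with a fixed unit-norm stain matrix
  (`OD = Cᵀd`, solved exactly per pixel), yielding per-stain density planes
  and collagen area fraction.
- **Per-cell immunofluorescence quantification** — automated Otsu
  thresholding of the DAPI channel, a fixed 0.3 threshold for marker
  channels, 8-connected component counting with an inclusive 15-px size
  filter, marker area per cell, and relative GFP⁺ cell counts.
- **Clonal analysis** of multicolour reporter images — per-channel
  components classified as clones (area ≥ 2000 px, inclusive) versus single
  cells, with group statistics.
- **Fibre architecture** — structure-tensor orientation fields, the axial
  alignment coefficient `R̄ = |Σ e^{2iθ}|/n` on doubled angles, the Rayleigh
  circular-uniformity test (`z = nR̄²`), PCA over fibre features, and
  box-counting fractal dimension.
- **Seeded phantom generators** for every input class, each paired with
  exact ground truth, so all of the above is validated by recovery
  experiments rather than by eye.
- **Batch orchestration** — a manifest-driven pipeline with per-group
  mean ± SEM, one-way ANOVA and Tukey/Benjamini–Hochberg post hoc tests,
  plus a thin command-line wrapper (`inst/cli/histoquant`).

Who it is for: anyone quantifying collagen content and architecture,
marker expression per cell, or clonal proliferation from standard RGB
micrographs, who wants the measurement rules (thresholds, size filters,
connectivity, angle conventions) explicit and tested.

## Worked example

```r
library(histoquant)

## trichrome: deconvolve a phantom with known 30% collagen coverage
ph  <- make_trichrome_phantom(seed = 42, collagen_fraction = 0.3)
od  <- rgb_to_od(ph$image, i0 = 255, eps = 0)
res <- collagen_content(deconvolve(od), density_threshold = 0.2)
#> collagen fraction: 0.306 (truth 0.306), tissue px: 36864, clip: 0.000

## immunofluorescence: count nuclei, normalize marker area per cell
ifp <- make_if_phantom(seed = 42)
q   <- quantify_if(ifp$image)
#> nuclei: 12 (truth 12); red marker area/cell: 21.33 px (truth 21.33)

## fibre alignment: structure tensor -> doubled-angle resultant length
fp <- make_fiber_phantom(seed = 42, kappa = 4)
fm <- quantify_fibers(fp$image)
#> alignment r_bar: 0.851 (Bessel-ratio expectation 0.864); Rayleigh p: 2.2e-308

## clones: the inclusive 2000-px rule
cl <- make_clone_phantom(seed = 42, areas = list(red = c(2500, 1500)))
quantify_clones(cl$image)
#> clones: 1, singletons: 1
```

The collagen fraction matches the phantom's realized coverage because
deconvolution inverts the exact forward model that generated the image; the
nucleus count and area-per-cell are exact because phantom objects are
rasterized with integer-pixel truth; the alignment coefficient approaches
the von Mises population value `I₁(κ)/I₀(κ)` (0.864 at κ = 4); and the
2500-px component is a clone while the 1500-px one is a single cell.

A one-command end-to-end demonstration (12 phantoms, all four assay stages,
ground-truth recovery checks, deterministic outputs):

```r
run_demo(seed = 7, out_dir = "demo")
```

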