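# scarkit

Quantitative analysis of incisional scar healing in rodent models.

Preclinical wound-healing studies (e.g. testing pre-incisional adjuvants
such as N-acetylcysteine in rat dorsal incisions) quantify healing along
four streams: how organized the collagen is in trichrome-stained sections,
how the wound geometry evolves in histological sections, how the visible
scar shrinks in calibrated photographs, and whether treatment arms differ
statistically. scarkit implements all four as a tested, reusable R
pipeline, together with seeded synthetic-data generators so every stage can
be validated against known ground truth. It is aimed at researchers and
image-analysis staff working on wound-healing and scar-remodeling models.

## What it computes

**Collagen fiber organization.** Collagen pixels are located by the
blue/red stain ratio of Masson's trichrome. Per-pixel axial orientation
θ ∈ [0°, 180°) is estimated by weighted vector summation: each collagen
pixel *j* within a disk around pixel *c* contributes a unit vector at twice
the angle of the segment *c → j*, weighted by its collagen signal. Fiber
organization is the directional variance on doubled angles,

  V = 1 − |Σ w e^(2iθ)| / Σ w ∈ [0, 1],

0 for perfectly aligned and → 1 for uniformly random orientations. Four
metrics are reported per region (scar S, flanking boxes LD/LP/RP/RD, plus
pooled distal/proximal rows): overall directional variance, mean local
directional variance (50 px neighborhoods), fiber density, and mean blue
intensity. For fiber phantoms with von Mises-distributed orientations the
population value is known in closed form, V = 1 − I₁(κ)/I₀(κ), which is
how the pipeline is validated.

**Histomorphometry.** From section measurements (D, DPA, EPI, L, N, NEO,
S, T, H, B) the eight healing indices are SCI = (L−S)/L, DCI = (N−D)/N,
WSI = (N−T)/N, RHI = (H₀−H)/H₀, MRI = (B₀−B)/B₀, GCI = SCI+DCI,
GHI = GCI−WSI, GRI = (RHI+MRI)/2, with day-7 baselines H₀, B₀. A bundled
reference summary table parameterizes the simulator and anchors a
consistency check of the formulas. The Meeh–Rubner surface-area utility
A = k·m^(2/3) supports dose scaling.

**Planimetry.** Calibrated shoelace areas, polyline lengths, and replicate
averaging from wound-photograph annotations, summarized into group × day
time-series over the standard 11 observation days.

**Group statistics.** The study-style decision pipeline per endpoint:
Shapiro–Wilk normality gate → ANOVA+Tukey or Kruskal–Wallis across the
three NAC arms → pooling into gNAC when they do not differ → gNAC vs CONT
t-test/Mann–Whitney (or NAC30 vs CONT when arms stay separate).

## Worked example

```r
library(scarkit)

# a validation phantom with known orientation concentration (kappa = 2)
ph <- generate_fiber_phantom(phantom_spec(
  image_height_px = 896, image_width_px = 896, n_fibers = 8000,
  kappa = 2, mean_orientation_deg = 60, target_density = 0.10,
  fiber_thickness_px = 3, fiber_length_px = 35, seed = 1))
cm    <- segment_collagen(ph$image)
field <- estimate_orientation_field(cm, window_radius_px = 8)

fiber_density(cm)                        # 0.100  (target was 0.10)
overall_directional_variance(field)      # 0.340  measured
vm_directional_variance(2)               # 0.302  closed-form target

# healing indices at day-7 control group means (day 7 is the baseline,
# so the remodeling indices are 0 by construction)
compute_indices(
  list(D = 527.2, L = 1909.8, N = 1434.4, S = 1533.2, T = 915.5,
       H = 1604.5, B = 189079.1),
  list(H0 = 1604.5, B0 = 189079.1))
#>  SCI   DCI   WSI   GCI   GHI   RHI   MRI   GRI
#> 0.197 0.632 0.362 0.830 0.468 0.000 0.000 0.000
```

The measured variance sits within the validated 0.05 band of the
closed-form value; SCI ≈ 0.20 and DCI ≈ 0.63 say that by day 7 the wound
has closed about 20% of its superficial span and 63% of its depth relative
to the surrounding dermis.

An end-to-end synthetic run (section phantom → fiber metrics, simulated
morphometry → indices and statistics, simulated planimetry → time-series):

```r
res <- run_pipeline(pipeline_config(seed = 1, out_dir = "demo_run"))
res$fiber_metrics
```

A thin CLI wrapper over the same functions ships at
`inst/scripts/scarkit.R`
(`Rscript scarkit.R run-all|simulate|fibers|morphometry|planimetry|scores|stats ...`).

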