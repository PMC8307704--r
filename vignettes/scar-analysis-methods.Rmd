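---
title: "Methods: quantitative scar-healing analysis with scarkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative scar-healing analysis with scarkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

scarkit implements the quantitative machinery of rodent incisional-wound
studies: collagen fiber organization from Masson's-trichrome histology,
wound histomorphometry indices, scar planimetry from calibrated photographs,
VAS histology-score aggregation, and a normality-gated group-pooling
statistical pipeline. This vignette explains the models, the parameters
that matter, the synthetic-data generators used for validation, and the
numerical and design choices behind them.

## 1. Collagen fiber organization

### Segmentation

Masson's trichrome renders collagen blue and cytoplasm/muscle red. A pixel
joins the collagen mask when its blue/red intensity ratio exceeds
`ratio_threshold` (default 1, strict inequality so neutral gray is
excluded; the small `1e-6` in the denominator only guards division by
zero). The collagen *weight* of a mask pixel is `clip(blue - red, 0, 1)` —
a simple monotone proxy for stain strength that is zero off the mask.

### Orientation by weighted vector summation

Fiber orientation is axial: a fiber at 10° and one at 190° are the same
fiber. All axial statistics therefore work on *doubled angles*, where 0°
and 180° coincide and perpendicular orientations are antipodal.

For every collagen pixel `c`, every other collagen pixel `j` within a disk
of radius `window_radius_px` contributes the unit vector `exp(2i*phi)`
(`phi` = angle of the segment `c -> j`), scaled by the collagen weight of
`j`. The orientation at `c` is half the argument of the resultant, in
`[0, 180)` degrees; the *certainty* is the resultant length divided by the
contributing weight, in `[0, 1]`. Along a straight fiber the contributions
reinforce (certainty near 1); at a crossing of perpendicular fibers the
doubled angles cancel (certainty near 0). Pixels whose neighborhood weight
is below `1e-9` carry no orientation and are excluded from all statistics.

The summation over all pixels is evaluated as an FFT cross-correlation with
a fixed complex disk kernel. Because the kernel is symmetric under offset
negation on doubled angles, this equals the literal per-pixel double loop
to floating-point round-off; the test suite checks pixel-for-pixel
agreement against a brute-force reference implementation on 32 x 32
fixtures.

Parameter notes:

* `window_radius_px` (default 8 px): must exceed the fiber thickness so the
  segment direction dominates the cross-width contributions. Larger windows
  average more neighbors but mix in more foreign fibers.
* Contributor weighting is the plain collagen weight with no distance
  decay — the simplest scheme consistent with weighted vector summation;
  both the window and (via the code) the weighting are deliberate,
  documented defaults rather than claims about the original
  implementation, which is not public.
* Angles are measured counterclockwise from the image x-axis as displayed
  (origin top-left, y down), axial domain `[0, 180)`.

### Directional variance

For axial angles `theta_i` with weights `w_i`, the directional variance is
the weighted circular variance on doubled angles,

    V = 1 - |sum_i w_i exp(2i theta_i)| / sum_i w_i,

0 for perfect alignment, 1 in the uniform limit, and exactly 1 for two
equally weighted perpendicular orientations. (Published wordings
occasionally state the opposite correspondence; scarkit follows the
standard circular-statistics convention, which is also the one consistent
with the weighted-vector-summation method itself.)

Two region statistics are reported:

* **overall directional variance** — one `V` pooled over all defined pixels
  of the region;
* **mean local directional variance** — at each defined pixel, `V` over the
  disk of `local_radius_px` (default 50 px, the standard choice) around it,
  truncated at image borders; the summary is the unweighted mean of the map.

In both statistics each pixel enters with weight
`collagen weight x certainty^2`. This is a deliberate design choice:
per-pixel orientation estimates at fiber crossings and contact points are
noisy, and with uniform weights that noise inflates the variance of dense
fields by 0.1-0.4. Squared-certainty weighting suppresses exactly the
incoherent pixels while leaving clean fibers untouched; with it, the
measured variance of validation phantoms tracks the closed-form target
across the whole concentration range (see below).

### Regions and the section report

A section is analyzed over five regions: the scar `S` (box or polygon) and
four square flanking boxes — left/right distant (`LD`, `RD`) and left/right
proximal (`LP`, `RP`) — of side 500 px in the standard layout (the
constructor accepts a different side so small synthetic fixtures remain
practical). `analyze_section()` reports four metrics per region — overall
directional variance, mean local directional variance, fiber density (mask
fraction), mean blue intensity over mask pixels — plus pooled `Distal`
(RD&LD) and `Proximal` (RP&LP) rows. Pooled rows pool the per-pixel data of
the two boxes, not the per-box metric averages.

## 2. Fiber phantoms and what the validation shows

`generate_fiber_phantom()` renders straight anti-aliased segments of fixed
thickness (default 3 px) whose axial orientations are drawn from a von
Mises distribution on doubled angles with concentration `kappa`
(Best-Fisher sampler). The implied population directional variance is the
closed form `1 - I1(kappa)/I0(kappa)`; `kappa = 0` is uniform, large
`kappa` aligned. Collagen pixels blend toward `(0.2, 0.3, blue_level)`
over a `(background_red_level, 0.4, 0.4)` background, which makes blue-red
segmentation unambiguous while still exercising the ratio logic. A
rendered pixel counts as collagen in the ground truth when its blended
color is blue-dominant — at the default colors, fiber coverage above 1/3 —
so the generator's realized density is defined independently of the
segmentation code. Fibers are rendered until the target density is
reached; the truth object records every drawn orientation, the realized
density, and the closed-form variance. All generators take explicit seeds
and restore the caller's RNG state.

Defaults (density 0.7, `kappa` 0.3, `blue_level` 0.8) mimic the dense
trichrome-stained dermis summarized in published section-level tables
(densities 0.6-0.75, blue intensities 0.71-0.76, variances 0.84-0.92).

The *parameter-recovery validation* deliberately uses sparser phantoms:
896 x 896 px, target density 0.10, fiber length 35 px, thickness 3 px,
concentration grid {0, 0.5, 1, 2, 5, 10}, ten seeds per concentration.
Two opposing error sources dictate this design. At high density,
neighboring-fiber contamination adds per-pixel orientation noise that
inflates the measured variance; at low fiber counts the sample variance of
the uniform limit is biased downward by roughly `0.886/sqrt(n_fibers)`.
The chosen geometry keeps ~700 fibers per phantom, bounding both effects
near 0.03, and the measured mean variance then matches the Bessel closed
form within 0.05 at every grid point while decreasing strictly with
`kappa`. Passing this shows the pipeline reads out orientation structure
correctly when fibers are resolvable; it does *not* certify absolute
variance accuracy in heavily overlapping fields, where all pixel-based
estimators partially mix neighboring fibers. Real sections are also
curved, variably stained, and contain nuclei and artifacts that the
phantoms do not emulate — phantom tests validate the measurement algebra,
not the histology.

## 3. Histomorphometry indices

From the section measurements (micrometres; areas in square micrometres) —
wound depth `D`, dermal proliferation area `DPA`, epidermis thickness
`EPI`, re-epithelialization length `L`, natural dermis thickness `N`, new
epidermis thickness `NEO`, border distance `S`, central connective-tissue
thickness `T`, hair-follicle distance `H`, dense blue-stained area `B` —
the eight indices are

    SCI = (L - S)/L        DCI = (N - D)/N       WSI = (N - T)/N
    RHI = (H0 - H)/H0      MRI = (B0 - B)/B0
    GCI = SCI + DCI        GHI = GCI - WSI       GRI = (RHI + MRI)/2

with `H0`, `B0` the day-7 baselines (same-group day-7 means under the
default policy; explicit baselines are accepted). The formulas are not
stated explicitly in the source summary tables; they were recovered from
the parameter definitions and locked only after a consistency check:
applied to the published group means they reproduce at least 80% of the
published index cells within ±0.02. Cells evaluated exclude the day-7
remodeling indices, which are the baseline day itself (the index is 0 by
construction there, and the published day-7 control RHI/MRI values are
internally inconsistent — a likely column misprint that scarkit reports
rather than reconciles). Residual discrepancies in pooled-group remodeling
cells are the expected mean-of-ratios versus ratio-of-means effect:
scarkit averages per-sample ratios, matching the published `mean ± SD`
convention.

Group summaries report the mean and SD of per-sample indices by group and
day. The Meeh-Rubner utility `A = k * mass^(2/3)` (k = 10 by default,
giving ~400 cm² at 250 g) supports dose-area scaling, with
`treated_area_fraction()` for the treated-to-total surface ratio.

## 4. Planimetry

Wound photographs are annotated with up to three replicate area polygons,
three length polylines, and width segments (three per rostral/central/
caudal region); a photographed millimetre scale supplies `pixels_per_mm`.
Areas use the shoelace formula (orientation-independent, self-intersecting
polygons rejected); lengths are summed Euclidean segments. A wound record
averages replicates with equal weight — including all nine width segments,
since per-region-then-overall averaging coincides under equal counts.
Records summarize to group x day mean ± SD tables over the standard
observation days {1, 2, 3, 4, 7, 14, 21, 28, 35, 45, 60}.

The synthetic time-series generator uses monotone exponential decay with
lognormal noise per measure. No published time-course model exists for
these wounds; the decay form is acknowledged plumbing chosen for
monotonicity and positivity, with initial dimensions matching a 15 mm
incision (~2 mm wide, ~30 mm² at day 1) and a faster early area/width
decay in the NAC30 arm so the downstream comparison has a known effect to
detect.

## 5. Histology scores

Semi-quantitative scoring uses a continuous 0-3 VAS with 0.1 increments
(the continuous extension of the ordinal 0-3 rubric; the exact anchor
definitions of the extended scale are study-internal, so the range is
configurable). Aggregation is the arithmetic mean ± SD across raters per
sample and parameter; single-rater SDs are flagged `NA`. Binary wound
closure is decided per sample by rater majority; exact ties are excluded
from the closure rate with a warning.

## 6. Group statistics

Per endpoint and day, on groups `CONT`, `NAC15`, `NAC30`, `NAC45`:

1. **Normality gate** — Shapiro-Wilk per group; the parametric branch
   requires every group to pass at `alpha`. Groups with n < 3 or zero
   variance force the nonparametric branch with a warning. (Whether the
   original analysis gated per group or on pooled residuals is not stated;
   per-group is the stricter reading and is what scarkit does.)
2. **NAC omnibus** — one-way ANOVA with post-hoc Tukey (parametric) or
   Kruskal-Wallis. "Two-tailed ANOVA" in the source methods is read as
   standard one-way ANOVA.
3. **Pooling** — the three NAC arms merge into `gNAC` exactly when the
   omnibus p exceeds `alpha` (strict; `p == alpha` keeps arms separate).
4. **Final comparison** — pooled: Student's equal-variance t-test (or
   Mann-Whitney) of `gNAC` vs `CONT`; not pooled: Tukey on the four-group
   fit with the `NAC30` vs `CONT` contrast reported (pairwise Mann-Whitney
   on the nonparametric branch).

`alpha = 0.05` throughout; no multiple-testing correction is applied
across endpoints or days, mirroring the original analysis (users who need
it can post-process the reported p values with `p.adjust`). Calibration is
validated by simulation: under a global null the full
gate-pool-compare pipeline rejects at 0.05 ± 0.02 over 1000 replicates
(n = 12 per arm), and a 3-SD NAC30 shift reliably blocks pooling and flags
the arm.

## 7. Numerical choices and degenerate inputs

* FFT convolutions pad to highly composite sizes (`nextn`) to avoid slow
  prime-length transforms; results match direct summation to ~1e-12.
* Zero total weight in a variance, empty masks, empty regions, zero index
  denominators, missing baselines, and constant endpoint tables are all
  signalled distinctly (error or `NA` + warning) rather than returning
  silent zeros.
* Right-angle rotations preserve the collagen mask exactly, so fiber
  metrics are rotation-invariant to 1e-6; indices are invariant under
  uniform unit rescaling; planimetry is invariant under rigid motions to
  1e-9. All three suites are tested.
* Images are written as 8-bit PNG after explicit quantization so repeated
  writes are byte-identical.

## 8. Problem sizes

Test-suite simulation sizes are chosen to keep the full suite under a few
minutes while leaving Monte-Carlo slack well inside each tolerance: 1e5
draws for closed-form variance checks, 60 phantoms (six concentrations x
ten seeds) at 896 x 896 px for parameter recovery, 500 px boxes for the
section-concordance check, and 1000 replicates for pipeline calibration.

## 9. Known limitations

* Pixel-based orientation estimation mixes neighboring fibers in dense
  fields; reported variances there are comparative metrics, not unbiased
  estimates of the fiber-level population variance.
* The morphometry simulator draws measurements independently per animal
  (truncated Gaussians); real section measurements are correlated.
* The planimetry time-series model is synthetic plumbing, not a fitted
  biological model.
* Automated measurement of the section geometry itself (done manually in
  the source workflow) is out of scope; scarkit starts from measurement
  tables and annotations.
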