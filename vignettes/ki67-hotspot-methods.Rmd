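---
title: "Methods: simulated Ki67 hotspot scoring and method comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulated Ki67 hotspot scoring and method comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ki67hotspot)
```

## The problem

The Ki67 proliferation index (PI) — the percentage of Ki67-positive nuclei
among counted tumour nuclei — is scored in breast cancer either globally or in
a *hotspot*, the tumour subregion with the apparently highest proliferation.
Manual hotspot scoring is variable: observers must first find the hotspot by
eye and then count 500 cells under a standardized protocol. Automated digital
image analysis (DIA) replaces both steps: nuclei are detected and classified
across the whole section, restricted to invasive tumour by a mask, and the
hotspot is defined exactly as the fixed-area window maximising the positive
ratio subject to a minimum cell count.

Clinical material for such comparisons is not shareable, so this package
builds the entire comparison on *synthetic* slides with known per-nucleus
ground truth. Every component is exercised against that ground truth: the
stain model, the nucleus detector, the serial-section registration, the
hotspot search (with a brute-force oracle), the simulated observers, and the
agreement statistics.

## The synthetic slide model

A case is a pair of virtual sections sharing one tissue layout.

**Regions.** The invasive tumour is a band under a smooth random front
anchored on the bottom slide edge (two sinusoidal harmonics with integer
periods, amplitude 8% of the slide height, so the nominal area fraction is
exact). Benign epithelium and carcinoma in situ are half-ellipse notches on
the opposite edge; stroma is the explicit complement. This tiling keeps every
region a simple polygon, mutually disjoint, with union equal to the slide —
properties the tests verify by rasterised pairwise intersection. In-situ
regions default to *high* Ki67 positivity (0.6) deliberately: excluding them
from the hotspot must be the mask's doing, not luck.

**Cells.** Invasive nuclei are placed by a hard-core process at
`tumour_density_per_mm2 = 1400`: a square grid of pitch $1/\sqrt{\rho}$
(26.7 µm) with uniform per-point jitter chosen so that no two centres come
closer than the maximum nucleus diameter. The density default comes from the
counted-cell scale of published DIA hotspots (a 0.5 mm² window holding a few
hundred to ~3000 cells, median around 700). Nucleus diameters are uniform in
[6, 10] µm; every nucleus must fit wholly inside its region (centroid at
least one radius from the boundary). The jittered grid is deliberately chosen
over sequential dart-throwing: it satisfies the same two contracted
properties (minimum separation, requested density) at vectorised cost; its
residual anisotropy is a known limitation (see below).

**Positivity field.** Each invasive nucleus is Ki67-positive with probability
$$p(x, y) = p_0 + (p_1 - p_0)\,e^{-d^2 / 2r^2},$$ where $d$ is the distance
to the planted hotspot centre, baseline $p_0 = 0.15$, peak $p_1 = 0.6$, and
$r$ = `hotspot_radius_um` = 400 µm — a bump whose full width is comparable to
the 707 µm scoring window, i.e. a hotspot an observer could plausibly see.
Any unimodal field with a known argmax would serve; the Gaussian bump is a
stand-in, not a fitted model of real intratumoural heterogeneity.

**Optics.** Rendering and detection share one Beer–Lambert two-stain model
with Ruifrok–Johnston haematoxylin and DAB vectors (normalised; configurable).
Negative nuclei carry haematoxylin only; positive nuclei add a DAB optical
density of 0.5–0.8, far above the 0.15 classification threshold, honouring
the scoring rule that *any* distinct brown nuclear staining is positive.
Background texture is low-pass noise clamped below 0.05 OD so it cannot
create spurious detections. The CK8/18 section fills each epithelial region
with a DAB-like blush after applying the serial rigid transform
(`serial_shift_um`, `serial_rotation_deg`, about the image centre) plus
≤ 5 µm of vertex jitter emulating section-boundary roughness.

**Non-serial corruption.** A `serial_mode = "non_serial"` case regenerates
the CK layout from an independent seed **and** scales the invasive
cross-section area by U(0.45, 0.60) — a distant tissue level where the tumour
cross-section genuinely differs. The scaling makes failure a geometric
guarantee rather than a statistical accident: the intersection-over-union of
the two epithelial masks is bounded above by their area ratio, below the 0.6
registration-failure threshold for any rigid transform.

## The measurement pipeline

**Stain inversion.** `rgb_to_od()` applies
$\mathrm{OD}_c = -\log_{10}((I_c + 1)/255)$ (the +1 guards saturated zeros);
`deconvolve()` is the plain least-squares projection onto the two stain
vectors, which is exactly invariant to any pixel component along the residual
(cross-product) direction. Through 8-bit quantization the forward–inverse
round trip is accurate to 0.02 OD for total channel OD up to about 1.0; at
jointly high concentrations the information is no longer in the pixels — at
total OD ~1.9 the G channel sits near 3 DN, where adjacent representable ODs
differ by ~0.125 and the stain inverse amplifies that floor several-fold.
The tests assert the tight bound on the attainable region and record the
behaviour beyond it.

**Nucleus detection.** Deconvolve → total nuclear OD (H + DAB) → Gaussian
smoothing at 1 µm → threshold 0.3 OD → distance-transform watershed →
area filter $[\pi(\min d/2)^2, \pi(\max d/2)^2]$ with a permissive
circularity floor of 0.4 (watershed fragments are not perfect discs).
Classification is a single inclusive threshold on the per-nucleus mean DAB
concentration (≥ 0.15). The commercial detector this stands in for is
proprietary and specified only as "shape and size" detection; the substitute's
contract — precision, recall and class accuracy against the generator's
ground truth — is what the tests enforce.

**Masking, two arms.** The *VDS arm* registers the CK epithelial mask onto
the Ki67 section (below), transforms it into the Ki67 frame, removes
manually supplied exclusion polygons (benign, in-situ), and closes at nucleus
scale; it refuses when registration failed, and such cases are excluded from
that arm only. The *rule arm* rasterises invasive-tumour region polygons on
the Ki67 section alone — the package's stand-in for a trained tumour
detector, behind the same interface (`detector =` accepts a plug-in) — and
never fails. Cell membership is centroid-in-mask: the simplest rule that
makes counts exactly reproducible.

**Registration.** Rigid only — 3 µm serial sections justify small offsets.
Matching uses *edge maps* (morphological gradient of the foreground, frame
borders removed, lightly blurred): solid tumour bands carry almost no
translation signal along their long axis, while the boundary curves are
sharp, unambiguous correspondences. The search is FFT cross-correlation over
±500 µm at a 1° rotation grid (8 µm working resolution), a 0.25° grid around
the best angle, parabolic interpolation in angle and shift, and a final
continuous Nelder–Mead polish of the blurred-edge overlap evaluated sparsely
on the fixed-edge support with bilinear sampling. The alignment score is the
foreground IoU at the estimate; `status = "failed"` below 0.6. The threshold
is a package decision — the source material reports only causes of failure,
not a criterion — and it is configurable and reported per run.

**Hotspot search.** Candidate windows are axis-aligned squares of area
0.5 mm² (side 707.107 µm) on a 25 µm origin lattice, fully inside the slide;
a window is eligible with ≥ 500 masked cells; among eligible windows the
maximal positive ratio wins, with ties broken by higher cell count, then
smaller y, then smaller x origin. Ratio comparisons use integer
cross-multiplication, so the fast path (2-D difference-array counting) and
the brute-force oracle agree *exactly*, which an acceptance test asserts on
random instances. The PI is computed over **all** cells in the window — the
counted-cell distributions of real DIA hotspots run far above the 500
minimum, which rules out a first-500 convention. Heatmap bins with no cells
have an *undefined* ratio, never zero, so cell-free area cannot dilute the
display. Windows may overlap excluded geometry as long as enough masked
cells fall inside: the ratio is defined over invasive-tumour nuclei.

**Simulated observers.** Observers read the true slide, not the detector
output (human perception does not share the algorithm's segmentation errors).
They see positivity on a coarse 250 µm grid with additive N(0, 0.05) noise;
bins too sparse to support a 500-cell count are down-weighted in proportion
to occupancy, reflecting the tendency to annotate dense tumour areas inside
the lesion rather than sparse margins. The ROI (707 µm square, enlarged in
10% steps if it holds fewer than 500 invasive cells) is counted in a
typewriter pattern: rows of `count_row_um` top-to-bottom, left-to-right,
stopping at the end of the row in which the 500th cell falls; each counted
cell's class flips with probability 0.03. The row height default is 20 µm:
at realistic hotspot densities a row then holds ~20 cells, reproducing
reported totals in the 500–533 range with means a few cells above 500. (A
50 µm row would hold ~50 cells and overshoot far beyond the reported
maxima — that is the one place where an internal default of the design notes
was overridden by the printed count distributions.)

**Agreement layer.** Consensus = per-case mean of the two observers.
Spearman correlation (mid-ranks; undefined under zero rank variance),
Bland–Altman with the n−1 SD, limits at mean ± 1.96 SD, *strictly* greater
than 1.96 SD flagging, two-sided paired t (constant non-zero differences
reported as ±Inf with p = 0), and mean/min/Q1/median/Q3/max summaries with
type-7 (linear interpolation) quantiles — the convention is fixed and
documented because the original software default is unknowable. Analyses are
pairwise-complete: VDS comparisons use only VDS-scored cases.

## Study conditions and problem sizes

`run_study()` draws, per case: a seed; a serial transform (shift uniform
±150 µm per axis, rotation ±2°); non-serial status (probability 0.27, the
failure-prone fraction of the emulated archival material — or explicit
indices); and, by default, cohort heterogeneity — baseline positivity
U(0.02, 0.35) with peak = baseline + U(0.15, 0.6) capped at 0.95 — so
case-level PIs span the wide range seen in consecutive clinical series
rather than clustering at one value (correlations computed on a
range-restricted cohort would be meaninglessly attenuated).

Problem sizes are chosen so the full suite runs in minutes on one core:
the planted-recovery and observer-bias checks use 100 ground-truth cases at
the full 4 × 4 mm default extent (no rendering — those checks are mask-level
by construction); detection-contract checks render 1.2 × 1.2 mm tiles at the
default density and optics, since per-nucleus precision/recall does not
depend on slide area; registration checks use 2 × 2 mm layouts so that the
±300 µm shift range cannot make frame clipping, rather than misalignment,
dominate the IoU. The demonstration study in `analysis/03_run_study.R` runs
40 cases at 2 × 2 mm with both arms.

## What passing tests do and do not show

The generator emulates the statistical structure the analysis relies on —
planted unimodal positivity, hard-core nucleus spacing, distractor epithelium,
rigid serial offsets, section-quality failures — not histology. Nuclei are
flat discs without chromatin texture, overlap, staining gradients, folds or
out-of-focus blur; the jittered-grid hard-core process is slightly
anisotropic; CK rendering reuses the Ki67 optics rather than a true
cytokeratin chromogen; the rule arm's default mask comes from ground-truth
polygons, so it validates the hotspot logic downstream of tumour detection,
not a tumour detector itself. Consequently the detection and classification
contracts certify correctness of the implementation on its forward model,
and the method-comparison results (DIA scoring above manual consensus, high
inter-method correlation, VDS availability below rule-arm availability)
demonstrate the *mechanisms* — maximisation over all windows versus a noisy
fixed-size sample, and registration failure handling — under controlled
conditions. None of this measures performance on real stained tissue.

## Numerical conventions

- Coordinates in µm, origin at the top-left pixel corner, x rightward,
  y downward; all windows and bins half-open.
- Pixel (i, j) has centre ((j − 0.5)·res, (i − 0.5)·res); a pixel belongs to
  a polygon iff its centre does.
- Hotspot ties: higher n_cells, then smaller y0, then smaller x0.
- PIs are reported to one decimal, as printed clinically.
- Every stochastic step derives its stream from the case seed and a role
  label, so identical seeds give bit-identical cases, scores and files.
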