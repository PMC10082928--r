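---
title: "Methods: quantitative smFISH spot counting and its synthetic validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative smFISH spot counting and its synthetic validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ramfish)
```

## The measurement model

Single-molecule RNA FISH tiles a transcript with ~43–48 fluorescent 20-nt
oligos so that each mRNA images as one diffraction-limited spot (~250 nm
across, i.e. ~2.5 pixels at the 100 nm pixel size assumed throughout).
`ramfish` reproduces the widefield quantification chain used for
Arabidopsis root-apical-meristem cells:

1. **Maximum z-projection** of the 16-bit stack (0.2 µm z-sections).
2. **Rolling-ball background subtraction**, radius 3 px.
3. **Spot calling** as regional maxima with prominence ≥ 1700 grey values.
4. **Per-cell counting** inside manually outlined polygons, with
   volume $V = A \cdot n_z \cdot 0.2\,\mu m$ and concentration $N/V$.
5. **Fluorescence comparison** via per-spot total corrected cellular
   fluorescence, $\mathrm{TCCF} = \mathrm{IntDen} - \mathrm{area}\times
   \overline{\mathrm{bg}}$, with the background mean estimated from twenty
   spot-free 3×3 intracellular ROIs.

Counting spots on a 2D projection deliberately mirrors the original
analysis; it undercounts when spots overlap in projection ("optical
crowding"), which is negligible in the 10–100 mRNA/cell regime the method
targets and is quantified by the recovery tests below.

## Image operators and their numerical contracts

**Rolling ball.** The background is the grayscale opening of the intensity
surface with a *spherical-cap* structuring element: offsets
$(dy, dx)$ with $dy^2+dx^2 \le r^2$ and heights $\sqrt{r^2-dy^2-dx^2}$.
This is the mathematical morphology form of "rolling a ball under the
surface" — erosion (min of $f - b$) followed by dilation (max of $f + b$),
with out-of-bounds offsets ignored. It is *not* the paraboloid-plus-
subsampling approximation common in interactive software; the opening form
was chosen because it is exactly testable against an independent
min-then-max double-loop oracle, while preserving the operator's contract:
the background never exceeds the image, the subtracted image is
non-negative, and adding a constant to the image shifts the background by
exactly that constant. At radius 3 the element spans 7 px, so ~2.5 px
spots cannot be entered by the ball and survive subtraction essentially
intact.

**Prominence maxima.** A candidate spot is a regional maximum whose
*topographic prominence* — its height above the highest saddle connecting
it to any higher maximum — reaches the threshold. The implementation floods
the image from the top (union–find over pixels sorted by decreasing value);
when two summit components merge, the lower summit dies and records
`prominence = peak − saddle`. A connected plateau emits one candidate at
its centroid, rounded to the nearest pixel with half-ties toward smaller
$(y, x)$ and snapped to the nearest plateau member — a pure determinism
choice. The global maximum is always emitted for a non-constant image.
Border maxima are *emitted but flagged* (`on_border`), since the original
description does not say whether edge maxima were excluded; a flag
(`exclude_edges`) provides the other behaviour. Equivalence with a
brute-force threshold-descent saddle oracle is asserted over hundreds of
random images in the test suite.

**Spot and cell ROIs.** Spot intensity uses the 3×3 block centred on the
maximum (0.09 µm² at calibration); blocks clipped by the border are flagged
and excluded from TCCF by default because their pixel area differs. Cell
polygons are rasterised by the even–odd rule over pixel centres (integer
coordinates, 0-based). Outlines drawn on half-integer coordinates avoid
boundary ambiguity entirely. The fixed-area nuclear ROI (59.94 µm²) is
realised as exactly `round(59.94/0.01) = 5994` pixels nearest the centre —
a disc-like mask — because no integer-sided square hits the requested
physical area, and comparability across groups demands an *identical*
pixel count.

**TCCF area term.** TCCF is computed *per spot*, so the "area of the
selected region" in the correction is the 9-px spot ROI, not the whole
cell; this keeps the correction dimensionally consistent with the per-spot
integrated density. Negative TCCF values are retained and flagged rather
than clipped, preserving distributional statistics for the ANOVA.

## Statistics

All standard inference goes through the same base-R routines a desk
analysis would use: `median`, `cor.test` (Pearson, two-sided), `aov` +
`TukeyHSD` (Tukey–Kramer, valid for the unequal group sizes that arise
here), with no multiple-testing correction beyond Tukey. Relative label
intensity expresses each probe set's mean TCCF as a percentage of the
brightest set (the reference is the argmax by default, so it reads exactly
100%). Co-localization between two dye channels matches spots one-to-one,
closest pairs first, within a default radius of 2 px (~200 nm, one spot
diameter) — the threshold is a package choice, stated because the source
analysis names none — and reports the mean of per-cell fractions. The
false-detection rate is spots per cell in no-probe controls, also quoted
as its reciprocal ("one spurious mRNA per k cells").

## The synthetic-data generator

The generator defines the study conditions under which the pipeline is
validated; its defaults are fixed and are not tuning knobs.

**Cells.** Per-group cell volumes are truncated-normal with the printed
group statistics — means 1191, 1233, 1278, 996, 1204 µm³ and SDs 536, 506,
604, 495, 544 µm³ for MON1, TIP41, AP2M, NRPB1 and PP2A. The source lists
five means but six SDs for six groups; the no-probe control here reuses
the 1204 µm³ mean with the sixth SD (601 µm³). Projected areas follow from
$A = V/(n_z \cdot 0.2)$ with $n_z = 25$ slices (a 5 µm optical depth,
typical for meristem cells), and each cell is a star-shaped random polygon
scaled to exactly that area, placed on non-overlapping grid slots grouped
into square fields of four cells (fields are sized to their largest
member, so packing cannot overlap).

**Counts.** True counts are gamma-mixed Poisson around $\kappa V$. The
concentrations $\kappa$ are 0.021, 0.023, 0.0288, 0.0390 and 0.0391
mRNA µm⁻³; the first two are printed values, and the last three resolve
obvious magnitude typos in the printed concentrations (0.288, 0.390) by
consistency with the printed medians and volumes (e.g. 37/1278 ≈ 0.029),
all within the stated 0.02–0.04 µm⁻³ range. Pure Poisson counts with these
volume spreads would give count–volume $R^2 \approx 0.84$, above the
printed 0.51–0.78, so each group carries an overdispersion $\phi$
(variance of the unit-mean gamma multiplier) calibrated in closed form —
$R^2 = \kappa^2\mathrm{Var}V / (\kappa \mathrm{E}V +
\kappa^2\mathrm{Var}V + \phi\,\mathrm{E}[(\kappa V)^2])$, with
truncated-normal moments — to the printed $R^2$ targets
(0.761/0.662/0.734/0.513/0.778). `phi_for_r2()` exposes the inversion and
a Monte-Carlo test verifies the closed form. The no-probe group draws
spurious spots at 0.29 per cell (one per ~3.4 cells, inside the reported
"one per three to four").

**Rendering.** Each spot is a 3D Gaussian with $\sigma_{xy} = 1.06$ px
(250 nm FWHM) and $\sigma_z = 1.5$ slices (~300 nm), peak amplitude
$\mathcal{N}(6000, 800)$ truncated at 3400 grey values — twice the
detection prominence, so detection is well-posed by design. Background is
300 grey values modulated by a smooth (16 px grain, ±15%) autofluorescence
texture, followed by Poisson shot noise, Gaussian read noise (SD 30) and
16-bit quantization. A noiseless render conserves photons: the voxel sum
equals background plus $\sum_i A_i \,(2\pi\sigma_{xy}^2)(\sqrt{2\pi}
\sigma_z)$ to well within the 10⁻³ truncation tolerance (stamps extend to
5σ).

**Fluorescence table.** The tabular generator emits per-spot grey levels
from per-group background/amplitude means chosen so the brightest set
(TIP41) reads 100% relative TCCF and the others 40/38/34/26%, with MON1
the dimmest raw spots and TIP41 the brightest — matching the reported
ordering. Spot-level noise is 15% of the spot increment; background ROI
noise 5%.

**What the generator does not emulate.** Optical aberrations, chromatic
shift, tissue-layer occlusion, nucleoli, segmentation error in the manual
outlines, and spatial correlation of transcripts within cells. Passing the
recovery tests therefore demonstrates correctness of the *computational
chain* under realistic noise, not robustness to every property of real
tissue images.

## Problem sizes and reproducibility

The validation suite uses sizes chosen to exercise the method fully at
desk scale: oracle equivalence on ≥ 200 random 16×16 images; spot recovery
on rendered fields of ~50 spots (recall and precision ≥ 0.95 at 2 px
matching); concentration recovery from 200 rendered MON1-like cells
(regression slope of recovered counts on volumes within 10% of
$\kappa = 0.021$, median count in [23, 29]); and a full six-group table at
the study's cell numbers (n = 93 per probe set, 68 no-probe). Every
stochastic step takes an explicit integer seed, and identical seeds give
byte-identical CSV output.

The per-group medians in the table tests are judged against the printed
design centres with an allowance equal to the model-vs-print offset plus
three median standard errors computed from the generative moments — a
consistency band fixed by the model, not by the observed draws.

## Probe screening choices

The selection criteria are operationalised as: (i) length > 700 nt after
stripping a trailing A-run of ≥ 10 nt (the polyA rule is a package
operationalisation); (ii) paralogue distinctness fails when more than 5
of the gene's 20-nt windows (stride 5) have a ≥ 85% identity (≤ 3
mismatch) hit in a family member, either strand; (iii) at most 3
transcript variants; (iv) the longest region whose 20-mers occur in every
isoform must host ≥ 43 probes under the 20-nt/2-nt-gap left-greedy tiling
(≥ 944 nt). The off-target rule excludes a probe when its best ungapped
alignment to any non-target transcript has ≤ 3 of 20 mismatches: the
published phrasing ("more than 3 out of 20 mismatches were excluded")
reads inverted relative to its purpose — off-target risk comes from *few*
mismatches — and the implemented rule follows the purpose. The scan is
exhaustive (C++ Hamming over every offset and both strands); no heuristic
seeding, so the oracle comparison is exact.

## Known limitations

* 2D counting undercounts under optical crowding (> ~100 mRNA/cell).
* The rolling-ball operator deviates deliberately from interactive
  implementations (exact morphology instead of paraboloid approximation);
  absolute background estimates can differ slightly even though the
  subtraction contract is identical.
* Volumes from area × slices × 0.2 µm are approximate prisms, inheriting
  the original method's bias for non-prismatic cells.
* The supplementary measurement table of the original study is consumed
  through `run_reproduce()`'s column mapping; the package ships no copy of
  it, and its statistics are validated here on the synthetic study table.
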