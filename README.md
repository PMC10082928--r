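# ramfish

Quantitative single-molecule RNA FISH (smFISH) analysis for Arabidopsis root
apical meristem (RAM) cells.

smFISH tiles ~43–48 fluorescent 20-nt oligos along one mRNA so that each
transcript appears as a single diffraction-limited (~250 nm) spot in a
widefield z-stack. Counting those spots per manually outlined cell gives
absolute transcript numbers, and — because counts scale with cell size —
per-volume concentrations that can calibrate quantitative imaging against
reference (housekeeping) genes. `ramfish` implements that whole
quantification chain as tested R code, for microscopists and plant molecular
biologists who want reproducible spot counts instead of interactive
point-and-click measurement:

* **Image operations** — maximum z-projection; rolling-ball background
  subtraction implemented as grayscale opening with a spherical-cap element
  of radius *r* = 3 px; spot calling as regional maxima with topographic
  prominence ≥ 1700 grey values (prominence = peak height above the highest
  saddle to any higher maximum); 3×3-pixel (0.09 µm² at 100 nm pixels) spot
  ROI measurement; polygonal cell ROI statistics.
* **Per-cell quantification** — spot-to-cell assignment, cell volume
  *V = A · n<sub>z</sub> · 0.2 µm* from the projected area and z-extent,
  concentration *c = N / V* (mRNA µm⁻³), seeded spot-free background
  sampling (20 ROIs), and per-spot total corrected cellular fluorescence
  **TCCF = integrated density − area × mean background**.
* **Statistics** — group medians, Pearson count–volume correlation
  (`cor.test`), one-way ANOVA with Tukey HSD on TCCF (`aov` + `TukeyHSD`),
  relative label intensity (% of the brightest probe set), dual-dye
  co-localization by greedy one-to-one nearest-pair matching, and the
  no-probe false-detection rate.
* **Probe-set screening** — reference-gene criteria (length > 700 nt
  excluding polyA, paralogue distinctness, few isoforms, common-exon probe
  capacity ≥ 43), left-greedy 20-nt/2-nt-gap probe tiling, and off-target
  exclusion of probes with ≤ 3 mismatches anywhere else in a transcriptome
  (exhaustive ungapped Hamming scan, both strands).
* **Synthetic data** — a generator that renders study-like z-stacks (3D
  Gaussian spots, autofluorescent background, shot + read noise, 16-bit
  camera) and tabular six-group experiments with known ground truth, so the
  entire pipeline is testable without any raw microscopy downloads.

## Worked example

Simulate a small imaging experiment with known ground truth, run the full
quantification chain, and compare with the truth:

```r
library(ramfish)

cfg <- sim_config()                                   # study-like defaults
sim <- simulate_experiment(cfg, group = "MON1", n_cells = 4, seed = 42)
res <- quantify_experiment(sim, run_params(seed = 7))
res$cells
#>   cell_id   group spot_count area_um2 n_slices volume_um3 concentration_per_um3
#> 1 MON1_c001 MON1          38     385.       25      1925.                0.0197
#> 2 MON1_c002 MON1          25     178.       25       888.                0.0281
#> 3 MON1_c003 MON1          29     277.       25      1386.                0.0209
#> 4 MON1_c004 MON1          22     306.       25      1530.                0.0144

score_detection(res$spots, sim$truth)
#>   n_true n_detected n_matched recall precision
#> 1    115        114       114  0.991         1
```

Each row is one cell: the detected spot count, projected area, volume
(area × slices × 0.2 µm) and concentration in mRNA µm⁻³ — here ~0.02 µm⁻³,
the MON1-like design concentration. Detection recovers 99% of the true
spots with no false positives at a 2 px matching radius.

The tabular route reproduces the comparative statistics of a full
six-group reference experiment:

```r
tab <- generate_study_table(cfg, seed = 1)
run_reproduce(tab)
#> -- group summary --      (per group: n, median count, mean volume, ...)
#> 1 AP2M  93  35  1392.  0.0287
#> 2 MON1  93  26  1258.  0.0205
#> ...
#> -- relative TCCF --
#> 1 AP2M  3695  13609.  37.8
#> 2 MON1  2418  14403.  40.0
#> 3 NRPB1 3385  12202.  33.9
#> 4 PP2A  4541   9385.  26.0
#> 5 TIP41 2853  36032. 100
#> -- false detection (no-probe) --
#> 1 68 20 0.294 3.4
```

Median MON1 count 26 cells⁻¹, concentration ~0.021 µm⁻³, probe-set label
intensities 40/38/34/26% of the brightest set, and one spurious spot per
~3.4 no-probe cells — the study-like design centres of the generator.

`run_reproduce()` also accepts external per-cell/per-spot tables (CSV, TSV
or XLSX) with a `column_map` for foreign column names. A thin CLI with
`simulate` / `quantify` / `reproduce` / `probe-screen` subcommands lives at
`inst/cli/ramfish.R`.

## Layout

```
R/            implementation (image ops, quantify, stats, simulate,
              probe screen, pipeline, plots)
src/          C++ core: prominence maxima (union-find flood), Hamming scan
tests/        testthat suite incl. brute-force oracle comparisons
vignettes/    methods vignette (model, parameters, design decisions)
scripts/      acceptance.R (see above)
inst/cli/     command-line wrapper
```
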