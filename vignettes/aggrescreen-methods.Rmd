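---
title: "Methods: FRET aggregation screening analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: FRET aggregation screening analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aggrescreen)
```

# The assay and its analysis model

A FRET aggregation biosensor line expresses α-synuclein fused to a CFP
donor and a YFP acceptor. Seeding with pre-formed fibrils drives the fusion
proteins into shared inclusions; the resulting proximity produces
sensitized acceptor emission (FRET) that a flow cytometer detects per cell.
A screen plates the reporter line, pre-treats wells with library compounds
at several concentrations, induces aggregation everywhere except in
negative-control wells, and acquires an event table per well.

The analysis model is deliberately simple and robust:

1. **Gating.** Dead cells (viability dye) and non-reporter events (donor /
   acceptor double-positivity) are removed by rectangular thresholds. No
   gate geometry beyond rectangles is assumed.
2. **Scoring.** Each well is summarized by
   *normalized FRET = %FRET⁺ × FRET MFI*: the percentage of gated cells
   above the FRET-positivity threshold times the median fluorescence
   intensity of the FRET channel. The product rewards both more
   aggregate-bearing cells and brighter aggregates.
3. **Standardization.** Within each concentration tier the compound wells
   form the sample; scores become *z = (x − µ_sample)/σ_sample* with the
   sample SD (ddof = 1). Control wells are scored *against* this
   distribution without being part of it.
4. **Hit calling.** Inhibitors must reach *z ≤ −1.5* and exacerbators
   *z ≥ +1.5*; the default criterion demands this at **every** tier, which
   suppresses single-tier flukes; a single-tier mode exists for
   highest-dose-only calling.
5. **Quality control.** The Z'-factor
   *Z' = 1 − 3(σ_p + σ_n)/|µ_p − µ_n|* between vehicle (maximal induction)
   and negative-control (no induction) normalized-FRET bands, per
   replicate. This is the standard screening-window statistic: 1 only for
   zero-variance bands, negative when the bands overlap.

Because z-scores are invariant to positive affine transforms of the scores,
unit choices (percent vs fraction, MFI scale) cannot change hit calls.

## Design choices that were genuinely open

* **"MFI": median, over FRET-positive events.** Cytometry "MFI"
  conventionally denotes the median; computing it over the FRET-positive
  subpopulation makes the product read as "how many positive cells × how
  bright their aggregates are". Both choices are exposed
  (`fret_mfi(stat=, scope=)`); after z-scoring the hit list is insensitive
  to them in practice. A well with no positive events scores 0 (flagged),
  not an error, so negative controls flow through the screen.
* **Sample definition.** Control wells are excluded from µ and σ. This is
  what lets no-induction controls sit far *below* zero (they carry no FRET
  signal while the compound sample's mean is positive) instead of at z = 0,
  matching how such screens anchor their inhibitor threshold.
* **Control-anchored auto-gate.** The FRET-positivity threshold defaults to
  the 99.9th percentile of pooled negative-control events. The quantile
  was set from a bias budget: gate leakage inflates a well's positive
  fraction by roughly (1 − p) × (1 − quantile), and at 10,000 events per
  well the binomial SE of a strongly inhibited well (p ≈ 0.03) is ≈ 0.17
  percentage points, so leakage must stay an order of magnitude below the
  99.5th-percentile convention to keep fraction recovery unbiased.
* **Replicates.** z is computed per experimental replicate and averaged per
  compound (pooling first is available).

# Image quantification

Three pipelines, sharing one detection primitive:

* **Colocalization** is the Pearson correlation over all pixels of two
  registered channels (optionally masked); r and r² are both reported
  because co-staining results are conventionally quoted as R². Constant
  channels raise an undefined-correlation error rather than returning NaN.
* **Puncta detection**: Gaussian blur (σ = 1 px) → white top-hat with a
  disk of radius 5 px (removes structures larger than the disk, keeping
  puncta) → threshold at mean + 3 SD of the filtered image (adaptive to
  global offsets) → 8-connectivity labeling → area filter [4, 10 000] px².
  All parameters are exposed; the defaults are artifact choices, not
  measured values. **Touching-spot splitting:** thresholded footprints of
  diffraction-limited spots bridge surprisingly far apart — two Gaussian
  spots of width σ merge at centre distances of 4–5 σ — so by default
  touching components are split on the distance transform
  (`split_touching = TRUE`); disabling it yields the plain
  blur/top-hat/threshold/label pipeline.
* **TFEB translocation**: nuclei are segmented from the DAPI channel by
  global Otsu thresholding, hole filling, a distance-transform watershed to
  split touching nuclei, and a 50 px² minimum-area filter. Each cell's
  cytosol is a 5 px annulus around its nucleus, excluding all nuclei, with
  contested pixels assigned to the nearest nucleus. The readout is the
  per-cell nuclear/cytosolic mean-intensity ratio, aggregated as an
  arithmetic mean across cells (per-cell first, not pooled pixels, so large
  cells do not dominate). Cells with zero cytosolic signal are excluded
  and flagged.
* **Puncta area fraction** (galectin-3-type readouts): total detected
  puncta area inside a cell mask divided by the mask area.

Coordinates are 0-based (row, col); areas are px² — no physical
calibration is attempted.

# Omics stage

LFQ intensities are log2-transformed and each sample is centred on its
median over observed values (missing values are never imputed; all
statistics are pairwise-complete). Fold changes are differences of group
means on the normalized scale. The altered set of a treatment is
{flagged significant} ∩ {|log2FC| ≥ 0.5}, boundary inclusive. Overlap
between two altered sets is reported Venn-style, 100·|∩|/|∪|, with the
per-set fractions |∩|/|A| and |∩|/|B| attached since both conventions
appear in figure legends. Sample clustering is average linkage on
1 − Pearson over fold-change profiles — a declared artifact choice where
only "unsupervised clustering" is specified upstream.

Significance flags are expected from the user's statistical environment;
the built-in stand-in (per-feature Welch t-test, Benjamini–Hochberg at
0.05) exists so synthetic data can exercise the set machinery. At three
replicates it is deliberately conservative: with log2 effects comparable
to the noise SD it has little power, which is a property of the test, not
a defect of the pipeline — recovery tests therefore use high planted
effects (effect/noise ≥ 10).

# What the generators emulate — and what they do not

* **Plates** (`simulate_plate`): each well is a two-component mixture of
  FRET-negative and FRET-positive cells with log-normal channel
  intensities — the standard working model for cytometry fluorescence.
  Positive cells raise the FRET channel and lower the donor channel
  (sensitized emission with donor quenching). The default design follows
  the screening setup: 80 compounds, three dose tiers (2, 4, 10 µM labels),
  10,000 events per well, a 30% aggregate-bearing baseline in induced
  wells, 2% dead cells. Compound action is a multiplicative effect on the
  positive fraction. *Not emulated*: spectral overlap/compensation,
  doublets, acquisition drift, plate-position effects.
* **Images** (`simulate_image`): disk nuclei placed by rejection sampling
  (max 1000 retries, then an informative error), Gaussian or hard-disk
  puncta with a minimum separation (default 4 spot widths), Gaussian pixel
  noise, a colocalization channel built as
  ρ·z(aggregates) + √(1−ρ²)·noise with the noise orthogonalized against
  the aggregate channel so the sample correlation equals ρ up to floating
  point, and a TFEB-like channel whose nuclear pixels sit at `nc_ratio`
  times the cytosolic level. Disk spots have exact pixel-area ground truth;
  Gaussian spot truth areas are the pixels within 2σ. *Not emulated*:
  point-spread blurring of nuclei, uneven illumination, 3-D structure,
  photobleaching.
* **Omics** (`simulate_omics`): per-feature baseline log2 intensities,
  i.i.d. Gaussian noise, planted feature sets with controllable pairwise
  overlap carrying group-specific log2 shifts; shared planted features
  shift in a common direction so related treatments correlate. *Not
  emulated*: missingness mechanisms, intensity-dependent variance,
  peptide-to-protein rollup.

Passing recovery tests on these generators demonstrates that the
*computations* are correct and well-calibrated under their stated model;
it does not certify performance on real data whose artifacts (spectral
spillover, illumination fields, MS missingness) the generators exclude.

All generator randomness flows from one top-level seed; independent
streams are derived per well/image/matrix with a documented Lehmer-step
splitting rule (`split_seed`), so enlarging a design never perturbs
existing wells.

## The synthetic reference screen

`synthetic_reference_screen()` builds an 80-compound kinase-library score
table whose analysis reproduces known summary behaviour of such screens:
four named inhibitors beyond the threshold at every tier, five named
exacerbators (one dose-flat at mean z 4.49), null compounds inside ±1.5,
and no-induction controls whose mean z against the compound sample is
−1.88. It is constructed, not measured: target z-vectors are standardized
exactly (the null scores are a shuffled uniform grid affinely adjusted so
the 80-compound vector has mean 0 and sd 1, which provably keeps nulls
inside the threshold band), and scores are x = µ + σz with µ/σ = 1.88 so a
zero-aggregation score maps to z = −1.88. It exists to exercise parsing,
standardization and hit calling end-to-end with known answers.

# Numerical conventions and degenerate inputs

* Constant score vectors raise a degenerate-distribution error in
  `zscores`; equal control means make `z_prime` undefined (error).
* `normalize_lfq` errors on samples with fewer than two observed values;
  it is idempotent on already-normalized data to 1e-12.
* Empty event tables gate to empty with a warning; an empty gated well
  makes the positive fraction undefined (error), while a well with gated
  events but no positive ones scores 0 with a flag.
* Waterfall ties are broken alphabetically by compound id; missing tiers in
  hit calling raise an error naming the offending compounds.
* 16-bit TIFF round-trips losslessly on the 0..65535 integer grid; PNG is
  an 8-bit convenience format (values quantized to multiples of 257).
* Event tables are read from CSV. FCS parsing is out of scope for this
  package; export the four channels (donor, acceptor, fret, viability) to
  CSV from the acquisition software or an FCS-capable toolkit first.

# Problem sizes used by the test suite

The suite favours many medium-sized seeded replicates over few large ones:
flow recovery runs 20 plates of 30 compounds × 3 tiers at 10,000 events per
well; mixture calibration uses one 10⁵-event well; imaging recovery uses 50
seeded 128×128 images (SNR 50 at the default amplitude/noise settings) and
5 replicates each for translocation and area-fraction recovery; omics
properties use 400–4000 features with 3 replicates per group and 20 seeds
for the clustering separation rate. These sizes give the binomial and
Gaussian error budgets quoted in the tests while keeping a full run around
a minute.

# Known limitations

* Rectangular gates only; no compensation, doublet discrimination, or FRET
  efficiency computation (the readout is intensity-based by design).
* No plate-position (B-score/median-polish) correction and no dose-response
  curve fitting — screens with three fixed tiers are ranked, not fitted.
* Segmentation is classical (Otsu + watershed); densely packed or highly
  non-circular nuclei will need external masks, which every function
  accepts.
* The Welch/BH significance stand-in is for synthetic data; real
  differential analyses should supply their own flags.
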