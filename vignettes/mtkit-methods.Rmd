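---
title: "Quantifying microtubule-dependent transport, streaming, and tubulin glutamylation with mtkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying microtubule-dependent transport, streaming, and tubulin glutamylation with mtkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtkit)
```

mtkit quantifies four microtubule-dependent read-outs that are commonly
scored together when studying tubulin glutamylation in *Drosophila*:
organelle transport in wing-nerve axons, ooplasmic streaming in stage
10B (S10B) oocytes, alpha-tubulin C-terminal glutamylation from mass
spectrometry, and the localization of posterior determinants and motors
in oocyte images.  Each analysis has a matching seeded generator that
produces synthetic inputs with known ground truth, so every stage of
the pipeline is testable without microscopy or MS data.

This vignette explains the models, the parameters that matter, and the
design decisions behind the defaults.

## Run/pause segmentation and transport metrics

A trajectory is a time-ordered series of positions (µm) at a uniform
frame interval (default 2 s, i.e. 0.5 frames/s over 3 min, a standard
acquisition for mitochondria in wing neurons).  The instant speed of
each inter-frame interval is the Euclidean displacement divided by the
frame interval — matching what manual-tracking tools export, rather
than a path-projected coordinate.

Segmentation applies three rules, in order:

1. **Run window** (`detect_run_window()`): the run starts at the first
   interval whose speed reaches `v_pause` (default 0.2 µm/s) and ends
   at the last such interval.  Leading and trailing stationary tails
   are excluded from the run time.  A track that never reaches the
   threshold is "never motile" and excluded upstream.
2. **Labels** (`segment_run()`): within the window, an interval is a
   *pause* iff its speed is strictly below `v_pause`; a speed exactly
   at the threshold counts as transported, because the pause is defined
   as movement *below* the cutoff.  Maximal stretches of at least
   `min_pause_frames` (default 1) consecutive pause intervals form
   pause events.
3. **Motility filter** (`is_motile()`): a track is motile iff its total
   transport distance strictly exceeds `d_min_motile` (default 2 µm).
   The ordering window → segment → filter is deliberate and
   configurable in one place (`pipeline_config()`); the alternative
   (filtering before window detection) changes nothing for tracks with
   a single run but is ambiguous for tracks that creep below threshold
   throughout.

`compute_metrics()` then reports the five standard statistics: run
length (summed transport displacement), run time (pause + transport
time), total run velocity (run length / run time), transport velocity
(mean instant speed of transported intervals), pausing time ratio, and
pausing frequency (pause events per µm of run length).  The
decomposition `run_time = pausing_time_total + transporting_time` is
exact by construction.

Directionality (`assign_direction()`) uses the net displacement
projected on a user-supplied anterograde axis, with a ±0.5 µm ambiguity
band; tracks that reverse abruptly are classified by their net
displacement rather than split, since per-particle direction classes
are the standard unit of reporting.

`compare_groups()` provides Student's t-test (equal variances — the
classical form) and the Mann–Whitney test, exact when the smaller
group has at most 8 observations and no ties; means are reported with
SEM = sd/√n.

### What the trajectory generator emulates

`simulate_trajectories()` draws a two-state Markov chain per interval:
transport → pause with probability `p_pause_per_frame` (default 0.1),
pause → transport with `p_resume_per_frame` (default 0.5), giving a
stationary pause probability `p/(p+q)` = 1/6 and an expected pausing
frequency of `p_pause / (v̄·Δt)` pauses per µm.  Motion is 1-D along
the axonal coordinate, embedded in the plane; all reported metrics are
path-length based, so nothing is lost by the 1-D core.  Transport
speeds are N(0.5, 0.1) µm/s per interval (negative draws redrawn);
pauses have zero drift, so displacement during a pause is pure
localization noise (default SD 0.03 µm, typical of centroid fitting on
fluorescent spots).  That choice makes the error rate of the 0.2 µm/s
rule analytically computable: a pause interval's apparent speed is
|N(0, σ√2)|/Δt ≈ 0.02 µm/s — far below threshold — while a transport
interval misclassifies only when its drawn speed falls below 0.2 µm/s
(0.13 % at the defaults).  The generator does not emulate
photobleaching, drift, out-of-focus excursions, or speed
autocorrelation within a transport stretch, so passing round-trip tests
demonstrates correctness of the estimator, not robustness to every
imaging artifact.

## Ooplasmic streaming

Streaming movies (bright-field-like, one frame every 2 s for 2 min)
are analyzed in two complementary ways.

**Kymographs** (`build_kymograph()`): intensity sampled at 1-px
arc-length steps along a polyline (typically drawn near the posterior
cortex), averaging a configurable number of normal offsets with
bilinear interpolation.  Moving vesicles appear as sloped streaks;
`cortical_unidirectionality()` scores the fraction of gradient mass
voting for the dominant slope sign (≈1 for unidirectional cortical
flow, ≈0.5 for balanced counter-movement), using the identity that for
a conserved moving pattern the product of the spatial and temporal
gradients has the opposite sign of the streak slope.

**Flow fields** (`estimate_flow()`): the field is divided into square
patches (16 px, step 12 px); for sampled frame pairs separated by
`frame_lag` frames (default 3, i.e. 6 s — chosen so that typical
streaming displacements are a few pixels, above the integer-pixel
quantum but inside the ±8 px search), the patch displacement is the
argmax of the normalized cross-correlation.  Patches with correlation
peaks below 0.3 carry no reliable texture and are dropped.  This makes
the visual flow reading quantitative without particle linking, which
is impractical in dense vesicle fields.

`fit_rotation_center()` finds the center minimizing the radial energy
fraction of the vectors (grid search plus Nelder–Mead refinement) and
reports the tangential coherence
κ = |mean((v·t̂)/|v|)| about it: 1 for a perfect unidirectional
rotation, ~1/√n for random directions.  Two details matter:

* Patches retained with **zero displacement** (static texture)
  contribute 0 to κ rather than being dropped.  A frozen region is
  evidence of *no* coherent flow; dropping those vectors would make a
  field with a dead posterior look perfectly coherent.
* A region with fewer than `min_vectors` (default 5) usable vectors
  counts as having no coherent flow (coherence 0), not as missing
  data.

`classify_streaming()` is a deterministic surrogate for expert visual
scoring of the four published pattern classes.  With the AP axis along
image columns:

* **circular** iff whole-field κ ≥ 0.6 *and* posterior-window
  (posterior 40 % of the AP extent) coherence ≥ 0.3 —
  **central** if the fitted center lies at AP fraction ≥ 0.4,
  **anterior-biased** otherwise;
* otherwise **abnormal** — **partial** if the anterior part still
  rotates coherently on its own fitted center (κ ≥ 0.6) while the
  posterior does not (< 0.3), else **chaotic**.

The posterior-coherence condition on the circular call is load-bearing:
when coherent flow is confined to the anterior 60 % of the field,
exactly ~60 % of the vectors agree with one rotation sense, so the
whole-field κ sits right at the 0.6 cutoff and a single-threshold rule
would flip a coin on partially disrupted oocytes.  Requiring the
posterior window to stream as well separates the two cases cleanly.
All thresholds are explicit, configurable constants validated on
synthetic ground truth (the classifier benchmark in the test suite runs
200 seeded movies, 50 per pattern, at the default noise level and
requires ≥ 95 % accuracy; it currently classifies them all correctly).

The movie generator advects vesicles by exact rigid rotation (circular
patterns), by frozen random per-patch directions with boundary
reflection (disordered), or by rotation with coherent flow zeroed in
the posterior 40 % (partial), plus an isotropic velocity noise; spots
are rendered as σ = 2 px Gaussians, matching a diffraction-limited
appearance at the default 1 µm/px scale of the scaled-down field
(80×110 px).  Defaults (0.012 rad/s, so ~0.36 µm/s at 30 µm radius)
are in the range of fast S10B streaming.  The generator does not
emulate intensity inhomogeneity, z-drift, or the slow pre-S10B seethe.

Percentages (`summarize_patterns()`) pool the two circular and the two
abnormal subtypes and round half-up, which reproduces every printed
proportion checked (e.g. 12/17 → 71, 16/21 → 76, 1/24 → 4).

## C-terminal glutamylation from PSM tables

The counting unit is the peptide-spectrum match (PSM).  Only peptides
containing the **entire primary C-terminal tail** enter the totals:
isotype assignment (`assign_isotype()`) is a suffix match against the
tail model — the Tyr-terminal tail `...GEGEGAEEY` (positions 442–450,
with modifiable glutamates E443, E445 in the -GEGEG- context and
E448/E449 in -GAEEY) for the pooled general isotypes, whose tryptic
C-terminal peptides are identical, and a Phe-terminal tail for the
ovarian-specific isotype.  The packaged 67C default tail is a synthetic
stand-in carrying the defining terminal Phe; replace it with the true
sequence when matching real search-engine output.

`sidechain_length()` decomposes each modification mass delta into an
integer number of glutamyl residues (n × 129.04259 Da, the standard
monoisotopic glutamyl residue mass) within a tolerance of 0.01 Da per
added Glu.  Deltas of +57.021464 Da are flagged *ambiguous* and never
counted: the routine cysteine-alkylation step can modify glutamates
with exactly the nominal mass change of glycylation, so this mass
cannot be attributed.  Unknown deltas warn and leave the record with
the length of its resolvable modifications.

`summarize_glutamylation()` reports, per genotype × isotype, the counts
at sidechain lengths 1E/2E/3E (and >3E) and their frequencies as
percentages of the total PSM count, rounded half-up; the total modified
frequency is recomputed from the raw counts, never from the rounded
per-category percentages.  Counts are canonical throughout — stored
percentages never drive downstream arithmetic.  `isotype_ratio()`
reports the plain ratio of isotype totals to one decimal; note that on
the published totals (58/12) this gives 4.8, while the printed
expression-matched ratio is 4.6 — the basis of the printed value is
unstated, and the function does not force it.  A single modified PSM in
an otherwise unmodified genotype is reported as is (4 % for 1/24);
whether it is contamination is a biological judgment the pipeline never
makes.

The PSM generator has an **exact-counts mode** in which category counts
are assigned (n·p must be integral) instead of drawn multinomially;
this reproduces printed count tables exactly and is how the packaged
fixture encodes the published wild-type column (58 = 17 + 29 + 8 + 4,
printing as 50/14/7/71 %).  The 29/8/4 split is the unique integer
triple of 58 consistent with those rounded percentages (verified by
exhaustive search in the tests).

## Oocyte image quantification

All measurements run on a single-plane image with user-supplied
geometry: a cortex polyline and an anterior→posterior axis line with a
pixel size.

* **Crescent length** (`measure_crescent_length()`): background is the
  median intensity of a thin band along the cortex; the crescent is
  the longest contiguous arc (circularly, if the cortex is closed)
  whose background-subtracted intensity reaches half of the peak
  (threshold fraction 0.5).  A half-max rule was chosen because the
  boundary criterion of the published measurements is unstated and a
  scale-free contrast rule validates cleanly on synthetic ground truth
  (exact recovery at low noise; invariant to resampling the same scene
  at 2× resolution).  A shorter crescent means tighter posterior
  localization.
* **AP profile** (`ap_profile()`): mean of `line_width` (default 50 px,
  the "50 units" of the interactive tool that inspired it) bilinear
  samples across the axis at 1-px steps.
* **Inner peaks** (`detect_inner_peaks()`): local maxima of the lightly
  smoothed profile, excluding a 10 % margin at each end, with
  prominence ≥ 20 % of the interior dynamic range *and* ≥ 8× the
  profile noise scale (MAD of successive differences).  The absolute
  noise floor exists because on a flat profile the dynamic range *is*
  noise, and a purely relative rule would hallucinate peaks.  One peak
  anterior of AP 0.5 is `single_anterior`, otherwise `single_central`;
  two or more are `double_peak`.
* **Posterior enrichment** (`call_posterior_enrichment()`): a
  deterministic surrogate for two-person blind scoring — `TRUE` iff the
  mean intensity of the posterior cortical band (15 % of the cortex
  arc around the posterior pole, dilated 5 px inward) is ≥ 1.3× the
  mean of the rest of the oocyte mask.  Both constants are exposed.

The oocyte generator renders an elliptical oocyte (default 200×260 px
at 0.5 µm/px, i.e. a ~110 µm long oocyte), a boxcar crescent as a
Gaussian ridge (transverse σ = 2 px) over an arc of configured length,
and inner peaks as Gaussians on the AP axis.  Oocyte physical
dimensions per stage are not asserted anywhere — they are configurable,
and absolute crescent lengths are validated only against synthetic
truth, since no numeric crescent lengths are published.

## Reproducibility and problem sizes

All randomness flows from per-generator integer seeds; fixed seeds give
bit-identical outputs, and `run_pipeline()` writes every parameter it
used to `run_log.json`.  The packaged demo (`generate_fixtures()`)
contains the exact-counts PSM table, 20 trajectories, 4 movies (one per
pattern), and 6 oocyte images.

The validation suite uses desk-scale problem sizes chosen to keep the
full run in minutes while leaving comfortable statistical margins: 500
tracks for the stationary-distribution check (3 SE), 200 tracks per
cohort for parameter recovery (10 % bands), 200 movies for the
classifier benchmark, and the exhaustive 4⁶ speed-sequence enumeration
against a brute-force reference implementation.  Absolute in-vivo
magnitudes (wing-nerve metric values, crescent lengths in µm, raw MS
re-searches) have no deposited desk-scale inputs; for those the
package's evidence is parameter recovery, oracle equivalence, and
determinism — properties the tests compute, not figures they assert.

## Known limitations

* Flow displacements are integer pixels (no subpixel refinement); slow
  flows need a larger `frame_lag`.
* The streaming classifier assumes the AP axis runs along image
  columns; rotate inputs accordingly.
* Bidirectional transport tracks are classified by net displacement,
  not split into directional segments.
* State inference is threshold-based, as in the published procedure; no
  HMM smoothing is attempted.
* Automatic cortex/oocyte segmentation is out of scope — geometry is an
  input.
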