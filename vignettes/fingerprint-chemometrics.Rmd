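---
title: "Fingerprint chemometrics: species discrimination and antioxidant marker assignment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fingerprint chemometrics: species discrimination and antioxidant marker assignment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The analysis

`fingerchem` implements a complete chemometric workflow for HPLC-DAD
chromatographic fingerprints of medicinal-plant extracts. A fingerprint here
is the *entire* detector trace over a fixed retention-time window, used as a
holistic signature of a sample rather than a list of integrated peaks. The
workflow answers two questions about a two-species collection of extracts:

1. **Can the species be told apart from their fingerprints alone?**
   Pearson-correlation distances between traces, Ward clustering, and two
   validation statistics: the cophenetic correlation coefficient (CCC,
   dendrogram faithfulness) and the Hopkins statistic (clustering tendency).
2. **Which chromatographic peaks track antioxidant activity?** A composite
   relative antioxidant capacity index (RACI) summarising four in-vitro
   assays is regressed on the full fingerprint with latent-variable models
   (PLS and OPLS); retention regions with positive regression coefficients
   are candidate antioxidant markers, identified by matching against
   injected phenolic standards.

Because no raw chromatograms are deposited for this kind of study, the
package ships a synthetic-data generator that reproduces the statistical
structure the analysis assumes, with full ground truth, so every stage can
be tested as a parameter-recovery problem.

## The data model

A chromatogram set is a tibble with one row per injection: metadata columns
(`sample_id`, `species`, `extract_id`, `replicate`, `wavelength_nm`,
`blank`) and two list-columns (`time_min`, `absorbance`). All user-facing
functions take and return these tibbles (or small S3 result objects with
`tidy()`/`glance()`/`autoplot()` methods), so stages chain with the pipe.

The retention grid is uniform: the analysis window spans 13.2 to 64.5 min
and contains exactly 7696 absorbance measurements. Only the window endpoints
and the point count are fixed by the method; this implies a 0.4 s sampling
interval (2.5 Hz) with inclusive endpoints, which is what `make_time_grid()`
uses. The simulated run covers 10--66 min so that window cropping is a real
operation.

## The synthetic-data generator

`simulate_dataset()` renders, per wavelength (254, 280, 330 nm):

* a **peak library** of Gaussian peaks: 12 shared between species (equal
  amplitudes), 10 specific to each species (zero amplitude in the other),
  and 3 *active* peaks whose amplitudes drive the latent antioxidant level.
  Active peaks elute in the 20--35 min region where the phenolic standards
  (tannic acid, chlorogenic acid, vitexin) are found; the first is shared
  (vitexin-like, present in both species), the others belong to the
  high-activity species.
* **chromatograms** for 2 species x 20 extracts x duplicate injections
  (80 per wavelength): peak sum x extract-level lognormal amplitude factors
  (sd 0.2 on the log scale) x a per-injection scale factor (sd 0.01, log
  scale), plus a drifting baseline (slow sine + quadratic, amplitude 0.05 AU
  = 5% of the typical peak height, emulating mobile-phase composition
  changes and stationary-phase bleed) and i.i.d. detector noise
  (sd 0.005 AU). Duplicates share all extract-level factors and differ only
  in noise, drift phase and the injection factor — this is what makes the
  duplicate-correlation gate (r > 0.93) pass by construction.
* one **blank** per wavelength (drift + noise only),
* a four-assay **antioxidant panel**: each of total polyphenols (mg GAE/g
  DW), DPPH, ABTS, FRAP (mg TE/g DW) is a method-specific affine map of the
  latent activity plus Gaussian noise at 10% of the latent's spread,
* a **standards table** naming the active peaks at their true retentions,
* the **ground truth** (latent activity per extract, active peak ids,
  species effect) for parameter-recovery tests.

The latent activity is the unit-weighted sum of active-peak amplitudes after
the extract-level factors — the simplest ground truth that marker assignment
can recover. All draws derive from one master seed through fixed stream ids,
so identical configurations give byte-identical datasets and
`simulate_truth()` can reproduce the latent activity without rendering a
single trace.

**Calibration.** The generator's defaults are calibrated once against the
reference behaviour of real two-species fingerprint collections: duplicate
injections correlate above 0.93; the species clusters are tight enough that
the Ward dendrogram's CCC exceeds 0.968 and the Hopkins statistic stays at
or below 0.17. The number of species-specific peaks (10 per species) is the
knob that sets the between- to within-species distance ratio; with only 6,
within-species amplitude variability (the lognormal sd 0.2, which we regard
as fixed — it is what makes extracts genuinely different) left the Hopkins
median near 0.2.

**What the generator does not emulate:** retention-time drift between runs
(the workflow deliberately performs *no* peak alignment, so the simulator
keeps retention exact), detector saturation, co-elution shape distortion,
gradient-dependent peak widths, and between-batch effects. Passing tests
therefore certify the *analysis chain*, not robustness to misaligned or
saturated real-world data.

## Preprocessing

```{r}
library(fingerchem)
ds <- simulate_dataset(sim_config(seed = 1))
fm <- preprocess_dataset(ds, wavelength_nm = 280)
```

The pipeline is: blank subtraction (pointwise, negatives retained so
correlations stay unbiased) → replicate-correlation gate (minimum pairwise
Pearson r per extract; failures *warn* and are reported, never silently
dropped, and no alignment is attempted in either case) → consolidation into
per-extract mean chromatograms (the pointwise median across a species is
available separately via `group_median()` as a visual summary) → baseline
correction → cropping to 13.2--64.5 min → the 40 x 7696 fingerprint matrix.

**Baseline estimation** (`estimate_baseline()`) is an iterative peak-filling
scheme: after a light moving-average smooth (half-window 0.2 min), the trace
is repeatedly replaced by the pointwise minimum of itself and its
moving-window *opening* (running minimum followed by running maximum), with
window half-widths shrinking geometrically from 2.0 min; a final moving
average gives the baseline. The opening formulation keeps the estimator
exactly idempotent on noiseless input and free of the under-peak inflation
that plain moving-average suppression produces. Defaults (half-window
2.0 min, 8 iterations, smoothing 0.2 min) are chosen so that a 0.1-min-sigma
peak is untouched while 5-min-scale drift is removed. Corrected traces are
*not* clipped at zero.

Baseline correction runs before cropping: the estimator then sees the full
run and the crop cannot bite into its support. The reverse order is possible
and differs only near the window edges — the package tests assert this as a
documented difference, not an equivalence.

## Similarity and cluster validation

```{r}
v <- validate_clustering(fm, sqrt_dist = TRUE, k = 2)
v$ccc; v$hopkins
cut_clusters(v$tree, k = 2)
```

Distances are `1 - r` (Pearson) between full traces. Before Ward linkage the
square-root transform is applied — it compresses large distances, improving
dendrogram legibility, without changing any ordering. Linkage follows the
`ward.D2` convention (inputs treated as distances, objective on their
squares); the CCC is computed against the matrix actually clustered, i.e.
the transformed one.

The Hopkins statistic is computed on 2-dimensional PCA scores, not on the
raw 7696-dimensional rows: sampling uniform reference points in a bounding
box is meaningless in very high dimension. The orientation follows the
convention in which values *near zero* indicate clusterable structure
(`H = sum(w) / (sum(w) + sum(u))` with `w` the real-point nearest-neighbour
distances); structure-free data give H around 0.5. `m = max(5, floor(0.1 n))`
points are sampled without replacement.

## The antioxidant index

Each assay column is z-scored (sample sd, n - 1 denominator; the method is
not specified more precisely in the underlying protocols, and the choice
only rescales, never reorders). The RACI is the row mean of the z-matrix;
the PC1 variant takes scores on the first right-singular vector of the
z-matrix (unit norm, oriented to a positive loading sum). When the four
assays share one latent activity — as they do here by construction and,
empirically, in real panels — the correlation matrix is nearly
equicorrelated, the first eigenvector approaches (0.5, 0.5, 0.5, 0.5), and
the two variants agree to R^2 above 0.999. Both are invariant to affine
rescaling of any raw assay column.

`fit_calibration()`/`to_equivalents()` cover the assay calibration step
(OLS line of response on the standard series, inversion to mg equivalents
per g dry weight); plate-reader mechanics and assay chemistry are out of
scope.

## Latent-variable regression and markers

```{r}
idx <- antioxidant_index(ds$assay_panel)
y <- idx$samples$raci_mean[match(fm$sample_ids, idx$samples$sample_id)]
model <- fit_pls(fm, y, n_components = 2)
cv <- loo_cv(fm, y, method = "pls", n_components = 2)
fit_metrics(model, fm, y, cv)
markers <- match_standards(find_marker_intervals(model), ds$standards)
tidy(markers)
```

PLS1 is implemented as NIPALS with deterministic initialisation from `X'y`
(no random starts; for a scalar response the inner loop converges
immediately, and a 500-iteration cap at tolerance 1e-12 guards the general
scheme). Coefficients on the original centred predictors come from the
closed form `B = W (P'W)^{-1} q`, which reproduces the sequential NIPALS
predictions exactly. X is mean-centred but not variance-scaled — standard
for chromatographic profiles, where column variance carries signal;
`scale_mode = "autoscale"` is available.

OPLS peels y-orthogonal variation out of X (weight direction
`p - (w'p) w`, deflation by the orthogonal component, then a one-component
PLS on the filtered matrix). Its orthogonal scores are exactly uncorrelated
with y, and OPLS with 1 predictive + k orthogonal components predicts
identically to PLS with k + 1 components — both facts are asserted in the
test suite. Requesting zero orthogonal components returns the one-component
PLS fit. Default component counts are 2 latent variables for PLS and
1 + 1 for OPLS.

Cross-validation is leave-one-out with re-centring inside every fold;
`Q^2 = 1 - PRESS/TSS` with TSS about the full-data mean. Metrics report both
MSE and RMSE explicitly (labels in this literature are occasionally
ambiguous between the two), plus `RPD = sd(y)/RMSE` for calibration and CV;
a numerically perfect fit reports `Inf`.

Marker intervals are maximal runs where the coefficient exceeds
`0.1 * max(B)` — only *positive* coefficients, since peaks that grow with
the RACI are the antioxidant candidates — at least 0.1 min wide (narrower
runs are noise ripples, not chromatographic peaks). No numeric rule exists
in the underlying methodology ("analytically significant" coefficients);
these two thresholds are the package's own, deliberately permissive choice,
and both are tunable. Standards match an interval when their retention lies
within 0.5 min of the apex at the report's wavelength; unmatched intervals
are retained, since un-identified markers are a legitimate finding.

Because the high-activity species also carries species-specific *inactive*
peaks, those peaks correlate with the RACI through group membership and can
show positive coefficients too. This confounding is faithful to the real
situation (species identity and activity are correlated by design); the
recovery guarantee asserted in the tests is therefore that planted active
peaks are found and that every reported interval sits on a genuine peak —
not that inactive peaks never appear.

## Orchestration

`run_pipeline()` chains every stage at 280 and 330 nm (254 nm is recorded
metadata only, as in the reference workflow) from a YAML/JSON config or
nested list, in simulation mode or on external CSV data in the documented
dialect, and returns a machine-readable report (optionally written as JSON +
CSV). A panel with no antioxidant signal at all (possible when no active
peaks are simulated) skips the index/regression stages and reports empty
markers rather than failing. The gradient-program helpers
(`reference_gradient()`, `total_runtime()`, `composition_at()`) carry the
instrument method metadata: 110 min total runtime including 15 min
re-equilibration.

## Problem sizes and numerical choices

The test suite and the acceptance script run the full default design
(80 chromatograms per wavelength, 40 x 7696 fingerprint matrices); Monte
Carlo assertions use 20--100 seeds for panel-level quantities, 50 seeds for
the single-wavelength marker-recovery sweep, and 10 seeds where each
repetition involves a full leave-one-out loop. These sizes keep every
property estimate stable at the asserted tolerances.

Other numerical choices: grid divisibility is checked to 1e-6 steps and
uniformity to 1e-9 min; distance matrices are symmetrised and their
diagonals zeroed exactly; agglomeration ties are broken by `stats::hclust`'s
deterministic ordering; z-scoring refuses constant columns instead of
emitting NaN; SVD sign ambiguity in the PC1 index is resolved by the
positive-loading-sum convention.

## Limitations

* No retention-time warping or peak alignment is available anywhere — by
  design, mirroring the reference workflow, which found replicate
  correlations above 0.93 made alignment unnecessary. Data that need
  alignment must be aligned upstream.
* PLS/OPLS are single-response (PLS1); multi-response PLS2, VIP scores and
  permutation tests are out of scope.
* The marker rule is coefficient-sign-and-threshold only; it does not
  deconvolve co-eluting peaks and inherits the species/activity confounding
  discussed above.
* Hypothesis testing for the species contrast is intentionally omitted
  (only direction and magnitude are reported); any standard test applies
  downstream.
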