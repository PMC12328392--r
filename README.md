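# fingerchem

Chemometric analysis of HPLC-DAD chromatographic fingerprints: species
discrimination of medicinal-plant extracts and assignment of the
chromatographic peaks responsible for antioxidant activity.

## The problem

Closely related medicinal plants are often used interchangeably although
their chemistry — and hence their pharmacology — differs. When two species
of one genus must be told apart without reference compounds for every
metabolite, the *whole chromatogram* can serve as a fingerprint: a holistic
signature compared across samples rather than a list of quantified peaks.
`fingerchem` is for analysts who have (or want to prototype against)
HPLC-DAD fingerprints of a two-species extract collection together with an
in-vitro antioxidant panel, and who want a reproducible, tested pipeline
from raw traces to species clusters and candidate bioactive peaks.

## The methods

* **Preprocessing**: blank subtraction, a duplicate-injection
  reproducibility gate (minimum pairwise Pearson *r* per extract, threshold
  0.93), consolidation into per-extract mean chromatograms, iterative
  fill-peaks baseline correction (moving-window opening with geometrically
  shrinking windows), cropping to the 13.2–64.5 min analysis window
  (7696 points at 0.4 s sampling).
* **Similarity / clustering**: Pearson correlation distance
  *D*ᵢⱼ = 1 − *r*(xᵢ, xⱼ), optional element-wise square-root transform, Ward
  linkage (`ward.D2` convention), validated by the cophenetic correlation
  coefficient (CCC) and the Hopkins clustering-tendency statistic
  (near-zero-is-clusterable orientation, computed on 2-D PCA scores).
* **Antioxidant index**: the RACI — the mean of per-assay z-scores over
  {total polyphenols, DPPH, ABTS, FRAP} — and its first-principal-component
  variant (scores on the leading right-singular vector of the z-matrix,
  loadings oriented positive).
* **Latent-variable regression**: from-scratch NIPALS-PLS1 and OPLS
  (orthogonal-variation filtering, scores exactly uncorrelated with the
  response), leave-one-out cross-validation, R²X/R²Y, MSE/RMSE,
  RPD = sd(y)/RMSE, and Q² = 1 − PRESS/TSS.
* **Marker assignment**: maximal runs of positive regression coefficients
  above 0.1·max(B), at least 0.1 min wide, matched to a standards
  retention-time table within 0.5 min.
* **Synthetic data**: a seeded generator (Gaussian peak libraries with
  shared/species-specific/active peaks, lognormal extract variability,
  drifting baselines, duplicate injections, assay panels driven by a latent
  activity) with full ground truth for parameter-recovery testing.

The methods vignette (`vignettes/fingerprint-chemometrics.Rmd`) documents
the model assumptions, defaults and design choices in detail.

## Worked example

```r
library(fingerchem)

ds <- simulate_dataset(sim_config(seed = 1))
ds
#> <sim_dataset> 240 chromatograms (3 wavelengths), 3 blanks, 40 assay samples

fm <- preprocess_dataset(ds, wavelength_nm = 280)
fm
#> <fingerprint_matrix> 40 samples x 7696 timepoints at 280 nm (13.2-64.5 min)

validate_clustering(fm, sqrt_dist = TRUE, k = 2)
#> <cluster_validation> 280 nm: CCC = 0.995, Hopkins = 0.139, k = 2 clusters

idx <- antioxidant_index(ds$assay_panel)
idx
#> <antioxidant_index> 40 samples; PC1 loadings: tp_mg_gae_g 0.50,
#>   dpph_mg_te_g 0.50, abts_mg_te_g 0.50, frap_mg_te_g 0.50;
#>   R^2(mean, PC1) = 1.0000

y <- idx$samples$raci_mean[match(fm$sample_ids, idx$samples$sample_id)]
model <- fit_pls(fm, y, n_components = 2)
glance(model)
#> # A tibble: 1 x 8
#>   kind  n_components n_orthogonal r2x_total   r2y mse_cal rmsec rpd_cal
#>   <chr>        <int>        <int>     <dbl> <dbl>   <dbl> <dbl>   <dbl>
#> 1 pls              2            0     0.898 0.986  0.0140 0.118    8.42

markers <- match_standards(find_marker_intervals(model), ds$standards)
tidy(markers)
#> # A tibble: 9 x 6
#>   start_min end_min apex_min peak_coefficient compound         delta_min
#> 1      18.3    18.7     18.4          0.00943 <NA>              NA
#> 2      23.7    24.1     23.9          0.0172  tannic acid        0.00296
#> 3      32.5    33.0     32.8          0.0346  <NA>              NA
#> 4      33.5    34.0     33.8          0.0197  chlorogenic acid   0.0103
#> ...
```

Reading the output: the dendrogram reproduces the correlation-distance
structure almost perfectly (CCC 0.995) and the data are strongly
clusterable (Hopkins 0.139, near-zero convention); the two-cluster cut
separates the species exactly. The four assay loadings are equal to two
decimals, so the PC1 index and the plain z-mean RACI are interchangeable
(R² = 1.000). A two-latent-variable PLS calibrates the RACI on the 280 nm
fingerprints with RPD 8.4, and the marker scan flags the planted active
peaks, two of which match the injected standards (tannic and chlorogenic
acid at 280 nm; the 32.8 min peak matches vitexin in the 330 nm report).

The end-to-end orchestration (`run_pipeline()`) runs simulate → preprocess
→ cluster → index → model → markers at 280 and 330 nm from a YAML/JSON
config, in simulation mode or on external CSV data, and writes a
machine-readable report.

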