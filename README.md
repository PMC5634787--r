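# sacflux

Quantitative analysis of fluid absorption and expression dynamics in the
developing endolymphatic sac.

The embryonic endolymphatic sac (ES) absorbs endolymph from the inner ear;
when absorption fails, the sac and duct enlarge — the soft-tissue correlate
of the enlarged vestibular aqueduct seen in childhood sensorineural hearing
loss.  `sacflux` is for researchers quantifying this system in organ
culture and expression data.  It implements:

- **3D voxel volumetry** of a dye-filled lumen: width-5 mean filtering,
  global (Otsu or manual) thresholding, largest 26-connected component,
  exact voxel counting (one 3 µm voxel = 27 µm³ = 2.7×10⁻⁵ nl).
- **Absorption kinetics**: the absorption rate is the slope of the linear
  portion of the volume-time curve (longest prefix window with R² ≥ 0.98),
  normalized to the luminal surface area of the first image,
  reported in nl·hr⁻¹·mm⁻².
- **Surface geometry**: the lumen is modelled as two spherical caps
  enclosing a conical frustum,

  S = π(a₁² + h₁²) + π(a₁ + a₂)·√((a₁ − a₂)² + L²) + π(a₂² + h₂²),

  with the linear dimensions (a₁, a₂, h₁, h₂, L) measured from the
  segmented mask by principal-axis analysis and a 10%/90% axial split.
- **Group statistics**: Grubbs single-outlier screen, Shapiro–Wilk,
  one-way ANOVA with all-pairwise Bonferroni t-tests, Cohen's d
  (pooled SD).
- **Single-cell expression workflow**: median-of-ratios normalization
  (nTPM), the nTPM < 1 → 0 log2 rule, variable-gene filter (nTPM > 1 in
  > 2 cells, CV > 0.5), PCA, top-300 PC-correlated genes, Ward
  hierarchical clustering, rank-based differential expression gated by
  FDR < 0.05, detection > 50% and Jensen–Shannon specificity > 0.5,
  Fisher enrichment, and single-cell qPCR conversion
  (log₂ expression = 28 − Ct).
- **Array time course**: quantile normalization, probe retention filters,
  per-probe OLS on [1, t, t², g, g·t, g·t²] with separate BH-corrected
  global and genotype F-tests, temporal-profile clustering with the
  smallest-number gene-resolution rule, and relative qPCR quantification
  (efficiency = 10^(−1/slope)).
- **Synthetic-data generators** with known ground truth for all three
  data types (image time series, genes × cells matrices, probes × samples
  designs), used throughout the test suite.

## Worked example

Simulate one heterozygote-like sac shrinking at 12.3 nl·hr⁻¹·mm⁻² and
recover the rate from the rendered images alone:

```r
library(sacflux)

geom <- make_sac_geometry(rng_seed = 7)
sim  <- simulate_timecourse(geom, noise_model(seed = 11), rate_norm = 12.3)
rec  <- quantify_timecourse(sim$stacks)
rec
#> sac_record: 5 timepoints, surface 0.03134 mm^2
#>   volumes (nl): 0.4678, 0.3887, 0.3112, 0.2345, 0.1549
#>   normalized rate: 12.446 nl/hr/mm^2
```

The five volumes are the voxel counts of each segmented stack converted
to nanoliters; the surface (0.0313 mm²) comes from the caps-plus-frustum
model measured on the first image; the normalized rate (12.45) recovers
the planted 12.3 within a few percent.  Group-level comparison:

```r
het  <- simulate_rate_group(12.3, 2.6, 26, seed = 1)   # printed sample moments
homo <- simulate_rate_group(6.0, 1.6, 12, seed = 2)
one_way_anova_bonferroni(list(het = het, homo = homo))
#> One-way ANOVA with Bonferroni pairwise t-tests
#>   group  n mean  sd shapiro_p
#> 1   het 26 12.3 2.6   0.08059
#> 2  homo 12  6.0 1.6   0.90020
#> F(1, 36) = 59.5, p = 3.891e-09
#>   group_i group_j     t     raw_p bonferroni_p cohens_d
#> 1     het    homo 7.714 3.891e-09    3.891e-09    2.692
cohens_d(c(12.6, 2.7, 6), c(8.1, 1.5, 11), summary = TRUE)
#> [1] 2.269948
```

The last number reproduces the published gadolinium effect size (2.2)
from the printed summary statistics, within rounding of the inputs.

## Command-line interface

A thin CLI over the same functions lives at `inst/cli/sacflux.R`:

```sh
Rscript inst/cli/sacflux.R simulate sacs --seed 1 --out out/
Rscript inst/cli/sacflux.R quantify --stack out/t01.tif --threshold otsu --out q.json
Rscript inst/cli/sacflux.R rates --in out/ --out rates.tsv
```

Stacks are 16-bit multi-page TIFFs with JSON sidecars (voxel size,
acquisition time); matrices are TSV with ID columns.

See the methods vignette (`vignettes/sacflux-methods.Rmd`) for the model
assumptions, parameter defaults, numerical choices, and known
limitations.
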