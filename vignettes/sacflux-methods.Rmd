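---
title: "Quantifying fluid absorption and expression dynamics in the developing endolymphatic sac"
author: "sacflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying fluid absorption and expression dynamics in the developing endolymphatic sac}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sacflux)
```

# Scope

The embryonic endolymphatic sac absorbs endolymph; failure of that
absorption enlarges the sac and duct and is the earliest structural
correlate of the enlarged-vestibular-aqueduct phenotype.  `sacflux`
implements the quantitative machinery used to study this system:

1. **3D voxel volumetry** of a dye-filled lumen imaged by confocal
   microscopy: smoothing, threshold segmentation, voxel counting, and
   conversion to nanoliters.
2. **Absorption kinetics**: the luminal volume trajectory over repeated
   (semi-hourly) imaging, the slope of its linear portion, and the rate
   normalized to an estimated luminal surface area
   (nl·hr^-1^·mm^-2^).
3. **Surface geometry**: the lumen is modelled as two spherical caps
   enclosing a conical frustum, and its absorptive surface area is
   estimated from simple linear dimensions of the segmented mask.
4. **Group statistics**: Grubbs outlier screen, Shapiro-Wilk, one-way
   ANOVA with all-pairwise Bonferroni t-tests, Cohen's d.
5. A **single-cell expression workflow** (gene-level summation,
   median-of-ratios normalization, the nTPM &lt; 1 zeroing rule,
   variable-gene filtering, PCA, selection of component-correlated genes,
   hierarchical clustering, rank-based differential expression gated by
   detection and specificity criteria, Fisher enrichment, and the
   single-cell qPCR conversion log~2~ expression = LOD − Ct with LOD at
   28 cycles).
6. A **time-course array analysis** (quantile normalization, probe
   retention filters, per-probe regression on time, time², genotype and
   their interactions, FDR selection, temporal-profile clustering with
   the smallest-number gene-resolution rule) and relative qPCR
   quantification (efficiency = 10^−1/slope^).

Every analysis is exercised on synthetic data with known ground truth;
the generators are first-class, tested package functions.

# The lumen model and volumetry

## Geometry

A `sac_geometry` is a conical frustum (end radii $r_1$, $r_2$, axial
length $L$, all in µm) closed by spherical caps of heights $h_1$, $h_2$
whose base circles coincide with the frustum ends.  Its volume and
surface are analytic:

$$V = \tfrac{\pi h_1}{6}(3r_1^2+h_1^2) + \tfrac{\pi L}{3}(r_1^2+r_1 r_2+r_2^2) + \tfrac{\pi h_2}{6}(3r_2^2+h_2^2)$$

$$S = \pi(r_1^2+h_1^2) + \pi(r_1+r_2)\sqrt{(r_1-r_2)^2+L^2} + \pi(r_2^2+h_2^2)$$

The cap term $\pi(a^2+h^2)$ equals the zone formula $2\pi R h$ with
sphere radius $R=(a^2+h^2)/2h$, and degenerates to the flat disk
$\pi a^2$ at $h=0$.  These closed forms are the oracles for every
voxel-level estimate.

## Rendering and segmentation

Stacks use `(z, y, x)` axis order with isotropic 3 µm voxels (27 µm³ =
2.7×10⁻⁵ nl per voxel); voxel centers sit on the grid
$(i-1)\cdot\text{voxel\_size}$.  Rendering uses a **voxel-center
membership test** without partial-volume weighting: the simplest rule,
whose bias is quantified against the analytic volumes (below 2% for
radii of five voxels and above).  Intensities are additive Gaussian
around a background and a lumen mean, clipped at zero — sufficient for
threshold-based segmentation; Poisson photon statistics are out of
scope.

Segmentation mirrors the acquisition-software workflow: a width-5 3D
mean (box) filter (the vendor software documents only "smooth, xyz: 5";
a single-width box filter is the most conservative reading), a global
intensity threshold (automatic Otsu on the 256-bin histogram by
default, manual override available, where the original analysis set
thresholds per image by hand), and retention of the largest
26-connected component, which rejects salt noise.  Between two
well-separated intensity modes the Otsu criterion plateaus, so any
threshold inside the gap classifies identically; the implementation
returns the left edge of the plateau.

## Linear dimensions and the surface estimate

The absorptive surface is estimated from the first image of an
experiment.  `measure_linear_dimensions()` finds the principal axis of
the mask by second-moment analysis, takes the axial extent (plus half a
voxel per end), and splits it at the 10%/90% axial positions: the
central 80% is the frustum, the ends are the caps.  The end radii are
equivalent-circle radii $\sqrt{A/\pi}$ of the cross sections at the
split planes, where the cross-section area is interpolated between
one-voxel-thick layer counts.  Two numerical details matter:

* **Junction sampling.**  The radius is sampled one voxel layer to the
  frustum side of each split plane.  At the junction itself the cap
  curves away steeply (slope $(R-h)/a$, typically &gt; 1), so a
  half-voxel positional error costs more than a voxel of radius; on the
  frustum side the taper is gentle and its small effect cancels between
  the two ends.
* **Cap fraction as a prior.**  The 10% split matches elongated sacs
  with shallow rounded ends.  Strongly bulging shapes need a larger
  fraction: a sphere measured at the default split underestimates its
  surface by about a third, because a straight frustum chord cannot
  follow the bulge; at `cap_fraction = 0.25` the error drops inside
  10%.  The fraction is an explicit parameter, and the package's
  default synthetic geometry draws caps near 10% of the axial extent so
  the estimator's prior matches the shape family it measures — a
  deliberate coupling, stated here as a limitation for real data whose
  cap proportions are unknown.

Volumes are reported from exact integer voxel counts (1 nl = 10⁶ µm³);
surfaces in mm² (1 mm² = 10⁶ µm²).

# Absorption kinetics

The true synthetic trajectory is linear until a floor:
$V(t) = \max(V_0 - r_{\text{norm}} S_0 t,\; 0.05\,V_0)$, with the
geometry rescaled isotropically about its centroid to match each
volume (the source data show shrinkage without shape annotation, so
isotropy is an assumption, not an observation).  Default imaging times
are 0–0.8 hr in 0.2-hr steps: the synthetic sacs are miniaturized to a
64³ stack, so the volume-to-surface ratio — and with it the time to
empty — is smaller than in the original organ cultures; the default
grid keeps at least three timepoints inside the linear phase at the
fastest observed rates.

The **linear portion** is found by an explicit rule (the source
describes only "the linear portion" of the volume-time graph): among
contiguous windows starting at the first timepoint with at least three
points, the longest window whose least-squares fit has $R^2 \ge 0.98$
is used; if none qualifies, the best length-3 window.  Prefix windows
reflect that absorption slows as the lumen empties.  The rate is
$\max(-\text{slope}, 0)$, normalized by the first image's surface.

## Group scenarios

`absorption_scenarios()` encodes the five study conditions
(heterozygote control 12.3 ± 2.6 nl·hr^-1^·mm^-2^, n = 26; homozygous
mutant 6.0 ± 1.6, n = 12; ouabain 5.3 ± 1.8, n = 7; gadolinium control
12.6 ± 2.7, n = 6; gadolinium 8.1 ± 1.5, n = 11).
`simulate_rate_group()` draws normal deviates and standardizes the
sample to the printed mean and SD exactly: the published numbers are
*observed sample statistics*, so the synthetic cohort reproduces them
as such, and any deviation of the recovered group mean isolates
measurement error of the imaging pipeline rather than draw noise.  The
recovered group means land within one standard error of each
condition's mean, which is the package's parameter-recovery criterion.

## Statistics

`one_way_anova_bonferroni()` reproduces the reporting chain: optional
per-group single-pass two-sided Grubbs screen at α = 0.05 (the original
analysis removed exactly one outlier; iterated screening is behind a
flag), Shapiro-Wilk per group (a normality failure is reported, never
fatal — matching how the results were presented), the ANOVA F-test, and
pairwise t-tests that share the pooled within-group variance (the ANOVA
mean square), Bonferroni-multiplied by the number of pairs and capped
at 1.  Cohen's d uses the $(n-1)$-weighted pooled SD; computed from the
printed gadolinium summaries it gives 2.27, matching the published 2.2
within rounding of the inputs.  For two groups the ANOVA F equals the
squared pooled t statistic, which the tests verify numerically.

# Single-cell workflow

The synthetic expression generator plants two differentiated classes
(optionally a proliferating subset) in a TPM-like genes × cells matrix:
lognormal baselines, disjoint marker sets multiplied by a fold change
in their class, per-cell lognormal scale factors, and Bernoulli dropout
*independent of expression level* — the simplest mechanism that
produces the detection-fraction structure the calling criteria use.
Defaults (100 cells at 45:55 class proportions, 50 markers per class at
fold 8, 10% dropout) emulate the scale of the real 82-cell, two-class
data set.  What the generator does **not** emulate: expression-dependent
dropout, batch effects, doublets, or count noise; passing tests
demonstrate correctness of the chain, not robustness to those
artefacts.

Processing follows the published order: transcript-level values are
summed per gene; median-of-ratios size factors normalize cells (nTPM);
values below 1 are zeroed and the rest log2-transformed; genes
expressed (nTPM &gt; 1) in more than two cells with cell-to-cell CV
above 0.5 enter PCA.  All quoted thresholds are strict inequalities,
read literally.  The CV is computed on nTPM across all cells including
zeros (the source does not say; including zeros favours bimodal,
marker-like genes) with the sample SD.  Under heavy dropout no gene may
be non-zero in every cell, in which case the strict median-of-ratios is
undefined; `size_factors(..., pseudocount = 1)` is the documented
fallback.  Note the factors are not exactly scale-equivariant: scaling
one of $n$ cells by $c$ scales its factor by $c^{1-1/n}$, because the
per-gene geometric means absorb $c^{1/n}$.

Genes are standardized before PCA and each component is oriented so its
largest-magnitude loading is positive, making score signs reproducible.
The 300 most positively and 300 most negatively PC1-correlated genes
(ties broken lexicographically) feed hierarchical clustering of cells
(Euclidean distance, Ward linkage) cut at *k* = 2; genes cluster by
correlation distance with average linkage for display.

Differential expression uses a two-sided rank-sum test between two
clusters (Kruskal-Wallis beyond two) — the original custom scripts
built on a censored-regression likelihood whose settings are not
published, so a distribution-free test is used and isolated behind the
function interface.  A gene is called for the cluster with the highest
specificity only when all three criteria hold strictly: BH
FDR &lt; 0.05, detection (share of the cluster's cells with
nTPM &gt; 1) above 50%, and specificity above 0.5 (0.65 for four-group
comparisons).  The specificity of a gene for cluster $c$ is
$1-\sqrt{\mathrm{JSD}(p, e_c)}$ with base-2 logarithms, where $p$ is
the gene's cluster-mean profile normalized to a probability vector and
$e_c$ the indicator profile: 1 means expression confined to $c$, 0
confined elsewhere, and a gene uniform across two clusters scores
$1-\sqrt{0.3113}\approx0.442$ — below the call threshold, which is what
protects precision under the null.  Enrichment of a called set against
an annotation table uses the one-sided hypergeometric tail with fold
enrichment relative to a reference universe (e.g. the 22,320-gene mouse
reference) and Bonferroni correction; no ontology database ships with
the package.

Cell-level quality screening in the original study used a vendor tool;
the package documents a simple replacement (drop cells whose median
correlation to the cohort is more than 3 MAD below the cohort median),
off by default and not part of the tested chain.

# Array time course and qPCR

The synthetic array design is 4 ages (E13.5–E17.5) × 2 genotypes × 3
replicates on a log2 intensity scale; probes are null, time-responsive,
or genotype-by-time-responsive, with Gaussian noise (default SD 0.25
log2 units) and all present flags true.  Quantile normalization
delegates to the same implementation the original analysis used, with
tie handling that assigns tied values the mean of their ranks' values.
Probe retention follows the published two-part rule — present calls in
all required replicates and a mean-intensity sum at or above 600
(inclusive), 150 for the cross-platform subset.

Each probe's model is ordinary least squares on
$[1, t, t^2, g, g\,t, g\,t^2]$ with time centered at its mean (to
decorrelate the linear and quadratic terms; coefficients are reported
on the centered basis) and genotype coded 0/1.  Significance uses two
F-tests — all non-intercept terms against the intercept, and the three
genotype-involving terms against the time-only model — each
BH-corrected separately at FDR 0.05, yielding the two published
categories: probes significant for genotype (and time) and probes
significant for time only.  The original analysis used a two-step
stepwise selection package whose tuning is unpublished; transparent
F-tests replace it behind the same selection interface.  Noise-free
signals are recovered to ≤ 10⁻⁸ absolute coefficient error, and
null p-values are uniform (KS &lt; 0.05 at 2,000 probes).

Profile clustering standardizes each retained probe's mean
(genotype × time) profile, clusters hierarchically (Euclidean, Ward),
cuts at *k*, and renumbers clusters 1..k by decreasing size so that the
published gene-resolution rule — a gene whose probes fall in several
clusters goes to the *smallest-numbered* one — is deterministic and
independent of probe order.

qPCR quantification implements efficiency $=10^{-1/\text{slope}}$ from
the standard-curve slope (warning outside the plausible (1, 2.2]
range) and the relative ratio
$E_\text{target}^{\Delta Ct_\text{target}} / E_\text{ref}^{\Delta Ct_\text{ref}}$
with ΔCt fixed as calibrator − sample, so higher expression than the
calibrator gives a ratio above 1.

# Numerical choices and problem sizes

* Digitized-solid oracles place the solid center generically off the
  voxel lattice: centring exactly on the half-voxel lattice aligns
  boundary voxel centers with the analytic surface and inflates counts
  (about +3% for an 8-voxel-radius cylinder), while generic placement
  is unbiased.
* RNG: every generator consumes a private stream seeded explicitly and
  restores the caller's RNG state; identical seeds give identical
  output and no global state leaks.
* Test and verification sizes are chosen to exercise the statistics at
  meaningful power on a single CPU: 64³ stacks × 5 timepoints for the
  62 sacs of the five absorption conditions; 800–2,000 genes × 40–100
  cells for the expression chains; 400–2,000 probes × 24 samples for
  the array chains; 20 seeded replicates for FDR-calibration checks.

# Known limitations

* The cap/frustum split fraction is a shape prior; real sacs with
  unknown cap proportions inherit its bias (quantified at up to −30%
  of surface for a sphere at the default split).
* Dropout independent of expression level makes normalization harder
  than in data where dropout spares high expressors; conversely there
  are no batch effects, so clustering recovery here is an upper bound.
* The rank-sum DE test and the F-test selection are transparent
  replacements for unpublished custom procedures; counts from the
  original deposited data sets (cell-specific gene counts, significant
  probe counts) are out of scope by design.
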