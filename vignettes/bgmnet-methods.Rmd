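---
title: "Methods: tripartite brain-gut-metabolite association networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tripartite brain-gut-metabolite association networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The analysis

`bgmnet` implements a tripartite association analysis linking three data
blocks measured on the same subjects:

1. **Microbiome block** — fecal levels of three microbially derived
   tryptophan metabolites: indole, skatole (3-methylindole) and
   indoleacetic acid (IAA). These are positive, strongly right-skewed
   abundances.
2. **Clinical block** — body mass index (BMI), Yale Food Addiction Scale
   score (YFAS, integer 0–7) and the anxiety subscale of the Hospital
   Anxiety and Depression scale (ANX, integer 0–21).
3. **Brain block** — graph-centrality metrics of subject-level functional
   and anatomical connectomes, restricted to twelve extended-reward regions
   of interest: nucleus accumbens (NAcc), amygdala (Amg) and four
   anterior-insula substructures (short insular gyrus, anterior segment of
   the circular sulcus, horizontal and vertical rami of the anterior segment
   of the lateral sulcus), per hemisphere.

Every cross-block variable pair is tested with a covariate-adjusted Spearman
correlation; within-block pairs are never tested. Significant pairs become
edges of a tripartite network from which metabolite effects on clinical
variables are classified as *direct* (shared edge) or *indirect*
(linked only through a brain-metric neighbor).

## Connectome construction

**Parcellation.** The brain is divided into 165 regions: 74 cortical
structures per hemisphere, 7 subcortical structures per hemisphere, one
cerebellum per hemisphere, and a midline brain stem. Only the twelve ROI
labels are anatomically meaningful in this package; the remaining labels
are placeholders, since centralities are reported for the ROIs only.

**Functional networks.** For each subject, pairwise Pearson correlations of
the region-level signals are Fisher z-transformed (`atanh`). Connections
are retained where `z > 0.3` — strictly, so a tie at the threshold is
removed — and the retained z-magnitude is the edge weight. Negative
correlations can never survive a positive threshold and are therefore
excluded by construction. Correlations are clipped to ±(1 − 1e−12) before
`atanh` so that duplicated signals yield finite weights. Thresholding in z
is equivalent to thresholding `r > tanh(0.3) ≈ 0.2913`.

**Anatomical networks.** Edge weights are the absolute fiber count divided
by the volumes of the two interconnected regions. "Divided by the volumes
of the two regions" admits several readings; the default divides by the
*sum* of the two volumes, the common streamline-density convention. The
product and mean conventions are selectable via `anat_norm` for sensitivity
analyses. Weights scale as 1/c when all volumes are scaled by c.

## Centrality metrics

Two indices are computed per ROI, per modality, on the **whole** network
(not the ROI-induced subgraph), because the centralities are meant to
quantify each region's role in whole-brain integration:

* **Degree strength** `S` — the weighted degree, i.e. the sum of incident
  edge weights. The phrase "number of regions a region interacts with"
  is sometimes used loosely for this index; the standard network-
  neuroscience definition of strength is the weighted sum, which is what we
  compute (a binary degree would be obtainable by thresholding weights to
  0/1 upstream).
* **Betweenness centrality** `B` — for node v, the sum over unordered pairs
  (s, t), both ≠ v, of the fraction of shortest s–t paths passing through
  v. Edge distance decreases with connection weight: `d = 1/w` by default,
  with `d = −log w` selectable for weights < 1 (the tool chains used for
  such analyses do not document their transform, so it is left
  configurable). Betweenness is unnormalized, endpoints are excluded,
  tied shortest paths share credit fractionally (Brandes convention), and
  floating-point path-length ties are compared with tolerance 1e−9. The
  production implementation is a compiled Dijkstra/Brandes accumulation on
  the dense distance matrix; an exhaustive path-enumeration oracle
  (`brute_force_betweenness()`, ≤ 9 nodes) provides an independent check,
  and the test suite verifies equality on hundreds of random graphs plus
  every connected 4-node graph over a small weight grid.

Variable labels follow the reporting scheme `metric_hemisphere_region`,
e.g. `B_R_NAcc` (betweenness, right nucleus accumbens) or `S_L_Amg`
(strength, left amygdala).

## Association model

`partial_spearman(x, y, covariates)` performs a rank-scale partial
correlation controlling for age and sex:

1. select pairwise-complete subjects (x, y and all covariates observed);
2. average-rank transform x, y and each covariate;
3. residualize ranked x and ranked y on an intercept plus the ranked
   covariates by least squares;
4. r is the Pearson correlation of the residuals; the two-sided p-value
   uses `t = r sqrt(df / (1 − r²))` with `df = n − 2 − k`.

Constant or collinear covariates are dropped via the QR rank, so with
constant covariates the estimate equals the plain Spearman correlation
exactly. Sex enters as a numeric 0/1 code. Pairs whose ranks are degenerate
(zero variance) are excluded with a log message rather than reported.

Because case selection is pairwise-complete, sample sizes vary by row:
YFAS pairs use the 42 completers; anatomical metrics lose the one excluded
scan (n = 62); functional pairs use all 63. Two degrees-of-freedom columns
are emitted: `df_test = n − 2 − k` (the t-test's df) and
`df_printed = n − 1` (a reporting convention seen in published tables of
this kind, which cannot be the partial-test df; emitting both avoids silent
disagreement).

**Multiple testing.** Benjamini–Hochberg q-values are attached within
families. The default family partition is one family per block pair ×
modality (five families: metabolite~functional, metabolite~anatomical,
clinical~functional, clinical~anatomical, metabolite~clinical), because in
published tables of this design q is non-monotone in p across sub-blocks,
implying correction within sub-families. The partition is configurable
(`pooled`, `block_pair`, `source_variable`) since the exact partition used
in any given report is generally not recoverable from its text. The
global-null calibration experiment (below) runs with the `pooled` family:
under a global null, BH's false-discovery rate equals the probability of
any rejection, so the any-discovery rate of a *single* family is bounded by
alpha, whereas a union over five families need not be.

## Network assembly and effect classification

Two thresholded networks are first-class outputs, mirroring the dual
conventions used for such analyses: the *significant* network (q < 0.05)
and the *visualization* network (p < 0.05). Each edge keeps r, p, q and a
tier flag. Reference rows printed as bounds ("p < .050") are stored as the
bound plus a flag and pass a `p < .05` threshold.

The reported subnetwork keeps the metabolites, their first neighbors, and
*all adjacent edges*: every edge with at least one endpoint among the
retained nodes, together with its other endpoint. This deliberately keeps
clinical–brain edges hanging off a metabolite's brain neighbors — they are
exactly the length-2 paths that carry indirect effects.

For each metabolite × clinical pair, `classify_effects()` reports an
exclusive status — `direct` if they share an edge, `indirect` if not but at
least one brain-metric node is adjacent to both, else `none` — *and* the
full list of brain mediators adjacent to both endpoints. Mediators are
reported even for direct pairs, because a pair can be directly associated
and brain-mediated at once (e.g. a metabolite–YFAS pair with a direct edge
plus a shared NAcc neighbor); restricting mediators to indirect pairs
would hide half of that structure. Mediation here is purely topological —
no causal or statistical mediation model is implied.

## The synthetic cohort generator

All validation runs on synthetic cohorts; no subject-level data from any
real study is used or shipped. Defaults emulate the reference study
conditions: 63 subjects (29 M / 34 F), ages 18–60 (mean 29.42, SD 10.76),
BMI mean 25.82 SD 4.93, YFAS mean 1.24 SD 1.25 with 42 completers (the
missing 21 assigned deterministically to the last subject ids so pairwise
sample sizes are reproducible), HAD anxiety mean 4.25 SD 3.41, log-normal
metabolite marginals, 165 regions, 243 time points (8 min 6 s at TR = 2 s;
configurable since real scan lengths vary), and one excluded anatomical
scan.

**Latent factor.** One shared standard-normal factor L per subject induces
all planted cross-block correlations: a variable with loading ρ is
`ρ L + sqrt(1 − ρ²) ε` on the latent scale, then mapped to its marginal
(exponentiation for metabolites; affine for BMI; rounding + truncation for
scores). A planted pair (a, b, ρ) receives loadings `sqrt(|ρ|)` on each
side, so its latent correlation is ρ. This is the simplest mechanism that
produces a tripartite correlation structure; it cannot represent two
planted effects that share a variable with inconsistent implied loadings
(such specs are rejected), and all planted variables are mutually
correlated through L.

**Score marginals.** Naively rounding and clipping a normal to the
instrument range distorts the SD of low-mean scores like YFAS by ~13%.
The generator therefore moment-calibrates the latent mean/SD (closed-form
moments of the discretized normal, matched by deterministic optimization)
so the *post*-rounding marginals hit the requested mean/SD; the ±10%
marginal checks in the test suite then pass by construction of the model,
not by loose tolerances.

**Imaging stage.** Time series are multivariate normal with a cohort-level
baseline correlation matrix (off-diagonals uniform on a configurable range,
repaired to the nearest positive semi-definite correlation matrix by
eigenvalue clipping at 1e−8 and diagonal renormalization). Each subject's
matrix adds (i) a per-subject perturbation (SD 0.1) representing
inter-individual connectome variability and (ii) any planted shifts
`β L` on designated pairs, clipped into (−0.99, 0.99), with PSD repair.
Fiber counts are independent Poisson draws per unordered pair with
cohort-level log-normal intensities, per-subject log-normal jitter
(SD 0.5) and planted multiplicative effects `exp(γ L)`. The subject-level
variability is what makes every ROI's centrality a genuine random variable
across the cohort; without it, peripheral nodes have identically zero
betweenness for every subject and their association tests are undefined.
Even with it, roughly 1% of null cohorts contain one structurally-zero
betweenness variable, which is then dropped through the documented
zero-variance exclusion.

**Block-level simulation.** Planting a correlation at the connectivity
level and reading it out through graph metrics attenuates it nonlinearly,
so effect-recovery calibration uses `simulate_blocks()`: brain-metric
variables drawn directly from L with log-normal marginals. Note that a
planted ρ is a latent-scale Pearson correlation; the population *Spearman*
correlation of a ρ = 0.6 Gaussian copula is `(6/π) asin(ρ/2) ≈ 0.582`, so
rank-based estimates recover ≈ 0.58, not 0.60 — the calibration tolerance
accounts for this.

**What the generator does not emulate:** raw MRI volumes, motion or
physiological noise, preprocessing pipelines, tractography biases,
mass-spectrometry peak processing, zero-inflation of betweenness marginals
in the block-level simulator, or realistic spatial correlation structure
among brain metrics. Passing tests therefore validate the *statistical
machinery* under a known generative model, not the upstream imaging
science.

## Numerical choices

* Fisher-z clipping at ±(1 − 1e−12); strict `z > 0.3` retention.
* PSD repair: eigenvalue floor 1e−8, then renormalization to unit
  diagonal; Cholesky factors take an additional 1e−10 ridge.
* Betweenness tie tolerance 1e−9 in both the compiled implementation and
  the enumeration oracle, so mathematical ties classified identically.
* Average ranks for ties throughout the association stage; two-sided
  p-values; q capped at 1.
* Results tables sort by family, q, p, then |r| descending.
* One user seed is expanded into per-stage, per-subject child streams
  (integer congruential map below 2^31), so any stage can be regenerated
  in isolation and outputs are byte-identical for identical (config, seed).

## Validation problem sizes

The simulation experiments in the test suite and acceptance script use
cohorts of 63 subjects at a reduced parcellation of 20 regions (the 12
ROIs, 7 placeholder cortical regions, brain stem), which preserves the full
297-test association design while keeping whole-suite runtimes in minutes:
500 null cohorts for error-control calibration in the tests (200 in the
acceptance script), 200 planted-effect replicates (100 in the script), 500
random graphs plus an exhaustive 4-node sweep for the betweenness oracle,
and 100 random datasets for the partial-correlation oracle.

## Limitations

* The tripartite edges are cross-sectional associations; direct/indirect
  classification is graph topology, not causal mediation.
* The latent single-factor generator is a deliberately minimal model of
  cross-block dependence.
* The FDR family partition of any published table of this design is
  ambiguous; conclusions that depend on the partition should be checked
  under the alternatives provided.
* Betweenness on thresholded functional networks can be exactly zero for
  weakly connected regions; such degenerate variables are excluded from
  testing rather than imputed.
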