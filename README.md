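# bgmnet — tripartite brain–gut-metabolite association networks

`bgmnet` is an R package for integrating three data blocks measured on the
same cohort — fecal microbial metabolites, clinical/behavioral scores, and
graph metrics of subject-level brain connectomes — into a single tripartite
association network. It targets gut–brain-axis studies in which microbially
derived tryptophan metabolites (indole, skatole, indoleacetic acid) are
related to the connectivity of the brain's extended reward network (nucleus
accumbens, amygdala, anterior insula) and to measures such as BMI, food
addiction (YFAS) and anxiety (HAD).

The pipeline:

1. **Connectomes.** Functional: Fisher z-transformed Pearson correlations of
   region-level signals, thresholded at `z > 0.3` (weight = z magnitude).
   Anatomical: fiber counts normalized by the volume sum of the two
   connected regions. 165-region parcellation, 12 reward ROIs.
2. **Centralities.** Degree strength `S_i = Σ_j w_ij` and weighted
   shortest-path betweenness (edge distance `1/w`, Brandes accumulation,
   unnormalized) per ROI, computed on the whole network.
3. **Associations.** Partial Spearman correlations controlling for age and
   sex — ranks, least-squares residualization, Pearson on residuals, t-test
   with `df = n − 2 − k` — over every cross-block pair, pairwise-complete,
   with Benjamini–Hochberg q-values within configurable families.
4. **Network.** Significant pairs become edges of a typed tripartite graph;
   metabolite effects on clinical variables are classified *direct* (shared
   edge) or *indirect* (connected only through a brain-metric neighbor),
   with the mediating regions reported.

A latent-factor cohort simulator with plantable cross-block correlations
makes the whole pipeline testable end to end, and a bundled reference
association table from a published 63-subject cohort supports structural
reproduction checks. See `vignettes/bgmnet-methods.Rmd` for the model
details and design decisions.

## Worked example

Simulate a 63-subject cohort with one planted association (indole ~ degree
strength of the right nucleus accumbens, functional, latent ρ = 0.6) and
fit the tripartite model:

```r
library(bgmnet)

sp  <- cohort_spec(seed = 42, n_regions = 20,
                   effects = list(list(a = "Indole", b = "S_R_NAcc.func",
                                       rho = 0.6)))
fit <- tripartite(simulate_blocks(sp))
fit
#> Tripartite brain-gut-metabolite association fit
#>   63 subjects, 297 cross-block tests (families: block_pair_modality)
#>   significant: 1 at q < 0.05, 16 at p < 0.05
#>   strongest associations:
#>     Indole   ~ S_R_NAcc       r = +0.631  p = 5.111e-08  q = 3.68e-06
#>     YFAS     ~ S_R_Amg        r = -0.422  p = 0.006661  q = 0.3658
#>     ...
```

The planted pair is the only q < 0.05 discovery; its estimated partial
Spearman (+0.63 here) fluctuates around the rank-scale value of a ρ = 0.6
Gaussian copula, `(6/π)·asin(0.3) ≈ 0.58`. The remaining 296 tests are null
and behave accordingly.

The bundled reference table reproduces the published effect structure, e.g.
the food-addiction column:

```r
eff <- reference_effects()
eff[eff$target == "YFAS", c("metabolite", "target", "status", "mediators")]
#>   metabolite target   status                     mediators
#> 7        IAA   YFAS indirect                      S_R_NAcc
#> 8     Indole   YFAS indirect                      S_R_NAcc
#> 9    Skatole   YFAS   direct S_R_NAcc,S_L_NAcc,B_L_ALSVerp
```

All three metabolites reach YFAS through functional connectivity of the
right nucleus accumbens; skatole is additionally associated directly.
`run_pipeline()` chains the imaging stages (time series → connectomes →
metrics → associations → network) and writes CSV/TSV/GraphML/SIF outputs
plus a provenance manifest; `export_graph()` produces Cytoscape-ready
files.

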