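---
title: "Stepwise integrative analysis of microbiota-host-symptom data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stepwise integrative analysis of microbiota-host-symptom data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the approach

Cohort studies of functional bowel disorders increasingly measure several
layers of the same individuals at once: mucosal host-gene expression (qPCR
panels on biopsies), mucosa-adjacent microbiota composition (16S rRNA
counts), and validated symptom instruments, both gastrointestinal and
psychological. The biological question -- which host genes, which taxa and
which symptoms move together, and whether patients differ from healthy
controls in how they move together -- is about the *correlation structure*
across layers, not about any single marginal difference.

`stepnet` implements a stepwise, exploratory procedure for this question.
The working hypothesis is that functionally related variables of the
mucosal ecosystem exhibit interdependence that is approximated by their
rank correlations. The procedure deliberately trades specificity for
sensitivity: it uses uncorrected significance at $\alpha = 0.05$ to avoid
discarding candidate interactions (type-2 error), and treats every finding
as a hypothesis for experimental follow-up, not a confirmed effect.

The pipeline runs in seven steps, orchestrated by `run_all()`:

1. **Prepare.** Genus counts are normalized for sequencing depth by the
   median-of-ratios method, summed into their phyla (phylogenetic
   relatedness as the summarizing criterion), and taxa that were screened
   for but never observed are removed. Each group is screened separately
   for strong multivariate outliers by PCA.
2. **Phylum-level networks.** Host genes and phylum abundances are
   correlated all-against-all (Spearman). Two views are built per group:
   an *overview* network that keeps every pair regardless of significance
   (the force-directed layout then shows relative correlation strength),
   and a *significance-filtered* network keeping only $p < \alpha$.
3. **Compare groups.** Density statistics, edge sets (by pair and sign)
   and detected intercorrelation clusters are compared between patients
   and controls; clusters without a counterpart (Jaccard $\ge 0.5$) in the
   other group are called group-specific.
4. **Symptom layers.** Within-layer networks for GI domain scores and
   psychological scores are joined to the mucosal network by the
   statistically significant between-layer correlations only, as a
   dual-layer and a three-layer ("triangle") model.
5. **Select.** Variables belonging to patient-specific clusters, taxa
   attached to those clusters, and variables with significant symptom
   edges are selected, each with explicit reason tags.
6. **De-summarize.** Selected phyla are split back into their member
   genera (skipped when fewer than `desummarize_min_genera` members
   exist, or when the association does not survive re-evaluation).
7. **Genus-level networks.** The cluster genes (or the symptoms, for
   phyla selected only through symptom edges) are re-analyzed against the
   member genera at full taxonomic resolution.

## Statistical components

### Rank correlation and significance

All associations are Spearman correlations on midranks, because the
integrated layers live on incommensurate scales (positive continuous
expression, normalized counts, bounded ordinal scores) and rank
correlation is invariant to monotone transforms of each margin. Two-sided
p-values use the $t$ approximation
$t = \rho\sqrt{(n-2)/(1-\rho^2)}$ on $n-2$ df for $n \ge 10$ and exact
enumeration of all $n!$ permutations for $n < 10$. No multiple-testing
correction is applied by default -- the procedure's explicit choice of
favoring type-1 over type-2 error -- but `adjust = "BH"` is available.

Constant features (e.g. a symptom with zero variance in controls) yield
$\rho = 0$, $p = 1$ with a warning instead of an error, so a degenerate
column cannot abort a run.

### Network densities

Connectedness is summarized relative to all $\binom{V}{2}$ pairs by two
fractions: the *strength density* (pairs with $|\rho|$ above 0.3) and the
*significance density* (pairs with $p < \alpha$). Both are computed from
the full correlation and p matrices, so they are identical in the
overview and filtered views of the same data.

### Layout

Node placement uses a seeded weighted Fruchterman-Reingold layout with
$|\rho|$ as attraction weight: strongly correlated variables end up close
together, which is what makes intercorrelation clusters visible. Exact
coordinates are aesthetic, not inferential; the contract is
reproducibility (bit-identical coordinates for a fixed seed) and the
proximity property, which is what the tests assert. Edges are drawn green
for positive and red for negative correlations, with width proportional
to $|\rho|$.

### Cluster detection

Where a human would circle tight groups of nodes by eye, `detect_clusters()`
uses seeded Louvain modularity maximization on the subgraph of significant
edges with $|\rho| \ge \tau$ (default $\tau = 0.3$, aligned with the
strength-density threshold), discarding communities smaller than
`min_size = 3`. An algorithmic criterion is the price of reproducibility.
One consequence to be aware of: with uncorrected $\alpha$, spurious
significant edges occasionally attach a noise node to a genuine cluster,
so cluster membership should be read as "co-clustered", not as an exact
set -- the comparison step's Jaccard matching (threshold 0.5) is tolerant
to such hangers-on, and the validation suite scores recovery of planted
blocks by co-clustering for the same reason.

### Outlier screening

Before any network is built, each group is screened for strong
multivariate outliers: features are standardized (expression, counts and
ordinal scores differ by orders of magnitude; without scaling, a
score-unit rule would be dominated by the count features), PCA scores are
computed, and a sample is flagged when it lies more than
`outlier_margin = 10` score units outside the Hotelling-$T^2$-style 95%
confidence ellipse on PC1-PC2. The ellipse is fit non-robustly on all
samples of the group, so the rule only catches *strong* outliers -- which
is its stated intent; screening is single-pass, and removal decrements
the group everywhere, including the symptom tables.

## The synthetic cohort generator

No public dataset accompanies this class of pilot studies, so the package
ships a generator (`sim_spec()`, `generate_cohort()`) that produces
cohorts with *known* cross-layer structure, giving every pipeline stage a
ground truth. Structure is planted through a Gaussian copula: a latent
multivariate normal with correlation $r = 2\sin(\pi\rho_S/6)$ yields
population Spearman $\rho_S$ regardless of the marginal transforms --
exactly the invariance the pipeline's statistic assumes. Marginals are

* log-normal for gene expression (the $2^{\Delta Ct}$ scale),
* negative binomial for genus counts, scaled by per-sample library-size
  factors drawn log-uniformly from $[0.5, 2]$ (so the median-of-ratios
  normalization has real work to do) and re-rounded to integers,
* ordinal quantile bins for symptoms, respecting each instrument's range
  (GSRS domains 1-7, HAD subscales 0-21, VSI 0-75, MFI 4-20).

`preset_pilot()` encodes the pilot-scale study conditions: 42 patients
and 20 controls; 22 host genes; 188 genera in 11 phyla; 5 GI and 4
psychological scores, generated for patients only (controls enter
symptom-free). Planted effects are fixed at pairwise Spearman 0.6 within
gene blocks, $-0.5$ for taxon attachments and $-0.4$ for symptom
attachments: a patient-only 4-gene "permeability"-type block coupled to a
3-genus phylum and a single-genus phylum (the latter exercising the
de-summarization skip), and a 6-gene "immune-enteroendocrine"-type block
present in both groups with patient-only taxon coupling. Symptom
couplings attach to the *block* (all four genes), matching how symptom
associations to a cluster are read; secondary correlations among attached
variables are set to their one-factor-implied values so the latent matrix
stays positive definite by construction. About 20% of unplanted genera
are sparse (tiny negative-binomial means), so zero-hit removal and
low-prevalence behavior are exercised.

What the generator does *not* emulate: phylogenetic covariance between
related genera, ecological dynamics, compositional closure beyond the
library-size factor, instrument measurement error, and covariate
structure (age, sex). Passing tests therefore demonstrate that the
pipeline recovers the kind of structure it claims to detect at realistic
effect sizes and sample sizes -- not that any particular biological
finding generalizes.

## Numerical choices and edge cases

* **Missing cells** are rejected at ingestion. Correlations on silently
  imputed data cannot be audited; samples with partial data are dropped
  by `align_cohort()` (with a log line), never filled in.
* **Median-of-ratios** uses the geometric mean over features with no zero
  in any sample, and takes the per-sample median on the log-ratio scale
  (for even feature counts this differs from an arithmetic median of
  ratios; the log-scale construction matches the method's reference
  implementation, which the tests cross-check). Tables in which no
  feature is observed everywhere are refused rather than silently
  switched to a pseudo-reference. Normalized abundances are not
  re-rounded: downstream statistics are rank-based. Note that with only a
  handful of features the size factor contains a non-negligible share of
  each feature's own signal (self-normalization); the method presumes a
  feature-rich table like the 188-genus input.
* **Reference genes** are averaged on the Ct scale (where $\Delta Ct$ is
  defined) before exponentiation; expression may equally be supplied
  directly on the $2^{\Delta Ct}$ scale.
* **Determinism.** Every stochastic component (layout, community
  detection, simulation) takes a seed; `run_all()` derives per-step seeds
  from the run seed, and a repeated run writes byte-identical
  `report.json` and edge TSVs. Reports embed the configuration, its hash
  and the seed.
* **Degenerate inputs.** Single-node networks lay out at the origin;
  empty networks export as valid zero-edge files; removing every sample
  of a group is refused; an unknown phylum yields an empty member list
  with a warning.

## Validation scale

The validation suite runs on cohorts at the pilot scale (62 samples,
219 features) and on reduced null cohorts (40-50 samples, 10 genes, 30
genera) where hundreds of repetitions are needed: planted-structure
recovery uses 50 pilot replicates, significance-density calibration 100
null replicates, copula calibration a single cohort of $n = 2000$. At
these sizes the whole suite completes in well under a minute of compute
per property. Two calibration facts surfaced by the suite are worth
knowing when interpreting results: single-pair detection of a Spearman
0.4 effect at $n = 42$, $\alpha = 0.05$ has power of only about 0.75 (so
individual between-layer edges at the moderate effect sizes typical of
symptom associations are found in roughly three of four replicates, while
cluster-level attachment, which aggregates several edges, is found in
nearly all); and the maximum null correlation over several hundred pairs
routinely exceeds what any single pair would show, which is exactly why
the exploratory, uncorrected analysis must be read as hypothesis
generation.

## A worked run

```{r, eval = FALSE}
library(stepnet)

sim <- generate_cohort(preset_pilot(seed = 1))
report <- run_all(sim$dataset, pipeline_config(seed = 1),
                  out_dir = "pilot-run")
report
report$comparison$densities
report$selection
plot(report$networks$patient$significant, seed = 1)
plot(report$symptoms$triangle)
```

The same analysis is available from a shell via the installed script:
`stepnet simulate --preset pilot --seed 1 --out simdir` followed by
`stepnet run --config cfg.yaml --out rundir`.
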