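# stepnet

Stepwise integrative correlation-network analysis of
microbiota–host–symptom cohort data.

## What it is for

Studies of gut disorders such as IBS routinely profile the same
individuals on several layers at once: mucosal host-gene expression
(qPCR panels, reported on the 2^ΔCt scale), mucosa-adjacent microbiota
(16S rRNA genus counts), and symptom questionnaires (GSRS domain scores,
HAD anxiety/depression, VSI, MFI). The scientific question is which
variables move *together* — within and across layers — and whether
patients differ from healthy controls in that co-movement. `stepnet` is
for researchers who want a reproducible, algorithmic version of this
exploratory analysis: it turns "circle the clusters in the network plot"
into seeded, tested, re-runnable code.

## The method

All associations are Spearman rank correlations ρ on midranks (the
layers live on incommensurate scales; ranks are invariant to monotone
transforms), with two-sided p-values from the t approximation
t = ρ√((n−2)/(1−ρ²)) for n ≥ 10 and exact permutation enumeration for
n < 10. Significance is deliberately *uncorrected* at α = 0.05 — the
analysis favors type-1 over type-2 error, as befits hypothesis
generation (a Benjamini–Hochberg option exists, default off).

The stepwise procedure (`run_all()`):

1. **Prepare** — median-of-ratios size-factor normalization of the genus
   counts; summation of genera into phyla; removal of zero-hit taxa;
   per-group PCA screening for strong multivariate outliers (flagged
   when > 10 score units outside the 95% confidence ellipse on PC1–PC2).
2. **Phylum-level networks** — all-pairs correlation of host genes +
   phyla per group, as an *overview* network (all C(V,2) edges, laid out
   by a seeded weighted Fruchterman–Reingold force layout so proximity
   encodes correlation strength) and a *significance-filtered* network
   (p < α only). Two density statistics summarize each network: the
   fraction of pairs with |ρ| > 0.3 and the fraction with p < α.
3. **Compare groups** — densities, signed edge sets, and Louvain-detected
   intercorrelation clusters matched across groups by Jaccard ≥ 0.5;
   unmatched clusters are patient- or control-specific.
4. **Symptom layers** — GI and psychological within-layer networks joined
   to the mucosal network by significant between-layer edges only
   (drawn dotted, ρ printed to 2 decimals), as dual-layer and
   three-layer models.
5. **Select** — members of patient-specific clusters, taxa attached to
   them by ≥ 2 significant edges, and variables with symptom edges, all
   with reason tags.
6. + 7. **De-summarize** — selected phyla are split back into their member
   genera (phyla with < 3 genera are skipped) and re-analyzed at genus
   level against the cluster genes or the symptoms.

Because no public dataset accompanies this class of pilot study, the
package includes a Gaussian-copula cohort simulator with planted
rank-correlation structure (`sim_spec()`, `generate_cohort()`,
`preset_pilot()`): a latent normal with r = 2·sin(πρ_S/6) yields
population Spearman ρ_S through any monotone marginal — log-normal
expression, library-size-scaled negative-binomial counts, ordinal
symptom scores — so every pipeline stage can be validated against known
ground truth.

## A worked example

```r
library(stepnet)

sim <- generate_cohort(preset_pilot(seed = 1))   # 42 patients, 20 controls,
                                                 # 22 genes, 188 genera
report <- run_all(sim$dataset, pipeline_config(seed = 1))
report
#> run_report: 7 steps, seed 1, config 8cfa0e13
#> group_comparison
#>    group density_strength density_significant
#>  patient        0.1212121           0.1136364
#>  control        0.1875000           0.0625000
#> shared significant edges: 12; patient-only: 48; control-only: 21
#> patient-specific clusters: 3; control-specific: 3

report$clusters$patient
#> cluster_set: 3 cluster(s) (min size 3, tau 0.3)
#>   cluster_1 [mean |rho| 0.56]: Bacteroidetes, CHGA, CHGB, Fusobacteria, MUC, SCG3, TLR2, TLR6, TLR9, TNFa
#>   cluster_2 [mean |rho| 0.57]: Chlamydiae, Euryarchaeota, FFAR2, Lentisphaerae, OCLN, PAR2, SCG2, TJP1, TLR4
#>   cluster_3 [mean |rho| 0.34]: DOUX2, SLC6A4, TPH1
```

Reading this: of the 528 host-gene/phylum pairs, 11.4% correlate
significantly in patients versus 6.3% in controls. `cluster_2` is the
planted "permeability"-type block (PAR2, OCLN, TJP1, TLR4) recovered
together with its two planted negatively coupled phyla (Chlamydiae,
Lentisphaerae); it has no counterpart in the control group and is
therefore patient-specific, so its members are selected and the
Chlamydiae phylum is queued for genus-level de-summarization
(Lentisphaerae, having a single genus, is skipped with reason
`too_few_genera`). `plot(report$networks$patient$significant)` and
`plot(report$symptoms$triangle)` draw the network views; green edges are
positive correlations, red negative, width ∝ |ρ|.

A thin CLI wraps the same functions:

```sh
stepnet simulate --preset pilot --seed 1 --out simdir
stepnet run --config cfg.yaml --out rundir     # writes report.json + TSV/GraphML
```

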