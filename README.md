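# methylDeviance

An R package for case/control epigenome-wide association analysis of
Illumina 450K-style blood DNA methylation, built around a region-level test
that **accumulates independent, possibly opposite-sign CpG-site effects**
instead of averaging them. It was written for studies like blood-based
profiling of Paget's disease of bone — where a diagnostic methylation
signature in an accessible tissue matters clinically — and is usable for
any two-group 450K-style design with a discovery/cross-validation split.

## What it computes

**Site level.** For each CpG, an ordinary least-squares model on M-values
(`M = log2((meth+1)/(unmeth+1))`)

```
M ~ phenotype + age + sex + batch + cell fractions + surrogate variables
```

with empirical-Bayes moderated t statistics
(posterior variance `s~² = (d₀s₀² + d s²)/(d₀ + d)`), BH-FDR
discovery → subset-wise cross-validation replication, and inverse-variance
fixed-effect meta-analysis of the two stages
(`β_meta = Σwᵢβᵢ/Σwᵢ`, `wᵢ = 1/seᵢ²`). Effect sizes are reported as
`Δβ = β_control − β_case` (negative ⇒ hypermethylated in cases).

**Region level.** For a CpG island, gene body or promoter with sites
`s₁…sₙ`, the nested binomial regressions

```
[1] phenotype ~ confounders
[2] phenotype ~ confounders + s₁ + s₂ + … + sₙ
```

are compared by their deviance difference, referred to χ²ₙ. Each site
carries its own coefficient, so hyper- and hypo-methylated sites along one
region add evidence rather than cancel. Within significant regions,
site-level FDR (local to the region) marks important sites; these pool
with the discovery DMS into the *pooled sites*.

**Downstream.** An OPLS-DA classifier (orthogonal signal correction +
one predictive PLS component) trained on discovery pooled sites and
evaluated on the held-out split (Mann–Whitney AUC, median-score
threshold); an elastic-net *best subset* of discriminatory sites; and a
keyword network built from Schäfer–Strimmer shrinkage partial correlations
with Fisher-exact keyword-pair enrichment.

A seeded synthetic-cohort generator (beta-distributed baselines,
logit-normal noise, Dirichlet blood-cell mixtures, batch/sex/age structure,
planted sites and regions with ground truth) makes the entire pipeline
testable offline.

## Worked example

```r
library(methylDeviance)

syn <- syntheticConfig(
  seed = 1, nProbes = 4000, nIslands = 25, nGeneBodies = 25, nPromoters = 25,
  plantedDMS = data.frame(probe = 3000:3009,
                          deltaBeta = rep(c(1, -1), 5) * 0.06),
  plantedDMR = list(isl0001 = c(0.05, -0.05, 0.05, -0.05, 0.05, -0.05)))
cfg <- pipelineConfig(seed = 2024, synthetic = syn, annotation = "auto")
res <- runPipeline(cfg)

res$ledger
#> FilterLedger
#>   probes:  4000 -> 3940
#>     - detection        0
#>     - cross_reactive   20
#>     - snp_within_3bp   10
#>     - sex_chromosome   25
#>     - smoking          5
#>   samples: 492 -> 492
#>     - intensity        0
#>     - sex              0

unlist(res$runManifest$counts)
#> probes_retained  samples_retained  dms_discovery  dms_replicated
#>            3940               492             13              12
#> dms_meta_significant  dmr_discovery  dmr_replicated  pooled_sites
#>                   15              1               1            14
#> best_subset  cv_auc
#>          14  0.9672414

res$classifier$eval
#> ClassifierEval: AUC 0.967, sensitivity 0.91, specificity 0.87 @ 0.0399
```

Reading the output: the QC ledger conserves counts exactly (60 probes
excluded across five first-match categories). Of the 10 planted sites and
the planted mixed-sign island, 13 sites reach discovery FDR < 0.05 and 12
replicate with concordant direction; the island replicates in the region
track. The discovery-trained OPLS-DA separates held-out cases from
controls with AUC 0.97 at the median-score threshold.

## Documentation

The methods vignette (`vignettes/methylation-ewas-pipeline.Rmd`) describes
the statistical model, every tunable threshold with its default and
rationale, what the synthetic generator does and does not emulate, and the
package's numerical conventions (ridge stabilisation, separation handling,
degenerate regions).
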