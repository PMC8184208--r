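---
title: "Site- and region-level differential methylation with deviance accumulation"
author: "methylDeviance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Site- and region-level differential methylation with deviance accumulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylDeviance)
```

# Overview

`methylDeviance` implements a complete case/control epigenome-wide
association workflow for Illumina 450K-style blood methylation data, built
around one central idea: testing a genomic *region* (CpG island, gene body
or promoter) by letting each of its CpG sites contribute an independent,
possibly opposite-sign effect, rather than averaging methylation across the
region. Paget's disease of bone is the motivating application — a late-onset
skeletal disorder where a blood-based epigenetic signature is clinically
attractive because bone tissue is hard to collect — but nothing in the code
is disease-specific.

The pipeline stages are: quality control with a conservation-checked
ledger; M-value computation and quantile normalization; reference-based
blood cell deconvolution; surrogate-variable extraction; moderated
site-level models with discovery/cross-validation replication and
fixed-effect meta-analysis; the region deviance test; within-region site
selection and pooling; OPLS-DA classification with elastic-net subset
selection; and a shrinkage partial-correlation keyword network.

# The data model

Methylation at a CpG is summarised as a beta value (the methylated fraction
of signal, in `[0, 1]`) or an M-value,
`M = log2((meth + 1)/(unmeth + 1))`, which is approximately Gaussian and is
what every linear model in the package operates on. Beta values are used
only where an interpretable effect size is wanted: the reported
`delta_beta` is the raw group mean difference on the beta scale, oriented
`control - case` so that negative values mean hypermethylation in cases.
This orientation follows the convention of published 450K case/control
tables; the raw (rather than covariate-adjusted) difference is reported
because the adjusted coefficient already exists on the M scale and the raw
beta difference is the quantity a reader can check against group means.

# Site-level analysis

Each probe is fitted by ordinary least squares,

    M ~ phenotype + age + sex + batch + cell fractions + surrogate variables

and the phenotype coefficient is tested with an empirical-Bayes moderated
t statistic: per-probe residual variances are shrunk toward a common prior
estimated by method of moments on `log s^2`, the classic microarray
moderation model (delegated to `limma::squeezeVar`). Discovery-significant
sites (BH FDR < 0.05) are re-assessed in the held-out cross-validation
split, with the FDR recomputed **over that subset only** — the discovery
stage defines the family of hypotheses being replicated. A genome-wide
switch is available for users who prefer the stricter reading.

The two stages are then combined by inverse-variance fixed-effect
meta-analysis (`w_i = 1/se_i^2`). The pipeline feeds the per-stage M-scale
coefficients and their moderated standard errors into the combination; the
helper `seFromP()` exists only to reproduce published meta arithmetic from
printed effect/p pairs, by inverting the two-sided normal test. A
DerSimonian-Laird random-effects variant is available behind a flag; with
two stages its between-stage variance estimate is noisy, which is why
fixed-effect is the default.

# The region deviance test

For a region with sites `s_1 .. s_n`, two nested binomial (logistic)
models are fitted:

    [null]  phenotype ~ confounders
    [full]  phenotype ~ confounders + s_1 + ... + s_n

The deviance difference between them is referred to a chi-squared
distribution with `n` degrees of freedom (one per site actually entered).
Because each site carries its own coefficient, a region whose sites are
alternately hyper- and hypo-methylated accumulates evidence where a
mean-aggregate test cancels to zero; the acceptance suite demonstrates this
directly (deviance-test power near 1, mean-aggregate power near the 0.05
noise floor, on the same planted regions).

Numerical choices:

* Fitting is by iteratively reweighted least squares with a ridge penalty
  of `1e-6` on the non-intercept coefficients. The penalty exists purely
  for numerical stability in wide regions (real islands can hold tens of
  sites against a few hundred samples); at this magnitude its effect on the
  deviance is orders of magnitude below the `1e-6` agreement the test suite
  enforces against an independent Newton-Raphson fit. No site pre-screening
  is done — all of a region's sites enter.
* (Quasi-)separation is detected as a near-zero residual deviance or a
  diverging linear predictor (`|eta| > 25`); such regions are returned with
  `converged = FALSE` and a missing p-value, never an error or `p = 0`.
* A zero-site region returns `chi2 = 0`, `df = 0`, `p = 1` by convention;
  single-site regions are tested with `df = 1`. Constant site columns are
  dropped and the degrees of freedom reflect only the columns entered.

The two-stage workflow mirrors the site analysis: per region type
(island / gene body / promoter), discovery BH-FDR selects regions for
cross-validation testing, and the cross-validation FDR is computed over
that subset. The Bonferroni track adjusts discovery p-values over all
regions of the type and cross-validation p-values over the
discovery-Bonferroni-significant subset.

# Pooled sites

Within every discovery-FDR-significant region, the full model's per-site
Wald p-values receive a BH correction *local to that region* (m = the
region's own site count); sites passing FDR < 0.05 are "important". The
union of discovery-significant DMS and these important within-region sites
forms the *pooled sites*, with multi-tag provenance (`dms`, `dmr_island`,
`dmr_gene_body`, `dmr_promoter`) preserved per probe. Pooling is keyed on
discovery-significant regions (not replicated-only) because the pooled list
is a discovery-stage object that downstream classification then validates
on the held-out split; a flag switches to replicated-only regions.

# Classification

OPLS-DA is implemented from its NIPALS/orthogonal-signal-correction
definition: after mean-centering and unit-variance scaling (the default of
the chemometrics software this classifier is standard in), `nOrtho`
response-orthogonal components are removed and one predictive PLS component
is fitted. The default is a single orthogonal component — the standard
two-axis predictive-vs-orthogonal score plot — and is configurable. A
useful identity: since `X'y` is invariant under orthogonal deflation, the
predictive weight vector equals the one-component PLS1 weight; the value of
the orthogonal step is in the *scores*, which are freed of class-unrelated
structured variation (their covariance with the response is zero to
machine precision, an invariant the tests enforce).

Classifiers are trained on the discovery split over the pooled sites and
evaluated on the cross-validation split by Mann-Whitney AUC (ties at 1/2),
with sensitivity/specificity read at a threshold equal to the median of the
predicted scores being evaluated (configurable to the training median).

The *best subset* is the nonzero-coefficient set of an elastic-net
penalized logistic regression (mixing 0.5 by default) with lambda chosen by
10-fold cross-validation under the one-standard-error rule on
misclassification error. Misclassification (rather than deviance) is used
as the CV loss because the subset is selected *for classification*; in
planted-predictor simulations the deviance-based rule admitted 10–19% of
pure-noise features where the class-error rule stays under 6% with every
true predictor retained. Effect sizes (`|delta_beta|`) of best-subset vs
remaining pooled sites are compared by a two-sided Wilcoxon rank-sum test
by default (the effect-size distribution is strongly skewed); Welch's t is
available.

# Keyword network

Partial correlations among the pooled sites come from a Gaussian graphical
model. With more sites than samples the sample correlation matrix is
singular, so it is shrunk toward the identity with the analytic
Schäfer–Strimmer intensity before inversion;
`pcor_ij = -Omega_ij / sqrt(Omega_ii Omega_jj)`. Significance uses the
Fisher z transform with effective sample size `n - (k - 2) - 3`, and BH
over all pairs defines "significant" partial correlations (a raw-p option
exists). For two functional keywords, sites are mapped through
probe → gene → keyword, and a 2×2 Fisher exact test asks whether
cross-keyword site pairs are enriched for significant partial correlations
against the background of all other pooled-site pairs; pairs lying within a
single keyword are excluded from both counts. BH over all keyword pairs
retains edges at q < 0.05, and node degree identifies hub keywords.

# The synthetic cohort generator

Every stage is testable without array data through a seeded generator that
emulates the study conditions of a two-split blood EWAS:

* cohort structure: 116 cases / 130 controls in each of discovery and
  cross-validation; cases older and more male in the discovery split
  (means 72.1 vs 70.0 years; 56% vs 37% male) and balanced in
  cross-validation, reproducing a realistic confounding pattern;
* methylation: bimodal baseline betas; Gaussian noise on the M scale
  (`noiseSD = 0.5`, a typical 450K residual SD for mid-range probes);
  planted site effects specified on the beta scale (the study-size effect
  range is 0.01–0.04; power demonstrations use ≥ 0.05) and converted to
  M-scale offsets via the logit derivative at each probe's baseline —
  adequate because the residual attenuation bias (~0.0015 at
  `delta = 0.05`) sits well inside the Monte-Carlo calibration band the
  tests enforce;
* confounders: Dirichlet 8-part blood cell mixtures (neutrophil-dominated)
  whose cell-sensitive probes are true mixtures of generated reference
  profiles, so deconvolution is a meaningful inverse problem; batch shifts
  on a probe subset; autosomal sex and age effects; X-inactivation pulling
  female X betas toward 0.5, giving the sex-prediction filter real signal;
* plumbing: lognormal total intensities (configurably degraded below the
  log2 median-intensity QC threshold of 11.0), detection p-value failures
  at a configurable rate, and exact, disjoint exclusion-flag counts so the
  filter ledger can be checked to the probe.

What the generator does **not** emulate: Infinium I/II probe chemistry,
spatial array artefacts, genetic effects, and — by default — correlation
between neighbouring CpGs (a `withinRegionCor` parameter exists but
defaults to 0 because the within-region dependence in real data is not
well characterised). Passing tests therefore demonstrate statistical
correctness of the machinery under a clean noise model, not robustness to
every 450K artefact; real-data use still requires the usual array QC
upstream.

# Design decisions on points the workflow leaves open

* **Detection-p aggregation**: a probe is excluded when detection p > 0.05
  in more than 5% of samples (common EWAS practice); the proportion is
  configurable.
* **Normalization**: quantile normalization serves as the documented
  stand-in for array-specific normalization schemes and can be switched
  off.
* **Cell deconvolution**: non-negative least squares against reference
  profiles over a discriminating probe set (default: top probes by
  between-cell-type range, 100 per type) — the same contract as the
  reference-based method used with 450K blood data (profiles in, fractions
  out), without the original's full estimation pipeline.
* **Surrogate variables**: residual PCA with fixed k = 10 — principal
  components of the M matrix after projecting out phenotype and known
  covariates. This keeps the components exactly orthogonal to every known
  covariate (enforced to 1e-8 in tests); the "significant components"
  selection step of full surrogate-variable analysis is deliberately not
  reproduced.
* **Confounders** are identical in the site and region models: age, sex,
  batch, cell fractions and surrogate components. Seven of the eight cell
  fractions enter (the largest type is dropped) because the fractions sum
  to one and would otherwise be near-collinear with the intercept.
* **Meta-analysis weighting** is inverse-variance; weighting by sample size
  is indistinguishable here (equal-size stages) and not separately
  implemented.

# Problem sizes and runtime

The test and acceptance suites run at desk scale, chosen to keep the whole
suite under a few minutes while leaving Monte-Carlo bands tight enough to
be meaningful: null calibration of the region test uses 1000 replicate
regions (5 sites, 200 samples); mixed-sign power uses 30 replicate cohorts
of 200 samples; the end-to-end run uses 4,000 probes, 75 regions and the
full 492-sample two-split cohort with 10 planted sites and 5 planted
regions; ledger arithmetic is exercised once at the full 485,512-probe
array scale (manifest only). All randomness flows from per-stage seeds
derived from a single master seed.

# Worked example

```{r example, eval = FALSE}
syn <- syntheticConfig(
  seed = 1, nProbes = 4000, nIslands = 25, nGeneBodies = 25,
  nPromoters = 25,
  plantedDMS = data.frame(probe = 3000:3009,
                          deltaBeta = rep(c(1, -1), 5) * 0.06),
  plantedDMR = list(isl0001 = c(0.05, -0.05, 0.05, -0.05, 0.05, -0.05)))
cfg <- pipelineConfig(seed = 2024, synthetic = syn, annotation = "auto")
res <- runPipeline(cfg)
res$runManifest$counts
```

# Known limitations

* The deviance test relies on the asymptotic chi-squared null; with very
  wide regions relative to sample size the test is run (ridge-stabilised)
  but the `converged` flag and the df should be inspected.
* The subset-wise cross-validation FDR is a modelling choice; the
  genome-wide alternative is one flag away and is stricter.
* The shrinkage graphical model is a substitute for an exact partial
  correlation on systems where sites outnumber samples; its p-values are
  approximate and the keyword network should be read as exploratory.
* No probe-type bias correction, genomic-inflation control, or
  batch-correction beyond covariate adjustment is provided.
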