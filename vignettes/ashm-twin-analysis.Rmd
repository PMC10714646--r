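---
title: "Allele-specific hydroxymethylation analysis in discordant MZ twins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Allele-specific hydroxymethylation analysis in discordant MZ twins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ashmtwin)
```

## The scientific problem

5-hydroxymethylcytosine (5hmC) is an oxidized DNA modification enriched by
selective chemical labelling capture and sequenced as short reads. At a
heterozygous SNP, reads can be assigned to the reference or the alternative
allele, so the balance of allele-specific read counts measures
*allele-specific hydroxymethylation* (AShM). In monozygotic (MZ) twins the
two cotwins share a genome; when one cotwin is affected by a psychiatric
disorder and the other is not (a phenotype-discordant, PDC, pair), a change
of the allelic imbalance between cotwins points at a disease-associated
epigenetic transition rather than a genetic difference.

`ashmtwin` implements this analysis end to end: allele-aware count
ingestion and filtering, per-individual AShM calling with FDR control,
Bayesian quantification of site-level imbalance, Bayes-factor detection of
disease-associated transitions across PDC pairs, and the downstream
enrichment statistics used to interpret the transition sites. A synthetic
cohort generator with known ground truth makes every stage testable without
access to any twin sequencing data.

## Models

### Per-individual calling

For one heterozygous individual at one site, the alternative-read count out
of the total is tested against a balanced proportion of 0.5 with the exact
two-sided binomial test. Because the null pmf is symmetric, the p-value is
`min(1, 2 * pbinom(min(alt, ref), n, 0.5))`. Within each individual, the
Benjamini-Hochberg procedure controls the FDR across that individual's
tested sites at a nominal 10%; a record is an AShM call when its q-value is
strictly below the threshold. A minimum depth of 8 reads (configurable)
keeps hopeless tests out of the FDR family: below 8 reads the exact test
cannot reach p < 0.01 even at complete imbalance, so such records only
dilute the procedure.

### Site-level quantification

Across the heterozygous individuals of one site we model

$$y_i \sim \mathrm{Binomial}\!\big(n_i,\ \mathrm{logit}^{-1}(\beta_0 + b_{s(i)} + \gamma_i)\big)$$

where $\beta_0$ is the logit-scale degree of allelic imbalance (the target
of inference), $b_s$ a mean-zero two-level disease-status random effect
(effect-coded $\pm d/2$ with $d \sim N(0, \sigma_s^2)$), and $\gamma_i$ a
per-twin random effect. Priors are proper and weakly informative:
$\beta_0 \sim N(0, 3^2)$ (an imbalance of $|\beta_0| = 3$ is already an
alt fraction of 0.95), and Half-Normal(0, 1) scales for $\sigma_\gamma$ and
$\sigma_s$. Credible intervals are empirical posterior quantiles, and the
two-tailed posterior p-value is the tail area of $\beta_0$ beyond the
balanced null $\mathrm{logit}(0.5) = 0$.

### Disease-associated transitions

For candidate sites — AShM-significant in at least one PDC individual and
heterozygous in at least two PDC pairs — we compare, over PDC individuals
only,

* $M_1$: $\mathrm{logit}(p_{is}) = \beta_0 + \beta_s + \gamma_i$
* $M_0$: $\mathrm{logit}(p_{is}) = \beta_0 + \gamma_i$

by the Bayes factor $BF = p(\mathrm{data}\mid M_1)/p(\mathrm{data}\mid
M_0)$, each marginal likelihood integrating over all parameters. The status
effect in $M_1$ is "fixed" in the mixed-model sense but carries a proper
unit-information prior $\delta \sim N(0, 1)$ — without a proper prior the
marginal likelihood does not exist, and because Bayes factors are
prior-sensitive the prior scale is configuration-exposed and stamped into
outputs. Sites with $BF > 1$ are discordant AShM sites; $BF > 10$ is strong
evidence for a disease-associated transition. Both thresholds are
configuration values.

Independently of the BF, each site is classified from the per-individual
calls of its informative PDC pairs: *gain* (AShM in the affected cotwin
only), *loss* (unaffected only), *flip* (both AShM, opposite directions),
*similar* (both the same, or both non-AShM), with a majority vote across
pairs and ties left *unclassified*. The classifier is deliberately not
driven by the BF: magnitude differences without a pattern change can carry
a large BF, so the two outputs answer different questions.

## Inference backend

The per-twin random effects are integrated out of the likelihood
analytically by adaptive Gauss-Hermite quadrature (11 nodes by default; the
binomial-logit integrand is strictly log-concave in $\gamma_i$, so the 1-D
Newton mode search is globally convergent). What remains is a 2- to
4-dimensional marginal posterior over $(\beta_0, \text{status},
\log\sigma)$, for which the backend finds the mode (BFGS), forms a Laplace
approximation, and refines both the marginal likelihood and the posterior
summaries by importance sampling with a multivariate-t proposal (df = 4,
covariance inflated 1.3-fold; 2000 draws by default). If the effective
sample size falls below a quarter of the draws, one adaptive round
moment-matches the proposal to the weighted first-round draws — the
hierarchical status scale produces a curved ridge that the Laplace
covariance underestimates. All draws are seed-controlled; per-site seeds
derive deterministically from the run seed so results do not depend on
site order.

Two parameterization choices matter numerically. First, the random effects
must be marginalized (not sampled jointly): the joint density in centred
form is unbounded as a random-effect SD approaches zero, so no posterior
mode exists there, and non-centred sampling leaves a high-dimensional
funnel that defeats importance sampling. Second, the hierarchical status
effect is parameterized non-centrally as $d = \sigma_s z$ inside the outer
posterior; its implied marginal prior on $d$ has an (integrable)
logarithmic singularity at 0 and cannot be used as a density on a grid —
the package's test oracle therefore integrates it by exact cell
probabilities.

In tests, the backend is validated against an independent dense-grid
trapezoid quadrature oracle on small sites: posterior means of $\beta_0$
agree within 0.05 and log marginal likelihoods (hence log BFs) within 0.1.

## The synthetic cohort generator

`simulate_cohort()` emulates the study design this analysis targets:
MZ pairs split into PDC, disease-concordant (PCC) and healthy-concordant
(HCC) classes — 6/4/4 pairs (28 individuals) by default, matching the
discordant-twin design the pipeline defaults are sized for. Heterozygosity
is a pair-level property (cotwins always share genotype); each heterozygous
cotwin receives a depth from a zero-truncated negative binomial and an
alternative count that is binomial with logit-scale mean
$\beta_0(\text{status}) + \gamma_i$. Per-site scenarios define the truth:
*null* (0, 0), *stable AShM* ($\beta_0 = 2$ in both cotwins), *gain* (0
then `effect_size`), *loss* (`effect_size` then 0) and *flip*
($\pm$`effect_size`/2).

Defaults and why:

* `depth_mean = 40`, `depth_dispersion = 0.15` (variance $m + 0.15 m^2$).
  Capture-based 5hmC enrichment produces overdispersed per-site coverage;
  a negative binomial with moderate dispersion emulates that. Only the
  mean sequencing effort of such experiments is usually reported, not a
  per-SNP depth distribution, so this is a modelling choice.
* `het_prob = 0.3` — a realistic fraction of pairs heterozygous at a
  candidate SNP.
* `sigma_gamma = 0.3` — per-twin biological and technical variability on
  the logit scale; at depth 40 this is comparable to the binomial noise.
* `effect_size = 2`, `beta0_stable = 2` — an alt fraction of 0.88 for a
  "present" AShM state, a clearly detectable but not saturated imbalance.
* `scenario_mix` defaults to half null sites and the rest spread over
  stable/gain/loss/flip, so pipeline runs exercise every branch.

What the generator does *not* emulate: raw reads, alignment artifacts and
reference-mapping bias, base-calling error, 5hmC capture chemistry, linkage
between neighbouring sites, and read-level overdispersion beyond the
per-individual random effect (no beta-binomial layer). Passing tests
therefore demonstrate statistical correctness of the pipeline under its
own generative assumptions, not robustness to mapping bias — count tables
fed to the real-data path are expected to be already quality-filtered
("high-quality read" thresholds belong to the upstream counting tool, and
the candidate filter here reduces to `alt_reads >= 1`).

## Downstream statistics

Annotation enrichment uses the two-sided Fisher exact test with the
cross-product odds ratio (the quantity conventionally printed in
epigenomic enrichment analyses) and the Haldane-Anscombe 0.5 correction on
zero cells, flagged. Chromatin-state results from several tissues combine
by fixed-effect inverse-variance meta-analysis on the log OR
(`metafor::rma.uni(method = "EE")`); DerSimonian-Laird random effects are
available behind a flag since a plain "meta-analysis" leaves the model
open and fixed-effect is the minimal choice. Direction consistency between
a predicted chromatin feature effect and the hydroxymethylation side of
the alternative allele is tested with the same exact binomial kernel; sites
with a zero effect or an alt level of exactly 0.5 carry no direction and
are dropped with a log message, since no convention for them is
well-defined. Motif effects are additive PWM scores min-max scaled to the
motif's exact scoring range (computable per position), maximized over all
SNP-overlapping windows on both strands — max-aggregation is the motif-scan
convention; the aggregation is configurable. The TF screen reports Pearson
correlations between $|score_{ref} - score_{alt}|$ and alt-allele
hydroxymethylation, significant at $|r| > 0.5$ and $p < 0.05$ with at
least 3 paired sites per TF. Gene-set enrichment runs Fisher tests against
an explicit background list or a seeded random sample from a supplied gene
universe.

## Numerical and design notes

* Rejection at the FDR threshold is strict (`q < 0.10`), matching an
  "FDR less than 10%" rule; the naive step-up oracle in the tests uses the
  same convention.
* Ties (`alt == ref`) carry direction `none` before FDR and can never be
  calls.
* Coordinates: count tables and VCF are 1-based; BED intervals and profile
  bins are 0-based half-open. Binned profiles use 500-bp bins stepped every
  250 bp, so interior positions fall in exactly two bins; `rhms` is the bin
  count per million total reads, supporting only within-grid relative
  comparisons.
* Multi-allelic sites are excluded on ingestion (biallelic SNPs only),
  logged.
* Sites informative in a single individual skip the mixed model and carry
  only the per-individual call; Bayes factors require two informative PDC
  pairs.
* The `run_pipeline()` manifest records the package version, seed,
  configuration hash and per-stage row counts, so the funnel of sites
  through the filters is reportable for any dataset.

## Problem sizes used by the test-suite

The statistical suites run at sizes chosen to make their Monte-Carlo error
small relative to the tolerances while keeping a laptop-scale runtime:
exact-test oracles are exhaustive to depth 200; FDR calibration uses 5,000
null sites by 12 individuals over 3 seeds; BF calibration uses 200 null and
200 flip replicates plus a 4-point monotonicity sweep of 100 replicates
each; oracle agreement uses 50 random small sites against the dense-grid
quadrature. The acceptance script reruns the full pipeline on the default
500-site cohort and reports the recovered quantities.

## Known limitations

* No reference-mapping-bias correction: allele counts are taken at face
  value.
* No read-level beta-binomial overdispersion; overdispersion enters only
  through the per-twin random effect.
* Bayes factors depend on the status-effect prior scale; the default
  unit-information choice is sensible for logit effects of order 1-4, and a
  sensitivity rerun at different prior widths is recommended for borderline
  sites.
* The per-individual calling statistic (exact binomial + BH) is the
  minimal faithful choice for an "FDR 10% per individual" rule; the
  Bayesian machinery is reserved for site-level quantification and model
  comparison.
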