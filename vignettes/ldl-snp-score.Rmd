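---
title: "The seven-SNP LDL-C score: model, simulator and statistical stage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The seven-SNP LDL-C score: model, simulator and statistical stage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ldlprs)
```

## The score

Polygenic hypercholesterolemia is usually quantified with a weighted
allele-dosage score over a small panel of LDL-C-associated SNPs. The score
implemented here uses seven genotyped loci, but only five of them enter as
additive dosage terms; the two *APOE* coding SNPs (rs429358 and rs7412) are
weighted jointly through the ε diplotype they define:

$$ S \;=\; \sum_{i=1}^{5} d_i\,w_i \;+\; w_{\text{APOE}}, $$

where $d_i \in \{0,1,2\}$ counts copies of the risk allele at locus $i$ and
$w_{\text{APOE}}$ is one of six diplotype weights. The panel weights are:

| locus | gene | risk allele | weight per copy |
|---|---|---|---|
| rs629301 | *CELSR2* | T | 0.15 |
| rs1367117 | *APOB* | A | 0.10 |
| rs11220462 | *ST3GAL4* | A | 0.05 |
| rs6511720 | *LDLR* | G | 0.18 |
| rs1800562 | *HFE* | G | 0.057 |

with APOE diplotype weights ε2ε2 = −0.9, ε2ε3 = −0.4, ε2ε4 = −0.2,
ε3ε3 = 0, ε3ε4 = 0.1, ε4ε4 = 0.2. Two design points deserve emphasis:

* **Risk allele = reference allele at rs6511720 and rs1800562.** At these
  loci the minor alleles (T and A) are the LDL-lowering ones, so the major
  (reference) allele carries the weight and a typical homozygote
  contributes the full $2w_i$. This is taken literally from the weight
  table; it means "all-reference" genotypes do not score zero.
* **Dosage convention.** The weight tables define per-copy weights, and the
  additive dosage interpretation is the only one under which the published
  observed extremes (−0.62 and 1.174) and medians (0.824, 0.674) are
  attainable; a per-genotype (non-additive) reading cannot produce 1.174
  from these constants. The analytic extremes of the full weight system are
  −0.9 and 1.274, confirmed in the test suite by brute force over all
  $3^5 \times 6$ dosage/diplotype combinations.

Scores are kept at full precision internally and printed to three decimals
in text output, matching the precision at which such scores are usually
reported. No centering or standardization is applied: the published group
summaries are on the raw weighted-sum scale.

## APOE diplotype calling

rs429358 (T/C) and rs7412 (C/T) jointly define the haplotypes
ε2 = (T, T), ε3 = (T, C), ε4 = (C, C); the fourth arrangement (C, T),
sometimes called ε1, is vanishingly rare and outside this system. Eight of
the nine unphased genotype combinations either resolve uniquely or are
impossible without an ε1 haplotype (those raise an error rather than a
guess). The doubly heterozygous combination is consistent with ε2ε4 or with
ε1ε3; the default policy makes the conventional ε2ε4 call, and a strict
policy returns `unresolved` instead, excluding the sample from scoring.
The test suite checks all nine combinations against an independent
enumeration over ordered haplotype pairs.

Missing genotypes never produce a guessed diplotype: a sample missing
either APOE site is `unresolved`, and by default any sample missing one of
the seven genotypes gets an `NA` score with a structured reason
(`on_missing = "partial"` scores the available loci and flags the result).
Allele validation is strict — a call outside a locus's declared allele pair
is an error naming the sample and rsid, never a silent strand flip; none of
the seven loci requires strand disambiguation beyond its declared pair.

## The cohort simulator

No individual-level data accompany the study design this package
implements, so the simulator is a first-class module: it generates the
*conditions* of that design — two labelled groups of 93 patients and 61
comparison individuals — with the published group-specific variant-allele
frequencies and phenotype summaries as defaults.

* **Genotypes.** The five additive loci are drawn independently under
  Hardy–Weinberg proportions (no linkage disequilibrium is simulated; at
  these inter-chromosomal loci LD is negligible, and the two intra-*APOE*
  sites are handled jointly). rs429358/rs7412 genotypes are drawn as pairs
  of ε haplotypes with $p(\varepsilon4) = f(\text{rs429358-C})$,
  $p(\varepsilon2) = f(\text{rs7412-T})$ and
  $p(\varepsilon3) = 1 - p(\varepsilon2) - p(\varepsilon4)$ — a no-ε1
  constraint that keeps every simulated sample inside the diplotype system.
* **Frequency interpretation.** The published per-group "frequency (%)"
  values are treated as variant-allele frequencies by default. Some of
  them (e.g. rs6511720 at 36.07% against a gnomAD allele frequency of
  ~11%) look more like carrier frequencies, but the source does not say;
  the interpretation is therefore a documented switch
  (`freq_kind = "carrier"` converts via $p = 1 - \sqrt{1 - c}$) rather
  than a hard-coded assumption.
* **LDL-C.** Drawn from a log-normal matched to the configured group
  median (meanlog = log median) and truncated by rejection to the
  configured min–max; sdlog is set so the configured range spans the
  central 99% of the untruncated law. The log-normal is a choice of
  convenience for a positive, right-skewed concentration; the source
  reports only median and range.
* **Covariates.** Sex, ever-smoking, statin use and hypertension are
  Bernoulli at the published group prevalences; the published
  current/past smoking split is collapsed to a single ever-smoker
  indicator because the downstream models use smoking as one binary term.
  Age is uniform within the published min–max and unused downstream.
* **Disease model.** When coefficients are supplied, case status is
  assigned by a logistic model on the score and smoking,
  $\Pr(\text{case}) = \text{logit}^{-1}(\beta_0 + \beta_P S + \beta_S x)$,
  with candidates drawn from a base population (comparison-group
  frequencies by default) and the two groups filled to quota. This is the
  minimal joint genotype–phenotype structure under which the published
  regression is well-specified — an assumption of the simulator, not a
  claim about the real cohort. Quota sampling is case–control sampling:
  it biases only the logistic intercept, so slope recovery is well-posed.
  An unsatisfiable quota (e.g. an intercept so low that no cases arise
  within the draw budget, 10^6 by default) is an error, not a hang.
* **Randomness.** Everything flows from one seeded generator
  (`withr::with_seed`), so a cohort is a byte-deterministic function of
  (config, seed), which the tests assert.

What passing tests on these cohorts show is that the pipeline's statistics
behave correctly *under the stated generative model*. Real cohorts add
LD, genotyping error, ascertainment and treatment effects (e.g. statins
lowering LDL-C) that the simulator deliberately does not model.

## The statistical stage

* **Rank tests.** Quantitative variables are compared with the
  tie-corrected Kruskal–Wallis statistic (delegated to
  `stats::kruskal.test`); for two groups this equals the squared normal
  approximation of the two-sided Mann–Whitney test, which the suite
  verifies to 1e-9. An all-tied input returns $H = 0$ by convention.
* **Pearson χ².** Computed without Yates continuity correction — the only
  convention that reproduces the published group-characteristic statistics
  (0.252 for the sex split; 8.368 for hypertension, whose published
  comparison-group percentage implies a denominator of 60, not 61). The
  report generator always computes percentages from supplied denominators
  and never back-fills them.
* **Fisher exact.** The 2×2 two-sided p-value uses the point-probability
  rule (sum of all equally-or-less-probable tables with the observed
  margins, with the customary $1+10^{-7}$ relative tolerance); 2×3 tables
  go through the exact network algorithm in `stats::fisher.test`; larger
  layouts are redirected to χ². The suite checks every 2×2 table with
  $N \le 40$ against literal factorial enumeration to 1e-12.
* **Logistic regression.** An in-package IRLS with step-halving (the
  log-likelihood trace is non-decreasing, and tested), convergence when
  the max absolute score falls below 1e-8 or the relative log-likelihood
  change below 1e-10, Wald odds-ratio intervals
  $\exp(\hat\beta \pm z\,\mathrm{SE})$ (matching the symmetric-on-log-scale
  intervals such studies print; profile likelihood is not used), and a
  structured separation diagnostic (boundary-pinned fitted probabilities
  plus a runaway coefficient) instead of divergent estimates.
  `stats::glm` serves as the reference implementation in the tests.
* **Backward selection.** Iteratively drops the term with the largest Wald
  p ≥ α, refitting until all survivors have p < α; the intercept is never
  dropped and full elimination returns the intercept-only model with its
  trace. The default α is 0.05: the source prints "p < 0.5", which is
  almost certainly a typo for 0.05, but any threshold (including 0.5) can
  be passed. The candidate set for the case model is configuration, not
  code, since the source does not enumerate the covariates of each
  multivariate model; the default is score, smoking, sex, age,
  hypertension and statin use. The high-LDL-C model (outcome
  LDL-C > 4.9 mmol/L, strictly) is fitted within the comparison group by
  default, with an `"all"` override.

The published cohort-specific results — the group medians as *medians*,
the odds ratios 12.044, 24.962 and 20.391 — depend on the undeposited
individual-level data and are not reproduction targets. They enter the
package in two honest ways: as worked-example scores that the weight
system must attain exactly, and as true effects given to the simulator,
whose fitted 95% Wald intervals must then cover them in ≥ 90% of
replicates.

## Problem sizes and numerical choices in the test suite

The suite's statistical checks use sizes chosen to make Monte-Carlo error
negligible relative to the asserted tolerances: allele-frequency and
Hardy–Weinberg checks at n = 20 000 (3 binomial SEs), the rank test's
type-I error over 1 000 null cohorts of the study's size (93 + 61,
accepting 5% ± 1.5%), coefficient recovery over 500 case–control cohorts
of 2 500 + 2 500, and the exhaustive Fisher comparison over all ~1.3 × 10⁵
small tables. Score identities are asserted to 1e-12 (sums of a handful of
exactly representable decimals), rank-test equivalences to 1e-9
(accumulated floating error in the variance formula), and IRLS against the
reference fit to 1e-6–1e-7 (two optimizers with different stopping rules).

## Known limitations

* The panel is fixed at seven loci; arbitrary PGS-catalog scores are out of
  scope, though custom weight files with the same 5 + diplotype structure
  round-trip losslessly.
* The simulator draws covariates independently within groups (except where
  the disease model induces dependence), so covariance structure among
  sex, smoking, hypertension and statin use is not emulated.
* Genotyping error, missingness mechanisms and assay artefacts are not
  simulated; missing-data handling is exercised with constructed fixtures
  instead.
* Coordinates shipped with the panel are GRCh38 metadata for VCF output;
  matching is by rsID only, and no liftover is provided.
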