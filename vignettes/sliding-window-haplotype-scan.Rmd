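---
title: "Sliding-window haplotype association scans with hapslide"
author: "hapslide authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sliding-window haplotype association scans with hapslide}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hapslide)
```

# The problem

Single-SNP association tests can miss risk variation that is carried by a
particular arrangement of alleles along a chromosome rather than by any
one genotyped marker. Haplotype analysis addresses this, but deploying it
genome-wide raises three practical obstacles: haplotypes must be inferred
from unphased genotypes; block boundaries are ambiguous, which argues for
a fixed-width sliding window rather than data-dependent block calling;
and the scan produces hundreds of thousands of strongly overlapping,
correlated tests, so a Bonferroni correction on the raw window count is
badly conservative.

`hapslide` implements the full pipeline for unphased case-control SNP
data: quality control, E-M haplotype dosage inference within sliding
windows, covariate-adjusted logistic association tests, permutation-based
calibration of the effective number of independent tests, and exhaustive
follow-up of hit regions. A synthetic-cohort generator with exact ground
truth backs every stage with tests.

# The model

## Haplotype dosages by E-M

Within a window of $w$ consecutive SNPs, let $f_h$ be the population
frequency of haplotype $h$ and let $n_h(H)\in\{0,1,2\}$ count copies of
$h$ in an individual's (unobserved) haplotype pair $H$. Under
Hardy-Weinberg equilibrium the pair $(h_1,h_2)$ has probability
$f_{h_1}f_{h_2}$ (doubled when $h_1\neq h_2$). Given the unphased
genotype $G$, the E-step computes the expected dosage

$$ \hat n_h = E[n_h \mid G] \;=\;
\frac{\sum_{(h_1,h_2)\sim G} n_h(h_1,h_2)\, f_{h_1} f_{h_2}\,
      2^{[h_1\neq h_2]}}
     {\sum_{(h_1,h_2)\sim G} f_{h_1} f_{h_2}\, 2^{[h_1\neq h_2]}} $$

where the sums run over pairs compatible with $G$; the M-step re-estimates
$f_h$ as the mean expected dosage over individuals divided by two. Cases
and controls are pooled for inference. A genotype with $m$ heterozygous
sites has $2^{m-1}$ compatible pairs; missing sites are expanded over all
three genotype completions, so no sample is discarded for sporadic
missingness.

## Expectation-substitution association tests

The fitted dosages substitute for the unknown true counts in logistic
regression with covariates $X$ (age, study indicators, ancestry
eigenvectors in the motivating design):

* **haplotype-specific test** — a 1-df Wald test of the dosage
  coefficient in $\text{logit}\,P(Y=1) = \alpha + \beta \hat n_h + X\gamma$,
  reported as a per-copy odds ratio $e^{\hat\beta}$ with a symmetric 95%
  interval (a likelihood-ratio version is available);
* **global test** — haplotypes with frequency strictly above 1% are
  retained, the most frequent is the reference, and the remaining $k-1$
  dosage columns are tested jointly against the covariates-only model by
  a likelihood ratio on $k-1$ df;
* **SNP-adjusted test** — a 1-df LR test of the haplotype dosage in a
  model that also carries additively coded genotypes of chosen SNPs
  (the best constituent SNP, known risk variants), quantifying whether
  the haplotype signal is reducible to single-marker effects.

## Calibrating genome-wide significance

Case-control labels are permuted $B$ times (case counts preserved); the
E-M dosages are phenotype-free and computed once, and every window's
global test is refit per replicate. The minimum p-value per replicate is
recorded. If $n_\text{eff}$ independent tests were performed, the minimum
of $n_\text{eff}$ uniform p-values follows $\text{Beta}(1, n_\text{eff})$,
so three estimates are reported: the empirical 5th percentile $t$ of the
minima inverted as $0.05/t$ (with the exact inversion
$\log(0.95)/\log(1-t)$ alongside), the constrained maximum-likelihood fit
of $\text{Beta}(1, b)$ (closed form $\hat b = -n / \sum\log(1-p_i)$), and
the half-of-windows heuristic. EDF goodness-of-fit statistics
(Kolmogorov-Smirnov, Cramér-von Mises, Anderson-Darling) check the beta
fit. The genome-wide level is $0.05/(\tfrac12 \times \text{total
windows})$ under the half heuristic.

## Region follow-up

Scan hits are extended by half their width on each side, then every
contiguous run of 2-10 SNPs in the extended region is fitted by E-M and
every haplotype above 1% frequency is tested, ranked by unadjusted
p-value (ties: longer haplotype, then allele string). The top hit is
verified by the SNP-adjusted LR test against its best constituent SNP
(optionally the regionally best SNP, and any index SNPs in known risk
regions, with ±250 kb default flanks and per-region overrides). When
local-ancestry posteriors are available, the mean expected
European-allele dosage over the hit's constituent SNPs is appended as a
covariate and the adjusted test rerun.

# A small worked example

```{r example, eval = FALSE}
pool <- generateHaplotypePool(5, 8, seed = 7)
model <- DiseaseModel(riskHaplotype = poolHaplotypes(pool)[1],
                      riskStart = 1, betaH = log(1.8))
cohort <- generateCohort(pool, 1000, 1000, model, seed = 1)
gm <- cohortGenotypes(cohort)
scan <- scanChromosome(gm)
scan[which.min(scan$p_global), ]
pr <- permutationMinP(gm, B = 200, seed = 2)
calibrateScan(pr, totalWindowsGenome = 1006392)
```

# Parameters that matter

| parameter | default | meaning |
|---|---|---|
| window size `w` | 5 SNPs | fixed-width block proxy; 5 matches typical African-ancestry LD block spans at ~1M-SNP density |
| `freqThreshold` | 0.01 | haplotypes with frequency strictly above 1% are "common"; the rest are discarded to save df |
| `minCallRate` (sample, SNP) | 0.95 | strict `<` removal; ties at exactly 95% are kept |
| `minMaf` | 0.01 | computed on pooled cases+controls, non-missing calls, after sample QC |
| HWE flag threshold | 1e-6 | exact-test screen; flags are reported, never removed (admixture legitimately distorts HWE) |
| E-M `tol`, `maxIter` | 1e-8, 1000 | max absolute frequency change; dosages are stable to ~1e-6 at this tolerance |
| follow-up `lenMin..lenMax` | 2..10 | haplotype lengths searched exhaustively in extended regions |
| permutation `B` | 1000 | replicates; the 5th-percentile threshold has ~0.7% relative Monte-Carlo error at B=1000 |
| `flank` | 250 kb | known-region neighborhoods; per-region overrides for long-range-LD regions (e.g. 2 Mb) |

# Numerical choices

* **E-M initialization.** Frequencies start at the product of observed
  per-SNP allele frequencies, lightly smoothed so every compatible
  haplotype has positive mass, plus a tiny deterministic tilt
  ($10^{-3}$, quadratic in the haplotype string's lexicographic rank).
  The tilt exists because the exact product start can sit on a
  phase-symmetry saddle of the likelihood (two phase configurations
  exactly balanced), where the iteration stalls below the maximum; the
  tilt is canonical in the haplotype labels, so results do not depend on
  sample order and no random restarts are needed.
* **Underflow guards.** Frequencies are floored at $10^{-150}$ during
  iteration (far below the $10^{-12}$ pruning threshold) so that pair
  weights of rare-pattern samples cannot underflow to exact zero, and
  dosage rows are rescaled to sum exactly 2 after pruning.
* **Logistic fits.** Newton scoring with step-halving in compiled code;
  convergence at $|\Delta\ell| < 10^{-8}$, cap 50 iterations;
  quasi-complete separation is flagged when any coefficient passes 30 in
  absolute value. Rank-deficient designs are an error naming the
  redundant column; a dosage collinear with its adjustment SNPs yields an
  LR statistic of 0 with a collinearity note rather than a spurious
  p-value. The observed scan and the permutation scan share one code
  path (the observed labels are just one more "replicate"), so
  permutation minima are bit-identical to per-replicate recomputation.
* **Beta MLE.** Closed form under the $a=1$ constraint; otherwise Newton
  on the digamma score equations from a method-of-moments start with a
  quasi-Newton fallback. EDF p-values use the fully-specified-null
  asymptotics: `ks.test` for D, the classical Bessel-series law for
  W², and the Marsaglia-Marsaglia polynomial for A².
* **Degenerate windows.** Monomorphic windows, windows with fewer than
  two common haplotypes (df 0), and fit failures are reported with a
  status flag and excluded from permutation minima; they never abort a
  scan.
* **Percentile convention.** The threshold is the order statistic at
  `ceiling(0.05 * B)` of the ascending minima; `neffHalf` rounds half
  away from zero (15,645 windows → 7,823).

# What the synthetic cohorts emulate — and what they do not

The generator draws haplotype pairs from a finite pool under HWE
(block-structured LD with exact ground truth), assigns disease by a
logistic model with an additive per-copy effect of a designated risk
haplotype plus optional covariate effects, and fills case/control quotas
by rejection sampling, mirroring a fixed case-control design. Covariates
are age ~ U(35, 75), a nine-level study factor with the motivating
cohort's relative sizes, and ten standard-normal eigenvector stand-ins.
Long chromosomes concatenate independent block pools (a single pool
cannot represent thousands of SNPs); the admixture generator makes each
chromosome copy a Markov mosaic over two pools with per-Mb switch rate
and records the true local-ancestry posteriors as indicator triples.

Deliberately not modelled: realistic recombination maps and mutation,
empirical LD decay between blocks, genotyping error, imputation
uncertainty, and continuous (uncertain) local-ancestry posteriors.
Passing tests therefore demonstrate correctness of the inference and
calibration machinery under the stated generative model, not performance
on any particular real cohort; in particular the beta-fit consistency of
permutation minima is checked on independent-SNP chromosomes, where the
small-sample behaviour of the likelihood-ratio test is benign.

# Validation problem sizes

The packaged tests exercise: exact enumeration oracles for pair
compatibility and the HWE test (all tables to total 25 plus larger
spot checks); grid-search/optimizer oracles for the E-M maximum on 2-3
SNP toys; null calibration of both tests at 500 replicates of n = 2,000;
constrained-MLE recovery of block sizes 10, 100 and 7,823 from 2,000
minima; recovery of a planted per-copy OR of 1.79 at haplotype frequency
0.03 with n = 5,700 over 100 seeds; and an end-to-end run on a 2,000-SNP
chromosome (250 eight-SNP blocks, one causal block with a 0.20-frequency
risk sub-haplotype at OR 1.8, n = 2,000, B = 200 permutations). These
sizes were chosen as the smallest designs that leave the Monte-Carlo
error well inside each assertion's tolerance.

# Known limitations

* Expectation-substitution slightly attenuates large haplotype effects
  relative to joint ML estimation of frequencies and effects; the global
  test's chi-square approximation degrades at small n with many rare
  haplotypes (hence the 1% discard).
* The E-M enumeration is exponential in the number of ambiguous sites;
  this is immaterial at w ≤ 10 but the implementation caps compatible
  pairs at 2^20 per sample and drops (and reports) samples beyond it.
* Windows with a single common haplotype cannot be tested (df 0); they
  are reported, not interpolated.
* The half-of-windows heuristic is a transferable default calibrated for
  ~1M-SNP arrays and 5-SNP windows in admixed cohorts; for other designs
  the permutation machinery should be rerun.
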