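---
title: "Methods: germline CNV discovery and case-control risk association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: germline CNV discovery and case-control risk association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

cnvrisk implements a complete case-control analysis of germline copy-number
variants (CNVs) discovered from SNP-array intensity data: dual-decoder hidden
Markov model (HMM) calling from log R ratio (LRR) and B allele frequency
(BAF) signals, stringent quality control with dual-caller consensus, CNV
region (CNVR) clustering, per-individual burden regression, and in silico
CNVR genotyping with a joint mixture--logit likelihood-ratio risk test. This
vignette is the package's account of the underlying models, the tunable
parameters, the numerical choices, and what the synthetic-data generator can
and cannot tell you about real data.

## Signal model

A SNP array reports, per probe, the log ratio of observed to expected
intensity (LRR) and the allelic intensity fraction (BAF). Negative LRR
deviations suggest a deletion, positive ones a duplication; BAF clusters in
bands whose positions depend on the allelic composition: at copy number $c$
with $b$ copies of the B allele the band sits at $b/c$. The package fixes the
canonical LRR state means

$$\mu = \{0\!: -3.5,\; 1\!: -0.66,\; 2\!: 0,\; 3\!: +0.40,\; 4\!: +0.68\},$$

values conventional for Illumina-style arrays. They anchor the simulator and
the caller jointly: nothing downstream assumes them beyond `state_mean_lrr()`
and the `hmm_model()` defaults, and both are tunable.

## The HMM caller

The caller is a five-state HMM over copy numbers 0--4.

* **Emissions.** LRR is Gaussian around $\mu_c$ with per-state standard
  deviations (default $0.15 \times \{2.0, 1.3, 1.0, 1.1, 1.2\}$; homozygous
  deletions are noisier). BAF is a mixture over the canonical bands
  $b/c$, $b = 0..c$, weighted by $\mathrm{Binomial}(c, \mathrm{pfb})$
  genotype frequencies -- pfb is the population B-allele frequency from the
  probe map -- with truncated-Gaussian band noise (default SD 0.04). A small
  uniform outlier component (weight 0.01 over LRR $[-5, 5]$) absorbs isolated
  artifacts. Copy number 0 carries no allelic signal; missing BAF contributes
  the LRR factor only.
* **Transitions.** The probability of changing state grows with the physical
  distance $d$ between adjacent probes: off-diagonal mass
  $(1 - p_0)(1 - e^{-d/D})$ with $p_0 = 0.999$ and $D = 100$ kb, shared among
  destination states in proportion to a prior that strongly favours the
  diploid state (weight 0.99). Calls never span chromosome boundaries.
* **Two decoders, one model.** "Caller A" decodes the maximum a posteriori
  state path (Viterbi; ties broken toward the lower copy number for
  determinism). "Caller B" computes forward--backward posteriors and calls
  runs of non-diploid per-probe MAP states whose mean posterior is at least
  0.5. Real dual-algorithm pipelines use two external tools whose internals
  differ in undocumented ways; realizing the two "algorithms" as two decoders
  of one fully specified family preserves the dual-caller consensus semantics
  while keeping every computation testable -- the package's own design
  choice, made because an HMM decoder pair is the strongest fully
  reproducible analogue.
* **Confidence.** Each call carries a log10 Bayes-factor score: the summed
  per-probe emission log-likelihood ratio of the called state against the
  diploid state. It is additive over probe subsets and non-positive when a
  call is claimed over truly diploid probes.
* **GC waves.** Before decoding, `gc_correct()` removes the least-squares
  quadratic fit of LRR on probe GC fraction and restores the sample's global
  mean. A quadratic captures the smooth, monotone-in-GC drift that wave
  artifacts show; missing values are excluded from the fit and passed
  through.

All decoding is in log space. On instances small enough to enumerate every
$5^n$ path, Viterbi agrees exactly with exhaustive maximization (the test
suite checks 200 random instances up to 8 probes; enumeration beyond that is
infeasible at $5^{12} \approx 2.4\times10^8$ paths).

## Quality control and consensus

Sample-level QC excludes samples with LRR SD, BAF SD (computed on the open
heterozygous band $(0.25, 0.75)$, so homozygous bands do not dilute it), or
total call count above thresholds; all inequalities are strict, so a sample
exactly at a threshold passes. Two fixed profiles ship -- caller A: 0.28 /
0.13 / 124 with call-level filters of 5 kb and 5 probes; caller B: 0.21 /
0.102 / 160 with a logBF $\ge$ 15 filter -- and `derive_threshold()` lets a
user recompute cohort-specific cutoffs as mean $+ k \times$ IQR (quartiles by
the common type-7 linear interpolation; the convention matters little but is
fixed for reproducibility).

Technical duplicate pairs are resolved before QC by keeping the member with
the lower LRR SD; "lower LRR" is read as the noise metric used everywhere
else in sample QC, with exact ties going to the lexicographically smaller
sample id.

Consensus retains only calls made in the same individual by both decoders:
calls of the same sample and type overlapping by at least 1 bp are pooled
transitively, and each pool seen by both callers becomes one merged call
spanning the smallest start to the largest end. Requiring only positional
overlap (rather than a reciprocal fraction) is deliberately permissive; a
stricter threshold can be imposed downstream through the CNVR clustering
threshold. Merged copy number is the member state most extreme in the shared
direction; confidence is the minimum of the members, a conservative choice.

## CNVRs

Calls across samples are clustered into CNV regions: an edge joins two calls
whose *mutual* overlap -- the smaller of the two reciprocal fractions -- is
at least 0.40, and CNVRs are the connected components (single linkage), with
"relaxed" boundaries (min start, max end of members). Single linkage is the
least-surprising closure of "members of the same cluster" when the
clustering is described only as iterative; the suite checks it against a
quadratic all-pairs oracle and checks that raising the threshold only ever
refines the partition. Deletions and duplications cluster together (regions
with both are classified *multiallelic*); type only affects classification.
A CNVR with exactly one member is a *singleton*, the working proxy for rare
or de novo variation.

Reference-locus annotation (`annotate_overlap()`) is one-directional by
design -- the question "was this CNV previously reported?" asks what fraction
of the *query* is covered -- with a 40% default threshold and an optional
same-type requirement.

## CNV burden

Burden is the per-individual count of QC-passing consensus calls (all /
deletions / duplications; optionally singletons only). Count-based burden is
the primary metric; length- and gene-based variants exist in the literature
but are deliberately out of the default path. Technical factors (DNA source,
platform, batch, age, gender) are screened by univariate OLS of burden on
each factor; factors with any level at $p < 0.1$ are carried as covariates
into the multivariate logistic model. Burden association is a logistic
regression of status on burden; the per-unit odds ratio and 1-df Wald test
are reported for univariate and covariate-adjusted models, over the subgroup
grid (all samples; cases with a family history vs all controls; cases
diagnosed at $\le 50$ vs controls aged $\le 50$). Age always enters models
continuously. Logistic fits use `glm` (iteratively reweighted least squares)
with tolerance $10^{-8}$ and a 100-iteration cap; non-convergence and
zero-variance predictors are explicit error states, never silent estimates.

## In silico CNVR genotyping and the risk LRT

For each CNVR the in-region probe intensities are summarized per sample by
the row mean or by the first principal component (sign-aligned to correlate
positively with the row mean). The scores are modelled as a $K$-component
Gaussian mixture whose components are integer copy-number classes:

* mean models: *free*, or *proportional* ($\mu_k = a + b\,c_k$ for
  consecutive integers $c_k$);
* variance models: *free*, *proportional*
  ($\sigma^2_k = s\,(c_k + \tfrac12)$, the $+\tfrac12$ floor keeping copy
  number 0 at positive variance), or *constant*.

EM is initialized from a $K$-quantile split plus seed-jittered restarts, runs
to a $10^{-8}$ relative log-likelihood tolerance (cap 500 iterations),
asserts a non-decreasing likelihood every iteration, and treats component
collapse (weight below $1/n$ or vanishing variance) as a failed start. Model
selection minimizes BIC over the $(K, \text{mean}, \text{var})$ grid among
converged fits, breaking exact ties toward smaller $K$ and simpler models.
Where an interactive analysis would add "subjective visual assessment",
the package substitutes the BIC plus convergence/collapse screens and
explicit exclusion reasons, and emits a diagnostic plot per locus
(`autoplot()` on the fit) for human review that never gates the automation.
Copy-number labels are anchored by declaring the modal component copy number
2 with consecutive neighbours -- the only convention that gives "per-copy"
effects a consistent sign without external information. For the proportional
models the provisional anchoring from the initial occupancy is held fixed
during EM (the constraint needs concrete $c_k$); reported labels are
re-anchored at the converged weights. Loci observed in fewer than two
samples, or where every grid cell fails, are excluded with a recorded reason
rather than force-fitted.

Association is tested by jointly maximizing

$$L = \prod_i \sum_k \pi_k\, N(x_i;\, \mu_k, \sigma^2_k)\,
\mathrm{Bern}\!\left(y_i;\, \mathrm{logit}^{-1}(\alpha + \beta c_k)\right)$$

with and without the constraint $\beta = 0$; under the null the Bernoulli
factor separates and $\hat\alpha = \mathrm{logit}(\bar y)$ exactly. The
statistic $2(\ell_1 - \ell_0)$, floored at zero, is referred to
$\chi^2_1$ -- the reference the two-stage testing tradition prescribes, used
here as such; the test suite verifies calibration empirically on 500
simulated null loci. Covariates stay out of the joint model and enter only
the follow-up logistic regression of status on posterior-modal copy number,
which reports the per-copy OR, 95% Wald interval and 1-df Wald p. Bonferroni
bookkeeping divides the family-wise level by the number of *tested* (not
excluded) loci.

## SNP-level cohort statistics

SNP QC drops markers with call rate below 95%, minor allele frequency below
5%, or Hardy--Weinberg exact p below $10^{-7}$ in controls (strict
inequalities). The HWE test is the standard exact conditional test: given
allele counts, heterozygote counts are hypergeometric, and the two-sided p
sums outcomes no more probable than the observed one (mid-p off), computed by
the het-count recurrence and verified in the tests against an independent
log-factorial enumeration over every table with $n \le 50$. Ancestry
covariates come from a plain standardized-genotype PCA (per-SNP mean
imputation, centring, $\sqrt{2p(1-p)}$ scaling, SVD, deterministic sign);
the downstream contract is only "top four principal components", so no
outlier-removal machinery is layered on top.

Fisher's exact test for cohort-characteristics tables uses, for 2x2 tables,
the *doubling* convention -- twice the smaller one-sided hypergeometric tail,
capped at 1 -- as the default two-sided rule, with the sum-of-small-
probabilities rule available via `two_sided = "minlike"`. The doubling rule
is the convention under which the package reproduces published
cohort-characteristics p-values at their printed rounding; the two rules
genuinely differ (0.0026 vs 0.0022 on the gender table), and the choice is
surfaced as an argument rather than buried. Larger tables use the exact
network algorithm where feasible and Monte Carlo (with reported standard
error) beyond that.

## The synthetic cohort generator

`simulate_cohort()` emulates the statistical structure the analysis assumes:
probe maps with exponential inter-probe gaps, a smooth GC track in
$[0.3, 0.7]$, common CNVRs at configured carrier frequencies, private
singleton CNVs (Poisson per sample, collision-checked so they stay private),
canonical LRR shifts and BAF bands with per-sample noise heterogeneity,
additive batch-specific GC waves, a platform noise multiplier, technical
duplicate pairs (same truth, fresh noise), and an optional risk locus with a
per-copy log-odds effect under retrospective sampling: a larger source
population is simulated, disease is drawn with probability
$\mathrm{logit}^{-1}(\alpha + \beta c)$ ($\alpha$ anchored so a diploid
individual is at 0.5), and the fixed case/control counts are sampled without
replacement -- the design of a hospital-based case-control study.

Defaults are fixed to the conditions of a typical hospital-based
pancreatic-cancer case-control array study: 223 cases and 169
controls plus 10 duplicate pairs, 28 batches, platform mix of 35.4% / 10.7%
quad among cases / controls, Table-2-like gender, family-history and DNA
source margins, and a singleton rate of 0.96 per sample. The probe map
defaults to 30,000 probes over 4 chromosomes at 8 kb mean spacing -- a
desk-scale stand-in for a 370k genome-wide array chosen so a full cohort
simulates in seconds; spacing, not total count, is what the
distance-dependent transitions actually see. Per-sample LRR noise defaults to
$U(0.10, 0.20)$, below the sample-QC exclusion thresholds, and batch GC-wave
amplitudes span 0.02--0.12. The additive GC-wave mechanism is one plausible
generative form for batch effects on call rate; real batch effects are not
known to be additive in GC, and this is flagged as a modelling choice, not a
claim.

**What passing tests do and do not show.** The generator draws noise
independently per probe; real arrays have autocorrelated noise, probe-specific
biases, mosaicism and LOH-without-copy-change states, none of which are
simulated (X/Y chromosomes are likewise out of scope). Caller recovery
figures on synthetic cohorts (sensitivity and precision $\ge 0.90$ for
$\ge$10-probe events at LRR SD $\le 0.20$) therefore bound performance under
the model's own assumptions, not on any particular real platform.

## Problem sizes used in the checks

The test suite and the acceptance script size their simulations as follows,
as the package's own evaluation design: caller recovery on 50 samples by
30,000 probes; Viterbi-vs-enumeration on 200 instances of 2--8 probes; LRT
calibration on 500 null loci of 400 samples; CI coverage on 100 seeds at
n = 2000; clustering-vs-oracle on 200 random call sets of up to 60 calls;
HWE-vs-enumeration over all 23,425 genotype tables with $n \le 50$.

## Known limitations

* The two decoders share one emission/transition family, so consensus
  filters decoder disagreement, not model misspecification.
* Mixture genotyping assumes Gaussian within-class scores; heavy batch
  structure inside a locus can masquerade as extra components (batch effects
  are not modelled inside the mixture).
* The $\chi^2_1$ reference for the joint LRT ignores boundary/label
  subtleties of mixtures; the package follows the established two-stage
  testing convention and verifies calibration empirically instead.
* `cluster_cnvrs()` sorts chromosomes lexicographically; with more than nine
  autosomes "chr10" sorts before "chr2", which affects display order only.
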