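---
title: "Models and methods: cis/trans divergence and imprinting from reciprocal hybrids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: cis/trans divergence and imprinting from reciprocal hybrids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybridase)
library(dplyr)
```

## The study design and the observation model

The reciprocal-hybrid design has six sample classes: two F0 homozygote
classes (`F0_B6`, `F0_CAST`, measured as total gene expression) and the
two alleles of each of the two reciprocal F1 crosses (`F1i_B`, `F1i_C`
for the B6♂ × Cast♀ cross, `F1r_B`, `F1r_C` for the reciprocal), each with
biological replicates (3 by default). Probabilistic quantification of
allele-specific expression yields, per gene × sample × allele, a
posterior mean of the natural-log expression parameter and its posterior
standard deviation. `hybridase` takes these summaries at face value:

$$ y_{gr} \sim \mathcal{N}(\mu_{g(r)},\ s_{gr}^2 + \sigma^2_\text{res}), $$

where $s_{gr}$ is the reported posterior sd and $\sigma_\text{res}$
(default 0, `prior_config(residual_sd = )`) is optional extra gene-level
noise added in quadrature. This known-variance Gaussian formulation is a
deliberate approximation of full hierarchical model-comparison machinery:
it buys exact, closed-form marginal likelihoods that can be verified
against independent numerical oracles. The cost is that genome-wide
tallies from any particular study (numbers of classified or excluded
genes) are not expected to reproduce exactly, because those depend on the
original tool's prior and variance-sharing scheme, which is not part of
this package's contract.

## Mean structures and priors

Let $\delta_0$ be the F0 strain effect (Cast − B6, log-e) and $\delta_1$
the F1 allelic effect (Cast allele − B6 allele, both crosses pooled).
The four regulatory models constrain the pair
$(\delta_0, \delta_1)$: conserved fixes both at 0; *cis* ties
$\delta_0 = \delta_1$ to one free effect; *trans* frees $\delta_0$ with
$\delta_1 = 0$; *cis and trans* frees both. Separate free baselines for
the F0 level and the F1 allele level absorb the ploidy/sequencing-depth
offset between total and allele-specific expression, so only
within-dataset differences carry information.

Baselines get $\mathcal{N}(0, 10^2)$ priors and effects
$\mathcal{N}(0, 1^2)$ (log-e), all exposed in `prior_config()`. The
vagueness contract (`baseline_prior_sd >= 10 * effect_prior_sd`) keeps the
comparison driven by differences rather than absolute levels. Two
consequences worth knowing:

* With a *proper* baseline prior, Bayes factors retain a residual
  dependence on the absolute expression level: shifting all observations
  of a gene by 5 log-e units moves log-marginal *differences* by about
  0.01 at the default sd 10. This is immaterial for classification (the
  decision thresholds are at odds of 2:1) and vanishes in the vague
  limit — the test suite demonstrates 1e-6 invariance at baseline sd 3000.
* The effect prior sd of 1 (log-e ≈ 1.44 log2) spans severalfold
  divergence. Halving or doubling it shifts individual Bayes factors and
  moves genes near the confidence thresholds; `prior_config()` makes
  re-running the benchmark under an alternative prior a one-line
  sensitivity check.

Marginal likelihoods are the density of
$y \sim \mathcal{N}(0, XVX^\top + \Sigma)$ evaluated by Cholesky
factorization; a singular covariance (degenerate prior) is an explicit
error, not a silent regularization. Posterior model probabilities are
computed in log space with max subtraction under equal 0.25 priors, and a
gene is confidently classified only if the winner exceeds posterior 0.5
and twice the runner-up; otherwise it is reported `unclassified` with
reason `low_confidence`.

## Imprinting detection and the order of operations

On the four F1 series only, the null model shares one allelic difference
$d$ across crosses, while the imprinting model sets $d_i = +m$,
$d_r = -m$: equal magnitude, opposite sign. Because the Cast allele is
the maternal allele in the B6♂ × Cast♀ cross, the sign of the posterior
mean of $m$ (maternal − paternal) gives the parental direction. Tier
labels follow the Bayes factor: ≥ 30 extreme, ≥ 10 high, > 3 possible.
The exclusion boundary is strict (> 3); BF = 3 exactly survives.

Exclusion runs in a fixed order — non-polymorphic genes (no
allele-resolved F1 data at all), then imprinting BF > 3, then incomplete
group data, then the confidence rule — so every gene carries exactly one
`excluded_reason` and headline denominators are auditable. The two model
families make opposite sign conventions testable: a pure cis pattern
($d_i = d_r \ne 0$) *favours the null*, so cis divergence does not leak
into the imprinting scan, and conversely imprinted genes are removed
before the cis/trans comparison, where their sign-flipped alleles would
otherwise masquerade as conserved or spurious cis calls. Note that the
null/imprinting pair are equally complex (one free effect each), so under
truly conserved data the Bayes factor has no Occam penalty in either
direction; a small fraction of null genes exceeds BF 3 by chance at 3
replicates (the tests bound it), which is precisely why the filter
threshold is an exclusion tier and not a discovery claim. That false-positive fringe shrinks with
replicates (a property test asserts this).

## Weighted fold changes and subcategories

Effect sizes are reported as inverse-posterior-variance weighted means of
the replicate log-e parameters, differenced between strains/alleles and
converted to log2 at a single point:
$x$ from the pooled F1 Cast vs B6 alleles, $y$ from the F0 strains. For
genes classified *cis and trans*, the joint geometry of $(x, y)$
subcategorizes the interaction: opposite signs of the cis component $x$
and implied trans component $y - x$ stabilize expression
(`CIS_minus_trans` when $xy > 0,\ |x| > |y|$; `TRANS_minus_cis` when
$xy < 0$), same signs shift it further (`CIS_plus_trans` when
$|x| < |y| < 2|x|$; `TRANS_plus_cis` when $|y| > 2|x|$). The defining
inequalities are open: points with $xy = 0$, $|x| = |y|$ or $|y| = 2|x|$
receive an explicit `boundary` label rather than a forced bin — measure
zero in theory, but reachable with rounded imported values, and
transparency beats silent tie-breaking.

```{r subcat-demo}
subcategorize(c(0.8, 0.5, 0.5, 0.3), c(0.4, -0.3, 0.7, 0.9))
```

## The synthetic-data generator

`simulate_expression()` emulates the statistical structure of the design,
not its sequencing physics: Gaussian log-e observations around group
means built additively from a gene baseline, $\delta_0$, $\delta_1$ and a
signed imprinting effect $m$, with the generating sd reported as the
posterior sd (the well-calibrated case; `sd_miscalibration_factor`
breaks calibration deliberately). Defaults encode the study conditions:
3 replicates per class, 1 log2 effect magnitudes with random signs
(severalfold divergence is what the design reliably detects), measurement
sd 0.15 log-e (giving replicate-concordance correlations in the
0.9–0.99 range typical of good bulk libraries), baselines uniform on
1–6 log-e, and a scenario mix of 55% conserved, 25% cis, 8% trans, 6%
cis-and-trans, 3% + 3% imprinted — the retina-like proportions with the
imprinting branch inflated enough to exercise it. F0 and F1 baselines are
drawn independently (each F1 allele carries roughly half the diploid
signal; all inference uses differences, so absolute offsets are free).
Non-polymorphic genes emit F0 rows only and must be excluded upstream,
mirroring the real pipeline's polymorphism filter.

What the generator does *not* emulate — read-mapping bias toward the
reference allele, transcript-level ambiguity, count overdispersion
beyond the reported variance, correlated replicates — bounds what a
passing benchmark shows: it validates the inferential machinery under
its own assumptions, not robustness to quantification artifacts.

`simulate_annotation()` lays the genes on one toy chromosome, plants 0–3
peaks per gene (gene body or within 1 kb of the TSS) and draws variants
at a uniform background rate (5/kb) plus a top-up to 10/kb inside the
central kb of peaks linked to true-cis genes. Because peaks of the same
gene may overlap, recovered central-kb densities slightly exceed the
nominal planting rate; the enrichment contrast, not the absolute rate, is
the designed-in signal. Each peak records the gene it was planted in,
giving the assignment ground truth.

## Annotation-side conventions

* Peak-to-gene assignment tests containment on the **peak center** (not
  any-overlap), which makes assignment total and unambiguous for
  span-straddling peaks; non-contained peaks go to the nearest TSS on the
  same chromosome. Equidistant TSSs and overlapping containing genes are
  broken toward the lexicographically smallest id and flagged
  `ambiguous`.
* All BED handling is 0-based half-open and VCF 1-based, with one
  conversion pair (`zero_to_one_based()` / `one_to_zero_based()`)
  property-tested for involution. Central windows are half-open
  $[c - 500, c + 500)$, so edge variants are counted exactly once.
  Indels are anchored at their VCF POS base.
* Sliding windows (50 bp, step 25, span 2 kb) give 79 windows; an
  interior variant is covered by exactly two windows, a span-edge variant
  by one — a conservation law the tests assert on random fixtures.
  Truncated windows at contig edges exclude the peak with a message.
* The variant-frequency enrichment test treats each **base pair** of the
  tabulated central windows as one hypergeometric draw unit
  ($N$ = total bp, $K$ = total variants, $n$ = subset bp): a coarser
  per-kilobase unit would put more "successes" than draw units in the
  population at realistic densities (≈ 8 variants/kb) and the
  distribution would be undefined. The bp construction reproduces the
  qualitative published contrast — cis-linked windows significantly
  enriched, trans-linked not.
* Heterozygous or missing-genotype VCF records are dropped at read time
  with a counted message (homozygous-only is the correct filter for
  variants of an inbred strain), and every filtered record class is
  counted so denominators remain auditable.

## Numerical and degenerate-input policy

Log-space posterior normalization with max subtraction; Cholesky-based
marginals erroring on singularity; genes with any missing group reported
`incomplete`, never imputed; empty subcategory sets reported absent
rather than NaN-propagated; Fisher's exact test two-tailed by the
probability-mass rule with a 1e-7 tie tolerance, summed exhaustively
(bit-stable and checkable against enumeration); zero-variance samples in
concordance matrices yield `NA` with a warning.

## Problem sizes and verification

The test suite verifies the closed-form marginals against a
prior-sampling Monte-Carlo oracle (50 random instances within 3 MC
standard errors, plus 1-D quadrature on the baseline-only case), the
exact tests against choose()-based enumeration, and the recovery
benchmark at the study operating point: 2,000 genes × 3 replicates,
1 log2 effects, sd 0.15 — where ≥ 85% of confidently classified genes
match truth (observed ≈ 98%), imprinting direction is recovered for all
truly imprinted genes at BF ≥ 30, and no excluded gene re-enters the
four-way classification. These sizes keep the whole suite comfortably
under a few minutes on one core while leaving the asymptotic claims to
the property tests.

## Known limitations

The known-variance Gaussian formulation ignores uncertainty in the
reported posterior sds; the generator draws effect magnitudes at a fixed
scale by default (use `effect_distribution = "half_normal"` for a
continuum, which is also what the misclassification-at-small-effects test
uses); the imprinting model assumes strict magnitude symmetry between
crosses, so partially polymorphic transcripts with cross-specific
coverage would dilute the Bayes factor; and cross-tissue comparison
assumes both tissues were classified by this same pipeline — mixing
classifiers invalidates the comparability rule.
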