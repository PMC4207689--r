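# hybridase

Dissecting *cis*- and *trans*-regulatory divergence and genomic imprinting
from allele-specific RNA-seq of F0 homozygotes and reciprocal F1 hybrids.

When two inbred strains (say C57BL/6J and Cast/EiJ) are crossed, both
alleles of every gene in the F1 hybrid sit in the same nucleus and see the
same *trans* environment. A *cis*-regulatory difference therefore shows up
as an allelic expression imbalance in the F1 that recapitulates the F0
strain ratio; a *trans* difference shows up as F0 divergence with balanced
F1 alleles; and a parent-of-origin (imprinting) effect flips the sign of
the allelic imbalance between the reciprocal crosses. `hybridase`
implements this dissection as a tidyverse-style pipeline for replicate-level
log-expression summaries (posterior mean and sd per gene × sample ×
allele, as produced by probabilistic quantifiers such as MMSEQ).

## The model

For gene *g*, observations are Gaussian on the natural-log scale with
known per-observation variance. Writing δ₀ for the F0 strain effect
(Cast − B6) and δ₁ for the F1 allelic effect, four models are compared:

| model | constraint |
|---|---|
| conserved | δ₀ = δ₁ = 0 |
| cis | δ₀ = δ₁ (one free effect) |
| trans | δ₁ = 0, δ₀ free |
| cis and trans | δ₀, δ₁ free |

Group baselines and free effects carry independent zero-mean Gaussian
priors and are integrated out in closed form, giving exact marginal
likelihoods. With equal prior probability 0.25 per model, a gene is
confidently classified when the winning posterior exceeds 0.5 **and** is
at least twice the second best. Before classification, genes with an
imprinting Bayes factor above 3 are excluded; the imprinting model
constrains the reciprocal-cross allelic differences to equal magnitude
and opposite sign (BF ≥ 10 "highly likely", ≥ 30 "extremely likely").
Effect sizes are summarized as inverse-posterior-variance weighted log2
fold changes *x* (F1 allelic) and *y* (F0 strain); genes divergent in both
*cis* and *trans* are subcategorized by the signs and magnitudes of
(*x*, *y*), e.g. *CIS−trans* when `x*y > 0 & |x| > |y|` (effects oppose,
*cis* stronger). Peak-to-gene assignment (containment, else nearest TSS),
sliding-window variant density, and hypergeometric enrichment connect the
classifications to candidate cis-regulatory elements.

## Worked example

```r
library(hybridase)

sim  <- simulate_expression(simulation_config(n_genes = 2000, seed = 83))
scan <- classify_imprinting(sim$measurements)
fit  <- classify_dataset(sim$measurements, imprinting = scan)
fit
#> Regulatory divergence classification
#>   genes analysed:       2000
#>   confidently classed:  1599
#>     conserved         838 (52%)
#>     cis               468 (29%)
#>     trans             160 (10%)
#>     cis_and_trans     133 (8%)
#>   excluded: imprinted_bf_gt_3 248, low_confidence 153

eff <- estimate_effects(sim$measurements, fit)
summarize_subcategories(eff)
plot_divergence(eff)          # x-vs-y scatter coloured by winning model
autoplot(scan)                # Bayes factor vs rank, tier thresholds
```

Of the 2,000 simulated genes, 1,599 are confidently classified; the
proportions track the generator's scenario mix (55% conserved, 25% cis,
…). The 248 excluded genes are those whose imprinting Bayes factor
exceeded 3 — the truly imprinted genes plus a small false-positive
fringe of conserved genes, which is exactly why the filter runs before
the four-way comparison. Checked against the known simulation truth,
about 98% of confident calls match their generating class.

The same functions consume real data via `read_expression_table()`,
`read_peaks_bed()`, `read_variants_vcf()` (homozygous genotypes only) and
`read_genes_tsv()`; a pipeline CLI is available through `ase_cli()` or
the `inst/exec/asepipe` script, e.g.
`asepipe all --out run1 --n-genes 500 --seed 7`.

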