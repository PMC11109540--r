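---
title: "Simulating genotyping error and its impact on kinship inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating genotyping error and its impact on kinship inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snperr)
```

## The error model

`snperr` models genotyping error as a per-genotype categorical process over
the diploid biallelic states. Every genotype of the designated target
sample is classified as `HOM_REF` (`0/0`), `HET` (`0/1` or `1/0`, either
phasing), `HOM_ALT` (`1/1`), `MISSING` (`./.`) or `OTHER` (anything else:
half calls, allele indices above 1, non-diploid calls). Each of the first
three classes has three directed error modes — to the two other called
classes and to missing — giving nine modes in total, named by source and
target allele content (`rarr` = het to hom-ref, `rraa` = hom-ref to
hom-alt, `aamm` = hom-alt to missing, and so on).

For a genotype of class $c$ with mode probabilities $p_{c,1}, p_{c,2},
p_{c,3}$, the injector makes **one** categorical draw over the four
outcomes $\{t_1, t_2, t_3, \text{stay}\}$ with
$P(\text{stay}) = 1 - \sum_k p_{c,k}$. This mutual-exclusivity design (one
draw, not three sequential coin flips) makes the per-class constraint
$\sum_k p_{c,k} \le 1$ natural and gives realized mode counts exact
$\text{Binomial}(n_c, p_{c,k})$ marginals over the $n_c$ eligible
genotypes. Specifications violating the constraint are rejected at
validation rather than renormalised — a spec that claims 60% drop-out and
60% drop-in of the same class is a user error, not a sampling problem.

Two deliberate asymmetries:

* `MISSING` is a sink. No mode resurrects a missing genotype, so missing
  inputs pass through unchanged and consume no randomness.
* `OTHER` genotypes are never touched. The model is defined over diploid
  biallelic states only; at a multiallelic record the target genotype is
  eligible only if both alleles are 0 or 1.

Rewritten genotypes are emitted as the canonical unphased representative
(`0/0`, `0/1`, `1/1`, `./.`); a drawn "stay" returns the input string
bit-identically, phase separator included. The error model defines class
transitions, not string transformations, so `1|0` mutated by `raaa`
becomes `1/1`, while an untouched `1|0` stays `1|0`.

## Streaming and reproducibility

Injection streams the VCF in bounded-size line chunks: memory is
proportional to the chunk size (default 20,000 records), not the file, so
whole-chromosome inputs are practical. One RNG stream consumes one uniform
draw per eligible genotype in file order; `(input, spec, seed)` therefore
fully determines the output file, and chunk size provably does not affect
the draws (tested). Only the GT subfield of the target sample's column is
ever rewritten — all other FORMAT subfields, all other samples, and all
fixed fields round-trip byte-for-byte. INFO annotations such as AC/AF are
*not* recomputed; consumers that re-derive allele frequencies from
genotypes should do so downstream.

## Concordance and NRC

The evaluator compares one sample between a truth and a query VCF over the
sites present in both (exact match on chromosome, position, REF and ALT;
allele-mismatched records are excluded and counted), optionally restricted
to a target-sites VCF. Counts are keyed on the *truth* class: $e_{rr}$,
$e_{ra}$, $e_{aa}$ are mismatches at truth hom-ref/het/hom-alt sites,
$m_{rr}$, $m_{ra}$, $m_{aa}$ the matches, and the full $4\times4$
truth-by-query transition matrix is tabulated alongside. Non-reference
concordance is

$$\mathrm{NRC} = 1 - \frac{e_{rr}+e_{ra}+e_{aa}}
{e_{rr}+e_{ra}+e_{aa}+m_{ra}+m_{aa}},$$

omitting $m_{rr}$ so that the typically vast count of concordant hom-ref
calls cannot mask error at informative genotypes. NRC is undefined (an
error, not NaN) when the denominator is zero.

Missing genotypes are a genuine policy choice in concordance tooling: by
default sites where either sample is missing are excluded from the $e/m$
counts (they remain visible in the transition matrix and the `excluded`
tally); with `missing_as_mismatch = TRUE` a missing query call at a
truth-called site counts as a mismatch of the truth class. Exclusion is
the default because a missing call carries no asserted genotype to be
wrong about; the mismatch policy is provided for pipelines that penalise
drop-out.

Because the injector reports realized per-mode counts and the evaluator
tabulates the truth-by-query matrix, the two tools close a validation
loop: the off-diagonal matrix cells of `concord(input, injected)` must
equal the injector's ledger *exactly*, for every mode including the
missingness modes. The test suite asserts this closure.

## Synthetic cohorts

Benchmark inputs are generated, not shipped. `simulate_founders()` draws a
per-site alternate allele frequency $f \sim U(0.05, 0.5)$ and founder
alleles as independent Bernoulli($f$) haplotypes, so genotypes follow the
Hardy–Weinberg law $\text{Binomial}(2, f)$. The lower MAF bound avoids
near-monomorphic sites that carry no kinship information; the upper bound
of 0.5 makes the alternate allele the minor allele throughout.
`gene_drop()` then transmits one uniformly chosen allele per parent per
site through the pedigree — Mendelian segregation with *unlinked* sites.

The simplification is intentional and has a precise justification: the
KING-robust estimator consumes only per-site genotype-class counts, whose
expectations depend on allele frequencies and kinship but not on linkage.
What linkage (and a realistic recombination map) would change is the
*variance* of the estimates — real data has fewer effective independent
sites — so passing tests here demonstrate correctness of the estimator and
the degradation mechanism, not the sampling variance a dense genotyping
array cohort with LD would show. The generator also omits population structure,
admixture and sex-specific transmission.

`build_benchmark_pedigree()` fixes an 18-member three-generation pedigree
around a focal individual: parents and a full sibling (1st degree),
paternal grandparents, an uncle and a half-sibling (2nd degree), two first
cousins (3rd degree), and eight unrelated or married-in founders. Truth
degrees are derived from the standard pedigree kinship recursion, not
hard-coded, and the truth labels map kinship $2^{-(d+1)}$ to degree $d$,
with anything beyond degree 3 labelled `UNRELATED`.

## Kinship estimation and the degradation sweep

Pairwise kinship uses the between-family KING-robust estimator

$$\hat\varphi = \frac{N_{\text{het,het}} - 2N_{\text{opp-hom}}}
{2\min(h_i, h_j)} + \frac12 - \frac{h_i + h_j}{4\min(h_i, h_j)},$$

over sites where both samples have called biallelic diploid genotypes;
$h_i$, $h_j$ are the samples' heterozygous-site counts. The estimator is
undefined when a sample has no heterozygous calls — in the sweep such a
pair is scored as misclassified, since no inference is possible. A
duplicated sample gives $\hat\varphi = 1/2$ exactly (algebraic identity,
asserted as such in the tests). Degrees are inferred with the standard
thresholds $2^{-(d+3/2)}$ (0.3536, 0.1768, 0.0884, 0.0442), the geometric
midpoints between expected kinships of adjacent degrees; the thresholds
are the conventional KING inference ranges, chosen here because no single
alternative is canonical.

`run_sweep()` reproduces the benchmark design: for each mode and each rate
on a grid (default 0 to 0.20 in 0.01 steps), inject that single mode into
the focal sample of the *clean* cohort — never cumulatively — re-estimate
kinship for every pair involving the focal sample, classify degrees, and
score accuracy against pedigree truth. The guessing floor reported
alongside is the accuracy of always predicting the most common truth
degree among the scored pairs, the natural floor for a degree classifier.

### Problem sizes

The default benchmark operates at 50,000 unlinked sites and 18
individuals (17 scored pairs). At that depth the binomial sampling noise
on $\hat\varphi$ (roughly 0.005 SD) is an order of magnitude below the
0.044 gap between adjacent degree thresholds, so clean-data degree
classification is reliably perfect through the third degree, and kinship
expectations $2^{-(d+1)}$ are recovered to well within 0.02 across
replicates. The test suite uses 300,000-site cohorts where a rate check
needs $\ge 10^5$ heterozygous genotypes and a one-million-site cohort to
exercise the streaming path.

## What error does to kinship: an asymmetry

Sweeping the modes reveals a strong asymmetry that is worth understanding
rather than merely observing. Hom-ref → hom-alt swaps (`rraa`) are
catastrophic: hom-ref is the largest genotype class, and every swap at a
site where a relative is also hom-ref manufactures a spurious
opposite-homozygote pair event. $N_{\text{opp-hom}}$ enters the estimator
with coefficient $-2$, so $\hat\varphi$ of true relatives collapses below
the unrelated threshold by ~10% error and accuracy falls to the guessing
floor.

The mirror-image swap `aarr` (hom-alt → hom-ref), by contrast, barely
moves $\hat\varphi$ under this generator's conditions. Converting a
focal-hom-alt site has two opposing effects: where the partner is hom-ref
it *removes* an existing opposite-homozygote event (the pair becomes
concordant hom-ref), and where the partner is hom-alt it *creates* one
(a concordant pair becomes opposite-homozygous). With the alternate allele
always the minor allele, partner-hom-ref sites are at least as common as
partner-hom-alt sites for weakly related pairs, so the two effects nearly
cancel: at a 20% `aarr` rate the measured shifts are about $-0.02$ for a
parent and $+0.01$ for an unrelated pair — never enough to cross a
threshold. In our sweeps `aarr` leaves degree accuracy at its clean
baseline even at 20% error while `rraa` destroys it, and the same
cancellation argument predicts `aarr` would become damaging only where
alternate alleles are frequently the major allele. Missingness modes
(`*mm`) mainly shrink the compared-site count and are the most benign;
het drop-out (`rarr`) degrades accuracy at intermediate rates by deflating
$N_{\text{het,het}}$ and the focal heterozygosity.

## Numerical and degenerate-input choices

* Class-sum validation uses a $10^{-12}$ slack so that probabilities
  summing to exactly 1 in floating point are accepted.
* Duplicate sample IDs in a VCF header are rejected as ambiguous rather
  than resolved positionally.
* Duplicate (chrom, pos) records are rejected by the concordance
  evaluator; sites present in only one file are simply not compared.
* Empty record streams are legal everywhere: a header-only VCF reads,
  writes and round-trips.
* A zero-rate sweep point is computed by the same injection path as any
  other rate (the draw is still made), so the rate-0 accuracy equalling
  the no-injection baseline is a verified property, not a shortcut.
* Writing to a path ending in `.gz` produces BGZF (tabix-indexable)
  output, not plain gzip.

## Known limitations

* The injector rewrites GT only; depth, quality and likelihood FORMAT
  fields of a corrupted genotype keep their original (now inconsistent)
  values, and INFO AC/AF are not updated.
* Error rates are global per mode — no per-site or frequency-dependent
  error maps.
* The synthetic cohorts have no LD, so absolute variances of kinship
  estimates are optimistic relative to an equal number of array sites;
  conclusions about *which* error modes harm inference, and the rate
  thresholds at which they do, transfer qualitatively rather than
  numerically to real array data.
* One sample is corrupted per pass; multi-sample error scenarios loop the
  injector externally (each pass leaves the other samples untouched, so
  passes compose).
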