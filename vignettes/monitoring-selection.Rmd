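---
title: "Monitoring short-term selection against a disease allele in a closed breed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monitoring short-term selection against a disease allele in a closed breed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(breedwatch)
library(dplyr)
```

## The problem

When breeders of a closed pedigree population start genotyping their animals
for a deleterious variant — here the canonical example is an autosomal
recessive disease allele segregating at high frequency in a dog breed — two
questions follow immediately:

1. **Is the observed decline in the allele real selection**, or could drift
   in a small breeding population produce it?
2. **Is the selection coming at a cost**: rising inbreeding, lost diversity,
   a shrinking effective population?

`breedwatch` implements the full analysis chain for both questions on
SNP-array data from two (or more) time-stamped cohorts: a sex-structured
Wright–Fisher drift null with empirical p-values, a per-SNP Weir–Cockerham
F_ST scan with EHH decay around the top hit, ROH-based inbreeding
(F_ROH) and observed heterozygosity, PCA / neighbor-joining / Nei's D
population structure, and LD-based contemporary Ne. A pedigree-aware
synthetic cohort generator reproduces the statistical structure of such a
breed so the whole chain is testable without any external data.

## The drift null

The question "could drift alone do this?" is answered by simulation rather
than formula because dog breeding has a strongly skewed sex ratio. With `Ne`
breeding animals of which a fraction `male_fraction` are sires, each
generation draws the next allele frequency as the average of two binomial
samples, one through each sex:

    q' = 1/2 [ Binomial(2 Nm, q)/(2 Nm) + Binomial(2 Nf, q)/(2 Nf) ]

with `Nm = round(male_fraction * Ne)` (round half up) and `Nf = Ne - Nm`.
This reproduces the classical unequal-sex-ratio variance effective size
`Ne_eff = 4 Nm Nf/(Nm + Nf)`: one generation of drift has variance
`q(1-q)/(2 Ne_eff)`. With the default sex ratio of 20% males, `Ne = 540`
gives `Nm = 108`, `Nf = 432`, `Ne_eff = 345.6` — drift is a third faster
than a naive census of the same size would suggest.

The sizing of `Ne` itself is deliberately simple: `breeding_ne()` takes a
registration census and a breeding fraction (default 10%, a standard figure
for companion-animal populations), so 5,395 registered dogs give a
large-model `Ne` of 540; a small model can use an LD-based estimate from the
data itself (`ld_ne()`).

The p-value is the *strict* lower tail: the fraction of simulated
trajectories strictly below the observed frequency, `p = #[q_sim < q_obs] /
replicates`, reported as `< 1/replicates` when no trajectory falls below.
Strictness matters only at ties, which are logged rather than split. The
default 10,000 replicates put the Monte-Carlo standard error of a p-value
near 0.05 at about 0.002. Significance is one-sided at 0.05 because only
the direction of selection (against the allele) is hypothesised.

```{r drift}
sim <- simulate_drift(ne = 540, q_start = 0.6, male_fraction = 0.2,
                      generations = 6, replicates = 10000)
tidy(sim)
empirical_p(sim, observed_q = c(0.45, 0.30), generation = c(3, 6))
```

`binom.test`-style exact Clopper–Pearson intervals accompany each observed
yearly frequency (`trend_ci()`); the binomial n counts chromosomes (2 per
dog) by default, switchable to dogs — the two conventions differ visibly
only at small cohort sizes.

## The selection scan

`wc_fst()` is the Weir & Cockerham (1984) per-SNP variance-components
estimator for two populations, computed on complete cases per SNP: sample
sizes `n_i`, allele frequencies `p_i` and observed heterozygote fractions
`h_i` per group enter the among-population (a), between-individual (b) and
within-individual (c) components, and `F_ST = a/(a+b+c)`. The estimator is
allowed its small negative values; SNPs where `a+b+c = 0` (monomorphic) are
undefined and excluded from ranking. `rank_scan()` flags the upper
`top_fraction` (default 0.1%) using a ceiling rule with all ties kept, so
143,013 SNPs yield 144 flagged.

EHH (`ehh()`) follows the classical definition: among the n phased
haplotypes carrying the core allele, the probability that two random ones
are identical over the whole interval from the core out to a flanking SNP,
evaluated at marker positions within a 1 Mb window. "Derived allele" is
undefined without an outgroup, so the user names the core allele; the
default is the allele commoner in the later cohort. Statistical phasing is
out of scope — the pipeline consumes phased haplotypes (the synthetic
generator emits truth phase).

## Inbreeding

`detect_roh()` uses the deterministic consecutive-SNP method: a run extends
through homozygous calls, tolerating up to `max_het`/`max_miss` exceptions
(defaults 0) and breaking at inter-SNP gaps above `max_gap`; candidates must
then pass all of `min_snp` (41), `min_length_bp` (50 kb) and `min_density`
(1/5000 per bp). These defaults suit ~150k-SNP canine arrays. **The density
and SNP-count thresholds are statements about the genotyping platform, not
about biology**: on a sparser map they must be scaled to the marker spacing
or no run can ever qualify, which is why the package's own simulation-based
tests pass `min_density` values matched to their synthetic maps.

`f_roh()` divides the summed run lengths by the *genotyped* genome span
(first-to-last marker per chromosome), not the assembly length, so the
numerator and denominator describe the same territory. Group contrasts use
Welch's unequal-variance t-test.

A caution established while validating the package: with few chromosomes the
realized proportion of the genome that is IBD varies widely around the
pedigree expectation (Mendelian sampling), so rank agreement between
pedigree F and F_ROH is only a meaningful check on a genome of many
chromosomes; the package's test uses ten.

## Structure and contemporary Ne

PCA uses Patterson scaling (center by the mean call, divide by
`sqrt(p(1-p))`, mean-impute missing calls) and an eigendecomposition of the
sample covariance. The NJ tree is Saitou–Nei on genotype-state p-distance
(proportion of mismatching genotype codes over shared non-missing SNPs) —
the simplest reading of "p-distance on genotype pseudo-sequences", declared
rather than inferred from any particular GUI tool's IUPAC handling.
Negative NJ branches are clamped to zero with the excess moved to the
sister branch, preserving tip-to-tip path lengths. Nei's standard D uses
the original 1972 gene identities without small-sample correction.

`ld_ne()` implements the LD method for contemporary Ne: Burrows' composite
disequilibrium from unphased genotypes with Weir's S/(S−1) correction,
squared and normalised to r², averaged over locus pairs **on different
chromosomes only** (physical linkage would otherwise bias the drift signal;
the reference implementation also uses within-chromosome pairs, a
documented difference), then corrected for the expected sampling
contribution (`1/S + 3.19/S²` for S ≥ 30) and inverted through the Waples
(2006) bias-corrected formula. A non-positive drift signal honestly reports
`Ne = Inf`. The S/(S−1) correction is not cosmetic: without it the
estimator's pure-sampling expectation falls below the Waples term and Ne is
overestimated by ~45% at true Ne = 50; with it, parameter recovery on
simulated populations of true Ne = 50 centres on 50.

## The synthetic cohort generator

`sim_config()` + `simulate_founders()` + `breed_forward()` emulate a closed
breed rather than any generic population:

* **Bottleneck LD and background homozygosity** come from drawing founder
  chromosomes as mosaics of a small pool of ancestral haplotype templates
  (default 6 per chromosome, ~5 template switches per chromosome). Sharing
  a template segment is what creates the long ROH and high baseline F_ROH
  (~0.3) typical of pedigree dogs. Verbatim template copies
  (`founder_mosaic_segments = 0`) are available but give unrealistic
  chromosome-length runs.
* **The focal locus** is placed at an exact bp position; `round(q0 * pool)`
  templates carry the mutant allele, so it rides specific ancestral
  backgrounds (needed for a scan to have anything to find) and the realized
  founder frequency is q0 up to binomial error.
* **Breeding** is one cycle per year with few sires and many dams
  (`male_fraction_breeding = 0.2`), Poisson litters, and a breeding-age
  window — overlapping generations, as in real kennels.
* **Selection policies**: `avoid_mutant_matings` (no carrier×carrier
  litters), `cull_mutant_offspring` (test-and-remove of affected pups), and
  `clear_sires_cull` (mutation-free studs plus culling — the regime that
  produces declines of the magnitude seen in tested breeds; recessive
  culling alone is far too slow). `policy_compliance` (default 0.9) models
  incomplete testing uptake and is what keeps a trickle of affected pups in
  post-selection cohorts.
* **Widened breeding post-selection**: once a policy is active the sire
  share and litter cap grow by 1.5× and mutation-free dogs from *outside
  lineages* (a separate template pool) are recruited. This reproduces two
  observations the analysis should recover: contemporary Ne rises rather
  than falls under informed selection, and EHH around the focal region is
  *shorter* in the post-selection cohort because its haplotypes sample more
  lineages. In a strictly closed bottleneck the opposite happens — selection
  on the favoured allele lengthens its haplotype homozygosity — so the
  recruits are a modelling statement, not a convenience.

What the generator does **not** emulate: coalescent-accurate breed history,
mutation, genotyping error, array ascertainment bias, strand flips, or
X-chromosome inheritance. Tests passing on this generator therefore
demonstrate correctness of the statistics and the pipeline's behaviour
under the stated population model, not performance on any particular real
array product.

```{r scenario, eval = FALSE}
# one end-to-end replicate of the reference selection scenario (~5 s)
selection_replicate(seed = 1)
```

## Numerical and design choices

* Allele orientation: the counted (A2) allele is the alphabetically second
  allele observed at first read, recorded in the map; all downstream
  frequencies are orientation-stable, and `wc_fst` is invariant to label
  swaps.
* QC order is fixed — non-autosomes, SNP missingness (< 1%), sample
  missingness (< 1%), MAF (≥ 0.01) — and logged per stage so counts always
  reconcile. Hardy–Weinberg filtering is intentionally absent: a managed
  breed is not random-mating.
* Relative pruning is greedy on KING-robust kinship at the 0.176 cutoff
  (the first/second-degree boundary): repeatedly drop the sample in the
  most above-cutoff pairs, ties broken toward the higher sample index.
* Fisher's exact test delegates to R's network algorithm; tables whose
  total exceeds the exact budget switch to Monte-Carlo with a reported
  standard error. All-zero rows/columns are uninformative and dropped
  before testing; a table reduced below 2×2 returns p = 1, flagged.
* All stochastic operations take explicit seeds (package default
  20231218); the pipeline derives stage seeds from one root seed so any
  stage can be reproduced in isolation.
* Problem sizes in the test-suite simulations (1,500–5,000 SNPs, 2–10
  chromosomes, cohorts of tens of dogs, 20 replicates for rate
  properties) are the package's chosen validation scale: large enough that
  every statistic is exercised in its intended regime, small enough to run
  interactively.

## Known limitations

* `fisher_exact` inherits `stats::fisher.test`'s workspace behaviour on
  pathological mid-size tables.
* The LD-Ne parametric CI treats locus pairs as independent chi-squared
  contributions; with thousands of correlated pairs it is narrower than a
  jackknife CI would be. The point estimate is unaffected.
* The consecutive ROH scanner with `max_het > 0` is greedy (runs close at
  the first over-budget exception); this matches the deterministic
  consecutive method but can differ from sliding-window implementations
  near run edges.
* p-distance on genotype states treats het↔hom and hom↔hom mismatches
  equally; tools that expand genotypes to IUPAC codes weight these
  differently, so tree branch lengths (not topologies) may differ.
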