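---
title: "Measuring and predicting SNP imputation accuracy: methods"
author: "ImputeAccuracy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and predicting SNP imputation accuracy: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, conventions and design choices behind
`ImputeAccuracy`.  It states no empirical result beyond what the package's
test suite and `scripts/acceptance.R` compute themselves.

## The evaluation loop

Imputation accuracy can only be measured where truth is known.  The
package's loop is: take animals genotyped at high density, *mask* their
genotypes down to a lower panel (`maskToPanel()` keeps the full SNP frame
and blanks everything off-panel, so true and imputed matrices stay
aligned), *impute* back against a reference set, and *score* the result.
A `Scenario` bundles one such configuration — reference ids, target ids,
source and target panels, imputation method, selection rules — and
`runScenario()` executes it end to end.

Two accuracy measures are computed per animal and per SNP, on the
comparable (both-called) entries:

* concordance rate, `CR = 100 · #(imputed = true) / #(both called)`;
* allelic r², the squared Pearson correlation of imputed and true dosages,
  which is far less dependent on allele frequency than CR (a rare SNP
  imputed all-reference-homozygote scores a high CR but r² near 0).

By default only the entries actually hidden by the masking are scored
(`evaluated = "masked"`).  Including the observed pass-through SNPs
(`evaluated = "all"`) inflates accuracy and is provided only for
comparison with pipelines that report it that way; with error-free
observed genotypes, CR(all) ≥ CR(masked) always.

**Zero-variance convention.**  A SNP monomorphic in the truth (or in the
imputed output) has no defined correlation; its r² is reported as 0 and
flagged.  This keeps MAF-bin means defined and matches how no-variation
SNPs are conventionally reported as zero-accuracy.  Units with fewer than
two comparable entries are `NA` and excluded from means.

## Genomic relatedness and Mendelian inconsistency

The genomic relationship matrix is VanRaden's method 1,

$$G = \frac{XX'}{2\sum_i p_i(1-p_i)},$$

where the incidence matrix $X$ holds dosages centered by twice the
B-allele frequency, $x_{ji} = d_{ji} - 2p_i$.  The printed denominator
$2\sum p(1-p)$ *is* the method-1 scaling, which is why the centered-dosage
reading of the incidence matrix is used.  Missing dosages contribute 0
after centering (mean imputation) — the standard convention that keeps G
defined under missingness.  Allele frequencies are computed over the union
of reference and target animals of the scenario at hand: that union is the
only set guaranteed to be available before imputation, and the choice is
exposed (`alleleFrequencies(gd, animals)`) rather than hidden.

Mendelian inconsistency (MI) between two animals is the count of opposing
homozygotes (0 vs 2) over co-called SNPs; it is symmetric, free of allele
labelling, and low MI indicates haplotype sharing.  Two per-target
summaries are provided because both appear in field practice: the mean MI
over the 10 *lowest-MI* reference animals (the default `avTopMI()`), and
the mean over the 10 most *G-related* reference animals
(`rankBy = "relationship"`).  The two rank animals concordantly on related
data (a tested property) but are not identical; the lowest-MI form is the
default because it needs no G matrix and is the more direct haplotype-
sharing signal.  Ties are always broken by ascending animal id.

MDS clustering uses the distance $d_{ij} = \sqrt{g_{ii} + g_{jj} - 2g_{ij}}$
— the natural Euclidean distance of the underlying centered dosage
vectors — with classical (Torgerson) scaling; negative eigenvalues, which
can arise under missingness, are truncated and their count recorded.

## The imputation engines

**Major-allele baseline** ("imputation by chance"): every missing entry is
replaced by the homozygote of the more frequent allele (0 if p < 0.5, 2 if
p > 0.5, the heterozygote at an exact tie).  Its expected CR at a SNP is
the population frequency of the filled genotype, which gives a closed-form
expectation the test suite checks.  Any real imputer must beat this
baseline to be worth anything.

**Window-haplotype imputer**: a deliberately simple, fully deterministic
reference-matching scheme.  For each target and each sliding window on the
high panel's SNP order, the reference animal minimizing the mean absolute
dosage difference on the co-observed low-panel SNPs in the window is
selected (ties to the lowest animal id) and its dosages are proposed for
the target's missing entries; overlapping windows vote per entry, majority
wins, and remaining ties take the later window's value.  It is *not* a
reimplementation of any published imputation software — no phasing, no
HMM, no family logic.  Its role is to be a self-contained, deterministic
engine with the qualitative behaviour the evaluation and prediction
machinery needs: accuracy that increases with reference size and
relatedness and decreases for weakly connected animals.

Window defaults are `window = 200` high-panel SNPs with `overlap = 150`
(stride 50).  Rationale: at a typical ~10 % low-to-high density ratio a
200-SNP window contains ~20 observed SNPs, enough to discriminate between
candidate reference animals (short windows collapse into ties, which the
deterministic lowest-id rule then resolves systematically and poorly),
while the 75 % overlap gives every SNP four votes and smooths over
window-boundary errors.  Both parameters are in units of high-panel SNPs
and should be scaled with the density ratio, not with the genome size.

**Two-step imputation** (`imputeTwoStep()`) imputes low→mid against a
(usually much larger) mid-density reference, then mid→high against the
high-density reference, mirroring the strategy of exploiting the many more
animals genotyped at intermediate density.  With `mid = high` or
`mid = low` it degenerates exactly to the one-step run (a tested
identity).

## Quality control

Per-SNP rules apply in the conventional order — defined map position, MAF,
call rate, Hardy–Weinberg — and each dropped SNP records the *first* rule
it failed; the per-animal call-rate filter runs last.  Defaults: MAF
≥ 0.0005 (strict "drop if below"), SNP call rate ≥ 0.95, HWE p ≥ 1e−5,
animal call rate ≥ 0.95.  HWE uses the 1-df χ² test on genotype counts
(standard chip-QC practice at these sample sizes); an exact conditional
test is available via `qcThresholds(hweTest = "exact")`.  All statistics
are computed in a single pass on the full animal set and are *not*
recomputed after animals are removed — whether the second pass should
happen is genuinely underdetermined in common practice, so the single-pass
choice is recorded in the report (`singlePass = TRUE`), and the
idempotence of the filter at the shipped noise levels is tested.  The
animal call rate is computed over the SNPs retained by the SNP filters.

## The synthetic-data generator

The generator exists so that every downstream stage is testable without
external data; it emulates the *structure* of a multi-breed sheep
population, not any particular dataset.

* **Breed divergence** follows the Balding–Nichols beta model: breed
  frequency at a SNP with base frequency $p$ is drawn from
  $\mathrm{Beta}(p(1-c)/c,\ (1-p)(1-c)/c)$ with a per-breed $F_{st}$-like
  divergence $c$.  One parameter per breed, and it reproduces
  MDS-separable breed clusters.  The default base spectrum is
  $\mathrm{Beta}(0.5, 0.5)$, a U-shaped frequency distribution whose mass
  near the boundaries supplies the rare variants (MAF down into the
  (0, 0.001] range) that rare-allele binning needs.
* **The default plan** (`defaultBreedPlan()`) has two closely related
  dual-purpose breeds (divergence 0.05 and 0.08), a composite line bred
  from their crosses, and one *terminal* breed at divergence 0.35 that
  never enters the crosses — so that every default population contains a
  weakly related group whose mean top-10 genomic relationship to the main
  breeds is near zero, the regime in which imputation collapses toward
  the chance baseline and the pre-imputation predictor must flag animals.
* **Recombination** uses the Haldane model: crossover counts per meiosis
  and chromosome are Poisson with mean the chromosome's genetic length in
  Morgans, positions uniform on the physical map, no interference — the
  simplest model consistent with gene dropping.  Error-free output is
  exactly Mendelian-consistent (parent–offspring MI = 0), which anchors
  the MI machinery.
* **Birth years** equal the generation index: reference selection rules of
  the form "the oldest animals" are driven by generation, which is the
  discrete-generations analogue of selecting by birth year.
* **Noise**: genotyping error flips a called dosage to one of the two
  other states uniformly; missingness blanks entries independently.

What the generator does **not** emulate: population-scale linkage
disequilibrium beyond family haplotype sharing (no coalescent history),
selection, sex chromosomes, or genotype-intensity artefacts.  Absolute
simulated accuracies therefore should not be read as predictions for real
panels; the tested claims are *directional* (reference size up ⇒ accuracy
up; related reference animals removed ⇒ accuracy down; two-step through a
large mid reference ≥ one-step; AVTOP10 up ⇒ accuracy down), plus exact
recovery of the closed-form and pedigree-expectation anchors
(parent–offspring G ≈ 0.5 at 10,000 SNPs, MI = 0, chance-baseline CR equal
to its analytic expectation).

## Pre-imputation prediction

`predictAtRisk()` computes AVTOP10 on the low-density SNPs only — nothing
an imputation run would need — and flags animals whose value *strictly*
exceeds the threshold ("higher than" is the published phrasing, hence
strict).  The shipped defaults, 400 at a 5K-like density and 3000 at a
50K-like density, come from published sheep-population practice and are
explicitly data-dependent: MI counts scale with the number of SNPs
compared and with population structure, so on any new population
`calibrateThreshold()` — which scans midpoint cuts and maximizes balanced
accuracy for classifying CR < 80 % — is the recommended path, and custom
panels require an explicit threshold rather than inheriting one.

## Numerical and interface conventions

* Dosages are integer 0/1/2 with `NA` missing; the A allele is the first
  listed (PLINK) or REF (VCF) allele and dosage counts the B/ALT allele.
* Positions are 1-based bp; the canonical SNP order is (chromosome,
  position), enforced by the `GenotypeData` validity method.
* The PLINK text writer emits a 6-column `.map` (with allele labels, as
  `.bim` does) so that write→read round-trips the dosage matrix exactly;
  a 4-column `.map` falls back to first-listed-allele coding.
* MAF bins are left-open right-closed; MAF exactly 0 is excluded (no
  minor allele present at all).
* Chromosome ends with fewer than 2n SNPs split at the midpoint without
  double counting and are flagged truncated.
* All ties anywhere (reference matching, AVTOP10, top-k) break by
  ascending id; all simulation randomness flows from explicit integer
  seeds; imputation itself is deterministic.

## Problem sizes used by the tests and the acceptance script

The shipped test populations are desk-scale stand-ins chosen to keep the
full loop fast while preserving the structural features above: 1000–2000
SNPs on 4 chromosomes of 1 Morgan each with nested ~10 % / 50 % / 100 %
panels for scenario work, a 10,000-SNP single-breed population for
pedigree-expectation recovery (parent–offspring G needs many SNPs for its
sampling noise to shrink below ±0.05), and a ~2900-animal single-breed
population with 1000 imputed targets for per-SNP r² — per-SNP correlations
need a large imputed set to be estimated without bias, which is why the
rare-allele workflow keeps the imputed set at ≥ 1000 animals.  Rare-allele
bins are formed on the simulator's true founder frequencies: empirical
frequencies from a few thousand animals cannot resolve MAF ≤ 1e−4 at all,
and the binning function takes its frequency vector as an explicit
argument so either source can be used.

## Known limitations

* The window imputer is a stand-in: it matches unphased dosages, so its
  absolute accuracy sits well below haplotype-based tools; comparisons
  against the chance baseline and across designs are the supported use.
* Mean-imputed missing dosages bias G slightly toward zero at high
  missingness; QC call-rate thresholds keep this second-order.
* The relatedness-exclusion rule computes G at target-panel density from
  the truth matrix, as masking happens afterwards; in a live pipeline the
  same rule would run on the pre-masking genotypes.
* Scenario-level Min/Max Top10 are summarized as the mean over targets of
  the per-target min/max of the top-k relationships; other summaries
  (global extrema) exist in the literature and can be recovered from the
  returned per-target table.
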