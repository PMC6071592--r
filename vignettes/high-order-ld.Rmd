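---
title: "High-order LD, phantom epistasis, and how phantomepi measures them"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{High-order LD, phantom epistasis, and how phantomepi measures them}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phantomepi)
```

## The model and its assumptions

`phantomepi` works on populations of inbred (effectively haploid)
individuals — wild-collected selfing accessions, recombinant inbred
lines, doubled haploids. Two assumptions follow and are used everywhere:

1. **Genotype = haplotype.** With no heterozygotes, the multilocus
   genotype of an individual identifies its haplotype, so LD statistics
   that are defined on haplotype frequencies can be computed directly
   from genotype frequencies, without phasing or an EM step.
2. **Two codes per marker.** Genotypes are stored as 0 (reference /
   major homozygote) and 1 (alternative homozygote), with `NA` for no
   calls. Residual heterozygous calls in input VCFs are treated as no
   calls by default (`het_policy = "missing"`), because in inbred panels
   they are mostly genotyping artefacts and dropping the whole marker
   would discard more information; `drop_marker` and `error` are
   available when stricter behaviour is wanted.

### Pairwise LD

For two bi-allelic loci with allele frequencies $p$ and $q$ and joint
frequency $p_{11}$,

$$ r^2 = \frac{(p_{11} - pq)^2}{p(1-p)\,q(1-q)}. $$

A locus that is monomorphic among the individuals entering the
computation has **no** defined $r^2$: the statistic is reported as
undefined (`NA`), never as 0. Pairwise statistics use pairwise-complete
individuals; three-locus statistics use triplet-complete individuals.
This maximises the data used per statistic, at the (documented) cost
that different triplets may be computed on slightly different subsets
when calls are missing.

### Second-order (high-order) LD

Two genotyped predictors $M_1$ (alleles A/a) and $M_2$ (B/b) form four
two-locus genotypes AB, Ab, aB, ab. Each is recoded one-vs-rest into a
bi-allelic *pseudomarker*:

| pseudomarker | carrier class |
|---|---|
| P1 | AB vs non-AB |
| P2 | Ab vs non-Ab |
| P3 | aB vs non-aB |
| P4 | ab vs non-ab |

The second-order LD of the pair to a target $Q$ is the largest defined
pairwise $r^2$ between $Q$ and P1–P4. Two numerical conventions matter
and are fixed here:

* a pseudomarker that is monomorphic among the triplet-complete
  individuals (an empty or universal carrier class) is **excluded from
  the maximum** rather than scored 0 — $r^2$ does not exist for it, and
  excluding it can never change a defined maximum;
* ties are broken by the lowest pseudomarker index, so scans are
  deterministic and regression-testable.

Swapping the predictors permutes P2 and P3; relabelling alleles at any
locus permutes carrier classes. Both leave the maximum unchanged, and
the test suite asserts these invariances against a brute-force
contingency oracle.

## Triplet scans

`scan_triplets()` evaluates every unordered predictor pair against every
eligible target. The tunable parameters, all configurable and defaulting
to the pipeline's standard values:

| parameter | default | role |
|---|---|---|
| `target_filter_r2` | 0.6 | targets whose best *single*-predictor r² is at or above this are skipped: the interesting targets are those no individual marker tags |
| `keep_r2` | 0.3 (strict) | retention threshold for storing a triplet record |
| `strong_r2` | 0.6 (strict) | a retained triplet is flagged *strong* above this |
| `window_bp` | 1,000,000 | the cis window of the distance classification |

A predictor is *cis* to a target when it lies on the same chromosome
within `window_bp` — the boundary is **inclusive** (exactly 1 Mb away is
cis; the choice is arbitrary and documented, and markers on different
chromosomes are always trans). A triplet is cis-cis, cis-trans or
trans-trans according to how many of its two predictors are cis.

Per-class *evaluated-triplet* denominators are recorded whether or not
any record is kept. The proportion of strong triplets per class divides
the strong count by the evaluated (predictor pair, target) triplets of
that class — not by predictor pairs alone. The distinction matters for
extrapolation: `count_possible_pairs()` counts genome-wide *triplets*
per class (for each target with $c_q$ of $P$ predictors in cis:
$\binom{c_q}{2}$ cis-cis, $c_q(P-c_q)$ cis-trans, $\binom{P-c_q}{2}$
trans-trans, and the three always partition
$\binom{P}{2} \times \#\text{targets}$), so proportion × total is
dimensionally consistent only with triplet denominators. Both counts
appear in the outputs, so the alternative convention can be recovered.

`extrapolate_genome()` pools windows (sum of observed over sum of
evaluated, rather than averaging per-window proportions, so windows with
more evaluated triplets weigh more), multiplies by the genome totals,
and reports the sample standard deviation of the per-window genome
estimates as the estimation error. A class never evaluated is undefined
(`NA`), not zero.

### Genome-scale proportions by Monte Carlo

The full cross product at a genome-like scale (thousands of predictors
and targets) has order $10^{10}$ triplets and cannot be enumerated on a
desktop. The per-class strong proportion, however, is a population mean,
and `estimate_strong_proportion()` estimates it without bias from a
uniform random sample of triplets, computed in vectorised blocks of
column sums. The acceptance script uses populations of 500 individuals
on 5 chromosomes × 30 Mb with 7,000 markers (2,000 predictors, 5,000
targets) and $3 \times 10^5$ sampled triplets per population over ten
simulation seeds — sizes chosen so the pooled estimates have small
enough Monte Carlo error to resolve proportions of order $10^{-5}$.

## The two-locus epistasis model

$$ Y = \beta_0 + a_1\beta_1 + a_2\beta_2 + a_1 a_2 \beta_{12} + e $$

with $a_1, a_2 \in \{+1, -1\}$ coding the two homozygous genotypes. The
package codes the reference (code-0) homozygote as $+1$ and the
alternative as $-1$, following the AA-vs-aa convention of the model; the
interaction code $a_1 a_2$ is $+1$ for the coupling classes (AABB, aabb)
and $-1$ for the repulsion classes. $\beta_{12}$ and all p-values are
invariant to this sign convention, and the main-effect signs simply flip
under relabelling.

In the perfectly tagged scenario (`make_perfect_tag_scenario()`: causal allele
of $Q$ carried exactly by the ab class, equal class frequencies, unit
allele effect, no noise) the orthogonal design gives exactly
$\beta_1 = \beta_2 = -0.25$, $\beta_{12} = +0.25$, while each single
marker has $r^2 = 1/3$ to $Q$ — statistical epistasis from a purely
additive single-locus architecture. This is the package's central,
literally assertable property.

**Stage 1** (`epistasis_scan()`) fits every unordered pair by OLS with a
closed-form normal-equations path (the 4×4 cross-product matrix is
assembled from precomputed column sums). A pair with an empty two-locus
genotype class has a rank-deficient design; such pairs are detected
exactly (cell counts, not a numerical tolerance), their aliased terms
reported as `NA` and the fit flagged — never silently dropped, and never
significant. Significance uses `bonferroni_threshold(alpha, n_tests)`
with `n_tests` either all pairs $\binom{m}{2}$ or an explicit,
externally estimated effective number of independent tests (the method
for estimating LD-block counts is out of scope; the number is a
configuration input).

**Stage 2** (`refit_with_kinship()`) refits passing pairs in the linear
mixed model $y = X\beta + u + e$, $u \sim N(0, \sigma_g^2 K)$, where $K$
is the genomic kinship (`genomic_kinship()`: cross-product of the
column-standardised genotype matrix divided by marker count, missing
entries mean-imputed for this computation only). The model is rotated by
the eigendecomposition of $K$; the variance ratio
$\lambda = \sigma_g^2/\sigma_e^2$ is profiled out by REML with a bounded
scalar search on $\log\lambda \in [\log 10^{-8}, \log 10^{8}]$
(tolerance $10^{-8}$; one eigendecomposition per dataset; the
no-structure boundary $\lambda = 0$ is taken whenever it is at least as
good, where the refit reproduces OLS exactly). Fixed effects get Wald
tests against a $t$ reference with residual degrees of freedom — the
common default of the mixed-model GWAS software family, chosen because
the two-stage procedure needs per-coefficient tests; a likelihood-ratio
alternative would require a second fit per term. Eigenvalues below
$-10^{-6}$ times the spectral radius are rejected as non-PSD; small
negative eigenvalues from floating-point noise are clamped to zero.

## Synthetic populations: what they do and do not emulate

All generators are deterministic given a seed and draw whole haplotypes
(no within-individual heterozygosity), matching inbred accessions.

* `haplotype_table()` / `sample_population()`: i.i.d. sampling from an
  explicit haplotype distribution — the right tool when a scenario's LD
  structure must be exact (both canonical scenarios use it or a direct
  equivalent).
* `simulate_mosaic_genome()`: founder-mosaic genomes. Defaults — 20
  founders, 5 chromosomes × 30 Mb, founder-switch rate $10^{-6}$/bp (a
  1 Mb LD length scale), founder allele frequencies log-uniform on
  [0.05, 0.95] (density $\propto 1/p$, the shape of a neutral site
  frequency spectrum). The skewed spectrum matters: chance
  near-coincidence of *rare* alleles is what creates strong spurious
  high-order LD in small samples, and a frequency spectrum concentrated
  near 0.5 (as a naive Bernoulli(½) choice would give) suppresses the
  phenomenon far below what real sequencing panels show.
* `make_complex_locus_scenario()`: four hidden linked effect loci (three
  trait-increasing, one decreasing, defaults ±1 with noise sd 0.5 —
  magnitudes are a qualitative choice; the goal is group separation, not
  a numeric match) whose carrier frequencies differ across the four
  groups of a cis/trans predictor pair, so the pair tags the hidden
  allele combinations far better than any single marker and the scan
  detects strong statistical epistasis between two non-causal markers.

Limitations to keep in mind when reading test results:

* The mosaic model has **no cross-chromosome population structure**:
  founder assignments are drawn independently per chromosome, so its
  kinship is block-local. Tests of structure correction therefore use
  explicitly structured fixtures (clone groups, differentiated
  subpopulations) instead.
* There is no selection, migration, demography or coalescent machinery,
  and no attempt to match the empirical LD spectrum of any real panel.
  Passing tests show the *mechanisms* behave as specified, not that any
  particular real dataset would yield particular numbers.
* Structural variation and multi-allelic loci are represented only
  implicitly (as hidden bi-allelic effect loci in the complex-locus
  scenario).

## Degenerate inputs and edge policies

* MAF thresholds are strict (`> t`), so "MAF > 0.05" reads literally; a
  marker at exactly the threshold is dropped.
* `compute_maf()` and all r² kernels error or return `NA` (as
  documented) on all-missing or monomorphic input rather than returning
  a misleading 0.
* Subsampling re-checks polymorphism (and optionally MAF) in the
  subsample and logs dropped markers, because a rare allele can vanish
  from a subsample.
* Fits require ≥ 5 complete observations and both loci polymorphic;
  smaller or degenerate inputs are errors, not silent `NA`s.

## Problem sizes in the shipped checks

The test suite and acceptance script are sized for a single CPU: 1,000
random three-locus datasets of up to 40 individuals for oracle
equivalence (plus an exhaustive sweep of all 4,096 four-individual
datasets), ten mosaic populations of 500 individuals with 7,000 markers
for the sample-size contrast, a 340-accession complex-locus scan over a
48-marker panel, and 100 pure-noise replicates of a 20-marker scan for
type-I behaviour. These sizes are the package's own reduced-scale study
design; every threshold involved (0.3, 0.6, 1 Mb, MAF 0.05, α = 0.05)
keeps its standard value at every scale.
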