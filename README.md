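# phantomepi

High-order linkage disequilibrium and phantom statistical epistasis in
inbred populations.

## The problem

Genome-wide scans for pairwise statistical epistasis test, for every pair
of genotyped markers, whether the interaction term of a two-locus linear
model is nonzero. A significant interaction is routinely read as evidence
of functional gene–gene interaction. In inbred (effectively haploid)
populations there is a simpler explanation that does not involve any
interaction at all: the *joint* genotype of two markers can tag a hidden,
ungenotyped polymorphism better than either marker alone. This
**high-order (second-order) linkage disequilibrium** turns a single
additive causal locus into an apparent interaction between two innocent
markers — phantom epistasis.

`phantomepi` implements the full analysis pipeline for quantifying this
phenomenon and for stress-testing epistasis scans against it:

* **Second-order LD.** For a predictor pair M1 (alleles A/a) and M2
  (B/b), the four two-locus genotypes AB, Ab, aB, ab are each recoded
  one-vs-rest into a bi-allelic *pseudomarker* P1–P4. The second-order LD
  of the pair to a target Q is

  ```
  r²₂(M1, M2; Q) = max_k r²(P_k, Q),      k = 1..4
  ```

  with r² the standard haplotypic LD measure D²/(p(1−p)q(1−q)), computed
  directly on genotype frequencies (inbred individuals: genotype =
  haplotype).

* **Triplet scans and genome-wide extrapolation.** Exhaustive window
  scans of all (predictor pair, target) triplets, skipping targets
  already tagged by a single marker (individual r² ≥ 0.6), retaining
  triplets with r²₂ > 0.3 and flagging strong ones (r²₂ > 0.6);
  classification into cis-cis / cis-trans / trans-trans by a 1 Mb rule;
  extrapolation of windowed strong-triplet proportions to genome-wide
  counts with an estimation error from the spread across windows. For
  genome-scale panels a seeded Monte Carlo triplet sampler estimates the
  same proportions without enumerating the cross product.

* **Two-stage epistasis scans.** The two-locus model

  ```
  Y = β₀ + a₁β₁ + a₂β₂ + a₁a₂β₁₂ + e,     a₁, a₂ ∈ {+1, −1}
  ```

  fitted by OLS for every marker pair (stage 1), then a kinship-corrected
  linear-mixed-model refit (y = Xβ + u + e, u ~ N(0, σ²g K), REML over
  the variance ratio) for pairs passing the Bonferroni threshold
  (stage 2).

* **Synthetic inbred populations.** Haplotype-table sampling,
  founder-mosaic genomes with distance-decaying LD and a rare-skewed
  allele-frequency spectrum, a perfectly tagged hidden-locus scenario,
  and a complex multi-allelic locus scenario (four linked hidden effect
  loci tagged jointly by a cis/trans predictor pair) — so every stage of
  the pipeline is testable without any external data.

## A worked example: epistasis from a single causal locus

The canonical configuration: a hidden locus Q whose causal allele is
carried exactly by the ab two-locus class of two genotyped markers, with
all four classes equally frequent. Neither marker tags Q usefully, the
pair tags it perfectly, and a purely additive single-locus trait shows
textbook statistical epistasis.

```r
library(phantomepi)

sc <- make_perfect_tag_scenario(n_per_class = 25)   # 100 individuals
g  <- sc$genotypes

second_order_ld(marker_codes(g, "M1"), marker_codes(g, "M2"),
                marker_codes(g, "Q"))
#> $r2
#> [1] 1
#> $per_pseudomarker_r2
#>        P1        P2        P3        P4
#> 0.1111111 0.1111111 0.1111111 1.0000000
#> $best_pseudomarker
#> [1] 4
```

Pseudomarker P4 ({ab vs non-ab}) tags Q perfectly (r² = 1) while the best
single marker reaches only r² = 1/3. Fitting the two-locus model to the
(noise-free) phenotype:

```r
fit_two_locus_model(sc$phenotype$value,
                    marker_codes(g, "M1"), marker_codes(g, "M2"))
#> <epi_fit> two-locus OLS fit, n = 100
#>   term        estimate
#> 1 (Intercept)     0.25
#> 2 a1             -0.25
#> 3 a2             -0.25
#> 4 a1:a2           0.25
```

β₁₂ = +0.25 — a nonzero interaction estimate from a generative model that
contains no interaction. A triplet scan finds and flags the pair:

```r
scan <- scan_triplets(g[, c("M1", "M2")], g[, "Q", drop = FALSE])
glance(scan)
#> 1 triplet evaluated, 1 kept, 1 strong (r²₂ = 1, class cis_trans)
```

`tidy()` / `glance()` return tibbles throughout, results chain with the
pipe, and `autoplot()` methods draw the standard displays (per-class
genome-wide estimates with error bars, r²₂ distributions,
genotype-class phenotype boxplots via `plot_pair_phenotypes()`).

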