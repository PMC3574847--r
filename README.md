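# haploclone

Haplotype analysis of endosymbiont clone libraries: PCR-artifact
filtering, recombinant screening, diversity statistics,
statistical-parsimony networks, AMOVA against host mitochondrial
haplogroups, and symbiont–host association tests.

## Who this is for

Molecular ecologists studying maternally inherited endosymbionts
(*Wolbachia* and relatives) in insect hosts. When symbiont densities are
low, within-host strain variation is surveyed by PCR-amplifying a variable
locus (e.g. *groEL*), cloning, and sequencing a handful of clones per
individual. Such clone libraries mix genuine strain variation with
polymerase errors and PCR-mediated chimeras, and the downstream questions
— how many strains and lineages, are individual hosts superinfected, is a
symbiont lineage associated with a host mtDNA haplogroup or a geographic
contact zone — need that noise removed first. `haploclone` covers the full
path, with a seeded, ground-truthed simulator so every stage is testable.

## Methods at the core

* **Artifact filter.** Clone haplotypes found ≥ 2 times, or verified in
  two independent PCR replicates, are retained unconditionally. Each
  remaining singleton at Hamming distance *d* from its nearest retained
  neighbour is tested under a Poisson error model with mean
  λ = *e·L·c* (error rate per bp per cycle × amplicon length × total
  cycles): it is removed when
  1 − (1 − p₁)ⁿ ≥ α, where p₁ = P(Pois(λ) ≥ d) and *n* is the number of
  clones from the same fly. Output: a *complete* dataset (retained
  singletons included) and a *conservative* dataset (multiplicity ≥ 2).
* **Recombinant screen.** For every haplotype pair, the longest
  mismatch-free run over polymorphic sites; the null permutes
  polymorphic-site order jointly across sequences; per-pair p-values are
  Bonferroni-corrected and the lower-frequency member of a significant
  pair is removed.
* **Diversity.** Nei's unbiased haplotype diversity
  H_d = n(1 − Σpᵢ²)/(n − 1); nucleotide diversity π = k/L_eff and
  segregating sites under complete deletion of gap/N columns.
* **Networks.** Statistical parsimony: pairs are connected up to the
  largest step count *j* with Π_{i<j}(1 − i/L) ≥ 0.95 (for L = 600 bp the
  limit is 8 steps); disjoint networks become Group1, Group2, … and
  thresholded edges define subgroups 1a, 1b, …
* **AMOVA.** One-level variance decomposition of squared pairwise
  differences among/within host mtDNA haplogroups, Φ_ST tested by label
  permutation; negative among-group components are reported as-is and the
  percentages always sum to 100.
* **Association.** Randomization tests (shuffle lineage-2 presence, or
  infection status, across individuals) and exact one-sided binomial tests
  per host haplotype.

## Worked example

Simulate a study (47 flies at 10 sites, two symbiont lineages, ~520
clones), filter, screen, and summarise:

```r
library(haploclone)

study <- simulate_study(seed = 1)
filt  <- build_datasets(study$clones,
                        error_model(rate = study$params$rate_e,
                                    cycles = study$params$cycles,
                                    length = study$params$L))
filt
#> <filter_result> complete: 21 haplotypes (546 clones), conservative: 17,
#>   artifacts: 8; alpha = 0.05, lambda = 0.0105
```

Of 554 clones, 8 haplotypes are attributed to polymerase error; the
conservative dataset (count ≥ 2) has 17 haplotypes and here matches the
number of true strains sampled twice or more (17 — the simulator's ground
truth, `sum(study$truth$strain_counts$n_clones >= 2)`).

```r
net <- build_networks(filt$conservative)
net
#> <haplo_network> 17 haplotypes, 86 edges, 2 network(s), connection limit 8 steps

grouping <- setNames(study$meta$mtdna_haplogroup, study$meta$individual_id)
summarize_groups(filt$conservative, grouping)
#>   group n_sequences n_haplotypes    Hd     pi  S    k
#> 1 North          30            9 0.857 0.0256 55 15.4
#> 2 South          26           13 0.923 0.0262 65 15.7
#> 3 (all)          56           17 0.891 0.0255 69 15.3
```

The two simulated lineages resolve into exactly two parsimony networks at
the 8-step 95% connection limit. Haplotype diversity is high (0.89 over 56
carrier sequences) and similar in both host haplogroups.

```r
ex <- expand_haplotypes(filt$conservative, unit = "carrier")
D  <- pairwise_distance_matrix(setNames(ex$sequence, NULL))
amova(D, grouping[ex$individual_id], n_perm = 1000, seed = 1)
#> One-level AMOVA
#>   variance components: among = -9.7312, within = 280.6739
#>   percentage of variation: among = -3.59, within = 103.59
#>   Phi_ST = -0.0359, p = 0.9251 (1000 permutations)
```

With no simulated coupling between symbiont lineage and host haplogroup
(the generator default), essentially all molecular variance lies within
haplogroups; the slightly negative among-group component (−3.6%, with
within-group at 103.6%) is the expected signature of groups no more
differentiated than random draws, and the permutation p-value is
non-significant.

The whole analysis is also available as one call writing every table to
disk with a checksum manifest:

```r
run_pipeline(pipeline_config(outdir = "out", seed = 1))
```

or from a shell via `inst/scripts/run_pipeline.R`.

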