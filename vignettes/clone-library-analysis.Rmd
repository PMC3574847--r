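---
title: "Methods: haplotype analysis of endosymbiont clone libraries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: haplotype analysis of endosymbiont clone libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haploclone)
```

## The problem

Maternally inherited endosymbionts such as *Wolbachia* can reshape the
population genetics of their insect hosts: because infected females
transmit both the symbiont and their mitochondria, a spreading infection
drags host mtDNA haplotypes along with it (cytoplasmic-incompatibility
driven sweeps). Testing whether this has happened requires knowing how many
symbiont strains are present — including several strains inside one fly
(superinfection) — and how symbiont sequence variation is distributed over
host mtDNA haplogroups and geography.

When symbiont densities are low, strain variation is accessed by PCR
amplification of a variable locus (e.g. *groEL*), cloning, and sequencing
of 2–20 clones per fly. Clone libraries conflate three sources of
variation: genuine strain differences, polymerase errors introduced during
PCR, and chimeric molecules from template switching between co-resident
strains. `haploclone` implements the full analysis path from raw clone
records to population-level inference, plus a ground-truthed simulator so
that every stage can be validated.

## Artifact filtering

Clones are collapsed to haplotypes by exact string identity (gaps and `N`
included verbatim; ambiguity resolution belongs to the filter, not the
collapser). Three rules then classify haplotypes:

1. **Multiplicity.** A haplotype observed in two or more clones — within or
   across individuals — is retained unconditionally: independent
   polymerase errors virtually never recur identically.
2. **Replicate verification.** A haplotype observed in two independent PCR
   replicates of the same individual cannot be a single-reaction artifact
   and is likewise exempt.
3. **Error-model test for singletons.** Each remaining singleton is
   compared with its nearest unconditionally retained neighbour at Hamming
   distance $d$ (columns with `-`/`N` in either sequence are excluded —
   indels and ambiguities are treated as alignment artifacts, not
   substitutions). Per-clone error counts are modelled as Poisson with mean
   $\lambda = e \cdot L \cdot c$ (error rate per bp per cycle $e$, amplicon
   length $L$, total effective cycles $c$ summed over consecutive PCRs,
   default $35+35=70$). The probability that at least one of the $n$
   clones sequenced from the same individual accumulates $\ge d$ errors is
   $1-(1-p_1)^n$ with $p_1 = 1-\sum_{k<d} e^{-\lambda}\lambda^k/k!$. A
   singleton is flagged as an artifact when this probability reaches
   `alpha` (default 0.05), i.e. when PCR error plausibly explains it.

Singletons are always judged against the unconditionally retained pool
rather than against previously accepted singletons; this keeps decisions
order-free and makes the artifact set exactly nested in `alpha`. Two
datasets are emitted: **complete** (everything not attributable to error,
retained singletons included) and **conservative** (count $\ge 2$ only).
The conservative set is the substrate for diversity and network summaries;
the complete set maximises sensitivity for lineage detection.

A note on the error rate: commonly quoted Taq polymerase figures of order
$10^{-4}$ per bp per cycle, taken at face value over 70 cycles of a 600 bp
amplicon, would give $\lambda \approx 17$ — every clone would then be
unique and no clone library could ever contain repeated haplotypes. Real
libraries show the opposite (most clones within a fly are identical), so
the effective per-clone error count must be far below one. The filter
keeps $\lambda = e L c$ as its working definition and leaves $e$
configurable; what matters for classification is the resulting $\lambda$,
not the factorisation.

## Recombinant screening

Chimeras are detected by a permutation test on *inner fragments*: for each
haplotype pair, the score is the longest run of consecutive polymorphic
sites (alignment columns with $\ge 2$ plain bases) at which the pair
agrees, runs being broken by any mismatch (a zero mismatch penalty — the
strictest convention). The null distribution jointly permutes the order of
the polymorphic-site columns across all sequences and records the global
all-pairs maximum run per permutation; per-pair p-values
$(1+\#\{null \ge obs\})/(1+n_{perm})$ are Bonferroni-corrected over pairs.
Which member of a significant pair is "the recombinant" is not identified
by the statistic; the package removes the lower-frequency member (tie:
lexicographically later sequence), the conservative choice when a
recombinant is expected to be a rare clone rather than an established
strain. Only within-dataset ("inner") comparisons are made; screening
against external reference pools is out of scope, as is breakpoint
estimation beyond the fragment span. With fewer than 3 haplotypes or fewer
than 2 polymorphic sites the screen reports "no test" rather than a score
of zero.

## Diversity statistics

* Haplotype diversity uses Nei's unbiased estimator
  $H_d = \frac{n}{n-1}(1-\sum_i p_i^2)$.
* Nucleotide diversity $\pi$, segregating sites $S$ and mean pairwise
  differences $k$ use **complete deletion**: every column containing `-`
  or `N` in the analysed set is dropped (pairwise deletion is available as
  an option), and $\pi = k/L_{\mathrm{eff}}$ by construction.
* Multiplicities are expanded exactly, never sampled.
* Group summaries count one sequence per (haplotype, carrier individual)
  pair — the unit in which clone-library surveys report "sequences" — so a
  haplotype shared by several flies contributes once per fly. Groups with
  fewer than two sequences are reported as undefined rather than zero.
* Reports print $H_d$ to 3 decimals and $\pi$ to 5, the conventional table
  precision; unrounded values stay in the returned data frames.

## Statistical-parsimony networks

Haplotypes are connected in ascending order of Hamming distance, up to a
connection limit: the largest step count $j$ whose probability of being
non-homoplastic still reaches the confidence level (default 0.95).
Modelling substitutions as falling uniformly and independently over the
$L$ sites, the probability that $j$ observed differences represent $j$
events with no two events at the same site is
$P_j = \prod_{i=1}^{j-1}(1-i/L)$ — a birthday-collision bound that is
monotone in $L$ (for $L=600$, the 95% limit is
`r connection_limit(600)` steps) and reaches 1 step as the confidence
approaches certainty. The exact coefficient series used by legacy network
software is not published to reproducible precision, so the package states
its criterion explicitly, cross-checks it in the test suite against a
directly evaluated probability series, and offers a fixed-limit override
for users who want to reproduce a specific legacy limit.

Disjoint networks become `Group1`, `Group2`, … by total haplotype
frequency. Within a group, removing edges longer than `subgroup_threshold`
steps (default 5 — chosen so that clusters of closely related variants
separate while single-step neighbours stay together; no published numeric
rule exists for this cut, so it is a package default, configurable) yields
subgroups `1a`, `1b`, … by descending frequency. Alternative equal-length
connections (loops) are retained in the edge set rather than resolved:
downstream analyses need components and step distances, not a unique tree.

## AMOVA

One-level analysis of molecular variance on squared pairwise differences:
$SSD_{total} = \sum_{i<j} d^2_{ij}/N$, within-group terms analogously per
group; $\sigma^2_{within} = SSD_{within}/(N-G)$,
$\sigma^2_{among} = (SSD_{among}/(G-1) - \sigma^2_{within})/n'$ with
$n' = (N - \sum_g n_g^2/N)/(G-1)$, and
$\Phi_{ST} = \sigma^2_{among}/(\sigma^2_{among}+\sigma^2_{within})$.
Negative among-group components are reported as-is (the percentages then
read, e.g., −2.5 / 102.5 but always sum to exactly 100); they arise
routinely when groups are no more differentiated than random draws.
All-zero distance matrices are reported as 0/100 with a warning rather
than NaN. The permutation test shuffles sequence-to-group labels with
group sizes fixed (the natural exchangeable unit; permuting sites would
break within-sequence linkage) and uses the add-one convention, so
$p \in (0,1]$. Haplotype multiplicities are expanded to one sequence per
carrier before the distance matrix is built.

## Association tests

Two randomization tests and one exact test:

* **Lineage 2 vs southern haplogroup:** the statistic is the *count* of
  individuals carrying lineage 2 and a southern mtDNA haplogroup (a
  proportion variant is provided; at fixed margins they are
  monotone-equivalent). The null shuffles the lineage-2 indicator across
  individuals.
* **Infection vs contact-region haplotypes:** the statistic is the
  proportion of infected individuals whose mtDNA haplotype occurs in the
  contact region; the null shuffles infection status.
* **Per-haplotype binomial test:** $P(X \ge k \mid n, 1/2)$, exact, for an
  excess of infected carriers of a haplotype. No multiple-testing
  correction is applied by default (a Bonferroni column is available).

The p-value convention is the plain proportion
$\#\{null \ge obs\}/n_{rand}$, matching how such tests are conventionally
reported at $n_{rand}=100$; an add-one variant (which cannot return 0) is
available by flag. A known limitation, measured by the calibration checks
in the test suite: when the lineage-2 count is small (a handful of
carriers among ~47 flies), the null is a coarse hypergeometric
distribution and the test is conservative — its effective size at a
nominal 5% level is roughly 2%, and its power against an odds ratio of 10
at $n=47$ falls just short of 80%. This is a property of discrete
randomization tests at these margins, not of the implementation; at 100
randomizations the p-value additionally carries ±0.1 resolution.

## The synthetic-data generator

`simulate_study()` emulates the sampling structure the analysis assumes:
10 sites contributing 2–8 flies each (47 total), 2–20 clones per fly
spread over two PCR replicates, two symbiont lineages 40 substitutions
apart, lineage 1 split into three subgroups (centroids 3 substitutions
from the lineage root, leaves 1–2 from their centroid, every substitution
at a globally distinct position so designed distances are exact), a rare
second lineage carried only by superinfected flies, spliced recombinant
clones in superinfected flies, and a host mtDNA haplotype pool with
North/South haplogroups, contact-region flags, and a log-odds coupling
$\theta$ (centred, so $e^\theta$ is the lineage-2/South odds ratio) for
association scenarios. A screening-survey scenario (default $N=366$)
couples infection status to contact-region haplotypes. Clone errors use
the cycle-compounded per-site probability $1-(1-e)^c$ — analytically
checkable and first-order consistent with the filter's Poisson mean. The
default error rate is set so that roughly 1% of clones carry an error,
the regime consistent with the within-fly clone concordance described
above; the default strain inventory (11+4+3 lineage-1 strains, 3
lineage-2 strains) yields a conservative dataset of about 20 haplotypes.
Ground truth records every template choice, error position and breakpoint,
so recovery can be asserted exactly.

What the simulator does *not* model: indels (the statistics exclude gap
columns anyway), coalescent genealogies within subgroups, selection or
sweep dynamics, primer bias, and chimera formation between more than two
templates. Passing tests therefore demonstrate correctness of the
algorithms under the stated generative assumptions, not robustness to
every artefact of real libraries.

## Numerical and design choices

* Indices are 1-based in the R API (idiomatic for R); file exports report
  spans as 0-based half-open alignment columns.
* All lexicographic tie-breaks use C-locale (radix) ordering, and every
  stochastic function takes an explicit seed and restores the caller's RNG
  state, so results are platform-stable and byte-reproducible.
* The pipeline derives per-stage seeds from the master seed as
  `seed * 100 + stage index`; any stage can be re-run in isolation.
* Nearest-neighbour ties in the filter resolve by smallest distance, then
  largest count, then lexicographic sequence.
* Degenerate inputs fail loudly with classed conditions
  (`hc_input_error`, `hc_no_test`, …) rather than returning NaN.

## Problem sizes used by the test suite

The suite validates parameter recovery over 50 seeded libraries
(~520 clones each), recombinant detection power over 50 constructed
recombinants at $10^4$ permutations, false-positive control over 100 null
datasets at $10^3$ permutations, network component recovery over 50
two-lineage strain sets plus 20 threshold-graph oracle comparisons,
randomization-test calibration over 500 null datasets × 1000 shuffles with
power measured over 100 datasets at an odds ratio of 10, and byte-level
reproducibility of two full pipeline runs. These sizes give the binomial
assertions comfortable margins while keeping a full run of the suite in
the low minutes on one core.
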