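---
title: "Fitness landscapes, restriction DAGs, and tumor simulation: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fitness landscapes, restriction DAGs, and tumor simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`cpmland` studies the correspondence — and its failure — between fitness
landscapes and the DAGs of restrictions inferred by cancer progression
models (CPMs). This vignette documents the models the package implements,
the parameters that matter, the design choices made where the design was
genuinely open, and the limits of what the synthetic experiments can show.

## Genotype space and accessibility

Genotypes are vectors of `m` biallelic loci, encoded as integers in
`0:(2^m - 1)` (bit `k` = state of gene `k`, wild type = 0). A fitness
landscape assigns each genotype a positive birth rate, normalized so the
wild type is 1; genotypes at or below `lethal_threshold` (default `1e-9`)
are effectively non-viable. Because the evolutionary model forbids back
mutation, adaptation proceeds only through mutation gains, and a genotype
is *accessible* when some chain of single gains from the wild type
increases fitness strictly at every step. Accessibility is computed by
dynamic programming over mutation counts; every non-WT accessible genotype
therefore has an accessible, strictly less fit, immediate predecessor.

**Peaks.** Two notions of local maximum are exposed. The default,
`landscape_peaks(neighbors = "gain")`, counts genotypes with no fitter
single-*gain* neighbor: the possible end points of adaptive walks in a
process without back mutation, which is the process actually simulated.
`neighbors = "all"` gives the classical landscape-theory peak (strictly
fitter than all Hamming-1 neighbors in both directions). The gain-only
default was a deliberate choice: under the both-directions definition the
mean accessible-peak count of the Rough Mount Fuji family saturates near
10 at `m = 7` even in the pure House-of-Cards limit, which is incompatible
with the ruggedness this family is meant to exhibit (a mean near 11.5
accessible peaks alongside a reciprocal-sign fraction near 0.27); the
gain-only count reproduces both simultaneously and is the quantity with a
direct evolutionary meaning here.

**Epistasis squares.** For loci `i`, `j` on a background with both loci
unmutated, the four genotypes `b, b+i, b+j, b+i+j` form a square,
classified by the two focal-effect sign patterns: reciprocal sign
epistasis when both effects strictly reverse sign across the other locus's
background, sign epistasis when exactly one reverses, magnitude epistasis
when neither reverses but the interaction is non-zero, additive otherwise.
Zero differences (exact ties, and ties up to a relative tolerance of
`1e-9` to absorb floating-point noise) count as *no* sign change:
continuous random fitness makes true ties measure-zero, and this choice
avoids spurious epistasis classes on degenerate hand-built fixtures.
`rse_fraction()` aggregates per square (all `choose(m, 2) * 2^(m-2)`
squares) by default; per-locus-pair aggregation (a pair counts if *any* of
its backgrounds shows reciprocal sign) is available via `per = "pair"`.
The per-square fraction is invariant under gene relabeling and under any
strictly monotone transformation of the fitness values.

## DAGs of restrictions

A restriction DAG has gene nodes plus a distinguished Root; an edge
`i -> j` makes a mutation in `j` conditional on `i`, and multiple parents
are conjunctive. A genotype is *compatible* when every mutated gene has
all of its gene parents mutated. Validity requires acyclicity, no edges
into Root, and every gene reachable from Root. All comparisons between
DAGs go through the transitive reduction (unique for DAGs), with Root
edges recomputed so that exactly the genes without gene parents carry one.
The distance between two DAGs is the size of the symmetric difference of
the reduced edge sets; the relative distance divides by the union size.
Root edges are included by default: two DAGs differing only in which genes
attach to Root encode genuinely different restriction structures
(`include_root = FALSE` gives the other convention). A landscape is
*representable* by a DAG when its accessible set equals the DAG's
compatible set.

## Random landscape families

All families default to `m = 7` genes.

* **DAG-derived, representable.** A random DAG (uniform random topological
  order; each forward edge included with probability `edge_prob`;
  parentless genes attached to Root; transitively reduced), then
  multiplicative fitness `prod(1 + s_i)` over the mutated genes of every
  compatible genotype, `s_i ~ U(0.1, 0.7)`; incompatible genotypes get
  `lethal_fitness = 1e-9`. These landscapes are representable by the
  generating DAG by construction and contain no reciprocal sign epistasis.
* **DAG-derived, non-representable.** Starting from a representable
  landscape, a uniformly sized random subset (1 up to all) of the
  accessible genotypes with at least two mutations is made non-viable —
  synthetic lethals, hence reciprocal sign epistasis. Draws are retried
  until every gene remains present in at least one accessible genotype;
  when a landscape admits no such subset the landscape itself is redrawn
  (`random_nonrepresentable_landscape()`).
* **Rough Mount Fuji (RMF).** Raw value `F(g) = -c * d(g, ref) + eps_g`
  with the reference genotype uniform over all genotypes,
  `c ~ U(0, 1.15)`, and `eps_g ~ N(0, 1)`; birth rate
  `exp(rmf_sigma * F)`, normalized to WT = 1. Only the slope/noise *ratio*
  affects ranks, hence accessibility, peaks and all epistasis sign
  statistics; the family spans near-additive (`c` large) to
  House-of-Cards (`c ~ 0`).

**Calibration.** The generator defaults are the package's study
conditions, fixed once: `edge_prob = 0.28` and the RMF slope support
`c(0, 1.15)` were chosen so that, at `m = 7`, the two seven-gene families
jointly reproduce the target summary statistics of this experimental
design — mean per-square reciprocal-sign fraction ≈ 0.27 and mean
accessible peaks ≈ 11.5 for RMF, versus ≈ 0.02 and ≈ 2.8 for the
non-representable DAG-derived family (measured at 600–1000 landscapes:
0.266/11.7 and 0.022/2.75). `rmf_sigma = 0.3` scales RMF birth rates to
the same order as the multiplicative family (maximum ≈ `e^1.8` versus
`1.7^7 ≈ 41`); it does not touch any rank statistic but keeps simulated
tumor dynamics on a common footing across families.

## The tumor simulator

A continuous-time multitype birth–death process started from `N0 = 2000`
wild-type cells. Per-cell birth rate = the clone's landscape fitness;
per-cell death rate `D(N) = log(1 + N/K)` with `K = N0/(e - 1)`, so
`D(N0) = 1` and a wild-type population starts at equilibrium (the neutral
check in the test suite verifies the mean stays within Monte Carlo error
of `N0`). On each division the daughter gains a mutation in one of its
unmutated genes with that gene's rate (no back mutation; simultaneous
double mutations are neglected, their probability being of order `u^2`
with `u <= 5e-5`). Mutation schemes: common `1e-5`, common `1e-6`, or
gene-specific rates geometrically spaced on `[2e-6, 5e-5]` (geometric mean
exactly `1e-5`), randomly assigned to genes.

**Detection** is checked on a fixed schedule with probability
`p(N) = 1 - exp(-k * max(0, N/N0 - 1))`, with `k` anchored so that
`p(2 N0)` is 0.1 (fast) or 0.01 (slow). The check interval defaults to 20
time units. This interval is a genuine modelling degree of freedom: with
per-unit checks, detection is dominated by drift excursions around `N0`
and the pooled detection-size median collapses to a few thousand cells,
while 20-unit checks give pooled quartiles (about 6k / 31k median over the
mutation-scheme × regime grid used in the tests) consistent with a process
whose detected tumors are mostly post-adaptation. The slow regime's upper
tail is heavier than ideal — between two checks a fit clone can grow far
past the size at which detection became likely — and is a known
limitation of sparse checking.

**Backends.** The default backend is tau-leaping (`tau = 0.05` time units;
per-capita rates are of order 1, so per-step event probabilities per cell
stay at a few percent), with Poisson/binomial draws switching to a normal
approximation above `1e8` expected events so that very fit clones between
detection checks neither overflow nor stall, and with mutants allocated to
target genes in bulk via multinomial draws. An exact event-by-event
Gillespie backend is provided for small populations; the test suite
verifies the two agree in distribution on a three-gene fixture
(Kolmogorov–Smirnov on final size, chi-squared on mutant presence, at
significance 0.01). Extinction before detection triggers a restart (the
attempt count is reported), conditioning on tumors that progress, and a
`max_time` horizon turns non-progressing runs into explicit errors rather
than silent hangs.

**Sampling.** Whole-tumor sampling calls gene `i` mutated when its cell
fraction reaches `sample_threshold` (default 0.5), giving one genotype per
tumor. `simulate_nonzero_cohort()` discards all-zero samples, mirroring
empirical cohorts restricted to patients with at least one mutation.

## The baseline learner

`learn_conjunctive_dag()` proposes `i -> j` when mutations in `j`
essentially never occur without `i` (violation fraction at most `epsilon`,
default 0.005) and `i` is at least as frequent as `j` (a temporal-priority
tie-break); mutual proposals keep the more frequent parent (exact ties
drop both), residual cycles — possible only among equal-frequency,
perfectly co-occurring genes — are dissolved by dropping all edges inside
the affected strongly connected components, and the result is reduced with
Root edges completed. On a noiseless cohort containing every compatible
genotype of a generating DAG at positive frequency, with `epsilon = 0`,
the learner provably recovers the generating reduced DAG: direct parents
are strictly more frequent than children and never violated; non-ancestors
are always violated; indirect ancestors are removed by the reduction. It
is deliberately *not* CBN or CAPRI — it exists so the metrics and
variability analyses run end-to-end without external software, and every
metric accepts imported DAGs (`import_dag()`, which always reduces, since
external tools may emit indirect edges) interchangeably.

## Misprediction and variability measures

With the wild type excluded from every set (it is trivially shared and
would dilute all ratios): PFD = |compatible \ accessible| / |compatible|
(1 − precision; `NA` when the DAG predicts nothing), and
PND = |reference \ compatible| / |reference| (1 − recall; `NA` on an empty
reference). The PND reference is the *observable* accessible set: the
accessible genotypes seen with frequency strictly greater than 5/1000 in a
large cohort simulated under the same condition, so that inferences are
not penalized for genotypes that are accessible but essentially never
observed — at that minimal frequency the probability of missing the
genotype in a sample of 1000 is `0.995^1000 ≈ 0.0067 < 1%`. Replicate-DAG
variability is summarized by the plug-in Gini–Simpson index over distinct
reduced DAGs (the `n/(n-1)`-corrected estimator is available by flag) and
by the mean pairwise relative DAG distance, within each condition and
pooled across conditions; landscape divergence by the symmetric difference
of accessible sets over their union.

## Cohort matching

`find_matched_landscapes()` searches for landscapes that could plausibly
have generated an observed cohort: candidates come from
`matched_rmf_landscape()` — an RMF draw post-processed so every observed
mutated genotype is accessible, by raising any non-increasing step of one
uniformly random maximal mutation chain per observed genotype by a factor
`1 + U(0.01, 0.1)`, re-verified and retried because later bumps can
disturb earlier chains — paired with mutation scheme and detection regime
drawn uniformly from their menus. Each candidate is simulated
`n_reps = 10` times at the observed cohort size (mutated samples only; the
sampler draws until the target count is reached, so simulated wild-type
tumors are excluded exactly as empirical all-zero patients are), and each
repetition is compared with the observed genotype distribution by a
2 × k chi-squared test over the union of observed genotype categories,
with no low-count pooling: the permutation test (label reshuffling over
the pooled samples) is the remedy for sparse cells, and both the
asymptotic and the permutation p-value must exceed `p_threshold = 0.6`,
with all genes observed, in at least `min_pass = 3` repetitions. The
per-repetition p-values and coverage flags are logged, making the
acceptance decision replayable. The demanding threshold keeps only
landscapes that *consistently* produce data a practitioner would accept as
equivalent to the observed cohort; the package's desk-scale demonstrations
use smaller cohorts and looser thresholds because the acceptance rate of
random candidates is low by design.

## Orchestration and problem sizes

`run_landscape_study()` runs the factorial design generate → simulate →
split → learn → score and emits tidy tables (per-landscape summaries,
per-replicate PFD/PND, within- and across-condition variability, and a
failure log with provenance for cells whose simulation did not complete).
`run_cancer_study()` runs matching, replicate inference per accepted
landscape, and between-landscape divergence tables. Defaults are desk
scale; the published-scale design (100 + 200 + 200 landscapes, three
mutation schemes by two detection regimes, 20 000 tumors per cell split
into 20 sets of 1000, 150 accepted landscapes per cohort) is expressible
purely through the configuration objects. The bundled test suite uses
seven-gene landscapes for everything that does not require simulation
(50-landscape round trips, 200-landscape family statistics,
1000+ randomized brute-force comparisons at `m <= 5`) and scales
simulation-bound checks to a few landscapes × conditions × tens of runs;
the acceptance script regenerates 400 landscapes per family. These sizes
were chosen so a full run completes comfortably on a laptop while keeping
Monte Carlo standard errors well inside the tolerances asserted.

## What the synthetic experiments do and do not show

The generators emulate the *structure* of the study — known ground-truth
landscapes, factorial mutation/detection conditions, cross-sectional
sampling at detection — so that every claim about mispredictions and
variability can be checked against a known truth. They do not emulate
several features of real tumor data: passenger mutations and
driver-calling errors (genotypes are observed without error, and all genes
are known drivers), spatial structure, treatment, back mutation, or
disjunctive (OR) dependency semantics. Stand-in cohorts shaped like
published pancreatic / colorectal / glioblastoma datasets
(`synthetic_cancer_cohort()`) are simulated from seeded random landscapes
— they carry their generating truth for recovery tests and are labelled
synthetic; nothing in the package redistributes or reconstructs the
original patient matrices. Consequently, passing tests demonstrate the
internal consistency of the pipeline and the qualitative phenomena
(representable landscapes are perfectly described by their DAGs;
reciprocal sign epistasis degrades DAG predictions; replicate inferences
vary; widely different landscapes match the same cohort) — not the
quantitative behavior of CBN or CAPRI on real data, which depends on those
external tools and on cohorts this package does not ship.
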