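# cpmland

Cancer progression models (CPMs) such as CBN and CAPRI take cross-sectional
tumor mutation data — a binary patients × genes matrix — and infer a
directed acyclic graph (DAG) of restrictions: an edge *i → j* means a
mutation in gene *j* can only occur once *i* is mutated, and multiple
parents are conjunctive (AND). A fitness landscape, by contrast, assigns a
fitness (here, a birth rate) to every genotype over *m* biallelic loci and
thereby fixes the set of *accessible* genotypes: those reachable from the
wild type through single-mutation gains along which fitness strictly
increases. A landscape is *representable* by a DAG when the accessible set
equals the DAG's compatible set — which is impossible whenever the
landscape contains reciprocal sign epistasis (two individually beneficial
mutations that are jointly deleterious, e.g. synthetic lethality between
drivers).

`cpmland` is a simulation laboratory for studying that gap. It provides:

* **Genotype space** — accessibility, fitness peaks, and classification of
  every two-locus square into no/magnitude/sign/reciprocal-sign epistasis
  (`accessible_genotypes()`, `landscape_peaks()`, `classify_square()`,
  `rse_fraction()`).
* **DAGs of restrictions** — construction and validation, AND-semantics
  compatible sets, transitive reduction, symmetric-difference edge
  distances, representability tests, and a plain edge-list file dialect
  for importing DAGs produced by external CPM software
  (`restriction_dag()`, `compatible_genotypes()`, `transitive_reduction()`,
  `dag_distance()`, `is_representable()`, `read_dag()`, `import_dag()`).
* **Random landscape generators** — DAG-derived representable landscapes
  (multiplicative effects *1 + s*, *s ~ U(0.1, 0.7)*), non-representable
  variants created by knocking out random accessible multi-mutants
  (synthetic lethals), and Rough Mount Fuji (RMF) landscapes with a random
  reference genotype and random slope/noise ratio spanning near-additive
  to House-of-Cards (`dag_derived_landscape()`,
  `make_non_representable()`, `rmf_landscape()`).
* **Tumor simulator** — continuous-time multitype birth–death process with
  density-dependent death *D(N) = log(1 + N/K)*, per-gene mutation on
  division without back mutation, stochastic size-dependent detection
  (fast/slow regimes anchored at detection probability 0.1/0.01 when the
  tumor doubles), and whole-tumor sampling at a cell-fraction threshold
  (`simulate_to_detection()`, `whole_tumor_sample()`,
  `simulate_dataset()`).
* **A baseline conjunctive learner** (`learn_conjunctive_dag()`) — *not* a
  CBN/CAPRI re-implementation, but a simple violation-threshold learner
  that recovers generating DAGs exactly on noiseless exhaustive cohorts,
  so the whole pipeline runs end-to-end without external binaries.
* **Misprediction and variability metrics** — PFD (1 − precision: DAG
  predicts genotypes that are not accessible), PND (1 − recall, with an
  observability correction that only counts accessible genotypes seen at
  frequency > 5/1000 in a large reference cohort), Gini–Simpson diversity
  of replicate DAGs, mean pairwise relative DAG distances, and
  accessible-set differences between landscapes (`pfd()`, `pnd()`,
  `observable_accessible()`, `gini_simpson()`, `dag_variability()`,
  `accessible_set_difference()`).
* **Cohort matching** — the acceptance loop that searches for landscapes
  (plus mutation/detection settings) whose simulated genotype frequencies
  are statistically indistinguishable from an observed cohort, via a
  chi-squared test with both asymptotic and permutation p-values
  (`genotype_chi2_test()`, `find_matched_landscapes()`), demonstrating the
  many-to-many relationship: widely different landscapes produce data like
  the observed ones and lead to widely different inferred DAGs.
* **Study orchestration** — `run_landscape_study()` (factorial: landscape
  families × mutation schemes × detection regimes → replicate DAGs →
  tidy metric tables) and `run_cancer_study()` (matching → replicate
  inference → within/between-landscape variability tables), both desk
  scale by default and paper scale by configuration.

## Worked example

```r
library(cpmland)
set.seed(1)

gp  <- gen_params()                   # 7 genes, calibrated defaults
dag <- random_restriction_dag(gp)     # random reduced DAG of restrictions
fl  <- dag_derived_landscape(dag, gp) # representable landscape

is_representable(fl, dag)             # TRUE
pfd(dag, fl); pnd(dag, fl)            # 0 and 0: perfect self-description

nr <- make_non_representable(fl, gp)  # knock out accessible multi-mutants
is_representable(nr, dag)             # FALSE
rse_fraction(nr)                      # 0.0208: reciprocal sign epistasis
pfd(dag, nr)                          # 0.3548: the DAG now over-predicts

co  <- simulate_dataset(fl, sim_params(), n_samples = 200)
d2  <- learn_conjunctive_dag(co, learner_config(epsilon = 0.01))
dag_distance(dag, d2)                 # count 3, relative 0.3
```

On the representable landscape the generating DAG scores `pfd = 0` and
`pnd = 0` by construction. After the knockout, about a third of the
genotypes the DAG still predicts are no longer accessible (`pfd` = 0.3548
above), and no DAG of restrictions can represent the new landscape: that
is the signature of reciprocal sign epistasis. Even on the representable
landscape, a DAG learned from 200 simulated tumors differs from the truth
in 3 of 10 distinct reduced edges (relative distance 0.3): finite-sample
inferences of restrictions are unstable.

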