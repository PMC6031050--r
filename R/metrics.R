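# Performance and variability measures relating DAGs of restrictions,
# fitness landscapes, and replicate inferences.  The wild type is excluded
# from every genotype set entering a ratio: it is trivially shared by all
# DAGs and landscapes and would dilute the measures.

acc_no_wt <- function(landscape) setdiff(accessible_genotypes(landscape), 0L)
comp_no_wt <- function(dag) compatible_genotypes(dag, exclude_wt = TRUE)

check_same_genes <- function(a, b) {
  if (!identical(a$genes, b$genes))
    stop("gene sets (and their order) must match")
}

#' Observable accessible genotypes
#'
#' The subset of accessible genotypes (wild type excluded) observed in a
#' large reference cohort with frequency strictly greater than `min_freq`.
#' The default 5/1000 makes the probability of missing a minimally
#' qualifying genotype in a sample of 1000 equal to `0.995^1000 < 1%`,
#' so the false-negative reference set only contains genotypes a sample of
#' that size would essentially always contain.
#'
#' @param landscape a [fitness_landscape()].
#' @param big_cohort cohort matrix simulated from the same landscape and
#'   condition.
#' @param min_freq frequency cut-off (strict inequality; default 0.005).
#' @return integer vector of genotype indices.
#' @export
observable_accessible <- function(landscape, big_cohort, min_freq = 0.005) {
  stopifnot_landscape(landscape)
  big_cohort <- as_cohort(big_cohort)
  if (ncol(big_cohort) != landscape$m)
    stop("cohort gene count does not match the landscape")
  freq <- cohort_genotype_freq(big_cohort)
  seen <- as.integer(names(freq)[freq > min_freq])
  sort(intersect(setdiff(seen, 0L), acc_no_wt(landscape)))
}

#' Proportion of false discoveries (PFD) of a DAG
#'
#' Fraction of the genotypes predicted to exist by the DAG (compatible,
#' wild type excluded) that are not accessible in the landscape;
#' equivalent to 1 - precision.  `NA` if the DAG predicts no mutated
#' genotype.
#'
#' @param dag a [restriction_dag()].
#' @param landscape a [fitness_landscape()] over the same genes.
#' @return fraction in `[0, 1]`, or `NA`.
#' @export
pfd <- function(dag, landscape) {
  stopifnot_dag(dag); stopifnot_landscape(landscape)
  check_same_genes(dag, landscape)
  comp <- comp_no_wt(dag)
  if (length(comp) == 0) return(NA_real_)
  length(setdiff(comp, acc_no_wt(landscape))) / length(comp)
}

#' Proportion of negative discoveries (PND) of a DAG
#'
#' Fraction of the reference accessible genotypes that the DAG fails to
#' predict; equivalent to 1 - recall.  The reference defaults to all
#' accessible genotypes (wild type excluded) but is normally the
#' observability-corrected set from [observable_accessible()], so that
#' inferences are not penalized for genotypes that are accessible but
#' essentially never observed under a given mutation/detection condition.
#'
#' @inheritParams pfd
#' @param observable reference set of genotype indices; must be a subset
#'   of the landscape's accessible genotypes.
#' @return fraction in `[0, 1]`, or `NA` if the reference set is empty.
#' @export
pnd <- function(dag, landscape, observable = NULL) {
  stopifnot_dag(dag); stopifnot_landscape(landscape)
  check_same_genes(dag, landscape)
  acc <- acc_no_wt(landscape)
  if (is.null(observable)) observable <- acc
  observable <- setdiff(as.integer(observable), 0L)
  if (!all(observable %in% acc))
    stop("observable set must be a subset of the accessible genotypes")
  if (length(observable) == 0) return(NA_real_)
  length(setdiff(observable, comp_no_wt(dag))) / length(observable)
}

canonical_dag_key <- function(dag) {
  paste(sort(edge_keys(transitive_reduction(dag))), collapse = ";")
}

#' Gini-Simpson diversity of a set of DAGs
#'
#' `1 - sum(p_k^2)` over the frequencies of distinct transitively reduced
#' DAGs (identity = exact reduced edge-set equality): the probability that
#' two DAGs drawn from the set differ.  The plug-in estimator is the
#' default; `corrected = TRUE` applies the `n/(n-1)` small-sample factor.
#'
#' @param dags list of at least two [restriction_dag()]s.
#' @param corrected apply the unbiased-estimator correction.
#' @return value in `[0, 1 - 1/n]` (plug-in) or `[0, 1]` (corrected).
#' @export
gini_simpson <- function(dags, corrected = FALSE) {
  if (length(dags) < 2) stop("need at least 2 DAGs")
  keys <- vapply(dags, canonical_dag_key, character(1))
  p <- as.numeric(table(keys)) / length(keys)
  gs <- 1 - sum(p^2)
  if (corrected) gs <- gs * length(keys) / (length(keys) - 1)
  gs
}

#' Mean pairwise relative DAG distance
#'
#' Average of [dag_distance()]'s relative component over all unordered
#' pairs of the supplied DAGs.
#'
#' @param dags list of at least two [restriction_dag()]s over a common
#'   gene set.
#' @param include_root passed to [dag_distance()].
#' @return fraction in `[0, 1]`.
#' @export
mean_pairwise_dag_distance <- function(dags, include_root = TRUE) {
  if (length(dags) < 2) stop("need at least 2 DAGs")
  reduced <- lapply(dags, transitive_reduction)
  keys <- lapply(reduced, edge_keys, include_root = include_root)
  n <- length(keys)
  tot <- 0
  for (a in 1:(n - 1)) {
    for (b in (a + 1):n) {
      sd <- length(setdiff(keys[[a]], keys[[b]])) +
        length(setdiff(keys[[b]], keys[[a]]))
      un <- length(union(keys[[a]], keys[[b]]))
      tot <- tot + if (un == 0) 0 else sd / un
    }
  }
  tot / (n * (n - 1) / 2)
}

#' Within- and across-condition DAG variability
#'
#' For replicate DAG inferences grouped by experimental condition,
#' computes the mean pairwise relative DAG distance and Gini-Simpson
#' diversity within each condition, and the same two summaries over all
#' replicates pooled across conditions.
#'
#' @param dags list of [restriction_dag()]s.
#' @param groups factor (or vector) of condition labels, one per DAG.
#' @param include_root passed to [dag_distance()].
#' @return list with `within` (data frame: group, n, mean_rel_distance,
#'   gini_simpson) and `across` (named numeric vector with the pooled
#'   summaries).
#' @export
dag_variability <- function(dags, groups, include_root = TRUE) {
  stopifnot(length(dags) == length(groups))
  groups <- as.factor(groups)
  within <- do.call(rbind, lapply(levels(groups), function(g) {
    sub <- dags[groups == g]
    data.frame(group = g, n = length(sub),
               mean_rel_distance =
                 if (length(sub) >= 2)
                   mean_pairwise_dag_distance(sub, include_root) else NA_real_,
               gini_simpson =
                 if (length(sub) >= 2) gini_simpson(sub) else NA_real_)
  }))
  across <- c(mean_rel_distance =
                if (length(dags) >= 2)
                  mean_pairwise_dag_distance(dags, include_root) else NA_real_,
              gini_simpson =
                if (length(dags) >= 2) gini_simpson(dags) else NA_real_)
  list(within = within, across = across)
}

#' Difference between the accessible sets of two landscapes
#'
#' Symmetric-difference count of the two accessible genotype sets (wild
#' type excluded) and the relative difference (count divided by the size
#' of the union of the two sets).
#'
#' @param l1,l2 [fitness_landscape()]s over the same genes.
#' @return named numeric vector `c(count = ..., relative = ...)`.
#' @export
accessible_set_difference <- function(l1, l2) {
  stopifnot_landscape(l1); stopifnot_landscape(l2)
  check_same_genes(l1, l2)
  a1 <- acc_no_wt(l1)
  a2 <- acc_no_wt(l2)
  sd <- length(setdiff(a1, a2)) + length(setdiff(a2, a1))
  un <- length(union(a1, a2))
  c(count = sd, relative = if (un == 0) 0 else sd / un)
}
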