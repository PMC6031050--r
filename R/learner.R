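# Obtaining DAGs of restrictions from cohort matrices.
#
# `import_dag()` brings in DAGs inferred by external cancer progression
# model software (CBN, CAPRI, ...) through the shared edge-list dialect.
# `learn_conjunctive_dag()` is a deliberately simple baseline conjunctive
# learner -- NOT a reimplementation of CBN or CAPRI -- provided so that the
# misprediction and variability metrics can be exercised end-to-end
# without external binaries.  All downstream metrics accept any
# `restriction_dag` regardless of origin.

#' Baseline learner configuration
#'
#' @param epsilon tolerated violation fraction for a dependency: an edge
#'   `i -> j` may be proposed only if the fraction of samples mutated in
#'   `j` but not in `i` (among samples mutated in `j`) is at most
#'   `epsilon` (default 0.005).
#' @param min_count minimum number of mutated samples for a gene to take
#'   part in dependency assessment (default 5).
#' @return a list of class `learner_config`.
#' @export
learner_config <- function(epsilon = 0.005, min_count = 5) {
  stopifnot(epsilon >= 0, epsilon < 0.5, min_count >= 1)
  structure(list(epsilon = epsilon, min_count = as.integer(min_count)),
            class = "learner_config")
}

#' Learn a conjunctive DAG of restrictions from a cohort
#'
#' Proposes an edge `i -> j` when mutations in `j` essentially never occur
#' without `i` (violation fraction `<= epsilon`) and `i` is at least as
#' frequent as `j` (a temporal-priority tie-break in the spirit of, but
#' not equivalent to, CAPRI's heuristic).  Mutual proposals keep the
#' higher-marginal-frequency parent (ties drop both directions); any
#' remaining directed cycles (possible only among equal-frequency,
#' perfectly co-occurring genes) are dissolved by dropping all edges
#' inside the affected strongly connected components.  The result is
#' transitively reduced with Root edges completed.
#'
#' On a noiseless cohort containing every genotype compatible with a
#' generating DAG (each at positive frequency) and `epsilon = 0`, the
#' learner recovers exactly the generating reduced DAG.
#'
#' @param cohort a cohort matrix (see [as_cohort()]).
#' @param config a [learner_config()].
#' @return a reduced [restriction_dag()] over the cohort's genes.
#' @export
learn_conjunctive_dag <- function(cohort, config = learner_config()) {
  cohort <- as_cohort(cohort)
  if (all(cohort == 0)) stop("cohort has no mutations")
  genes <- colnames(cohort)
  m <- length(genes)
  n_mut <- colSums(cohort)
  freq <- n_mut / nrow(cohort)
  assess <- n_mut >= config$min_count
  adj <- matrix(FALSE, m, m, dimnames = list(genes, genes))
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      if (i == j || !assess[i] || !assess[j]) next
      viol <- sum(cohort[, j] == 1 & cohort[, i] == 0) / n_mut[j]
      if (viol <= config$epsilon && freq[i] >= freq[j]) adj[i, j] <- TRUE
    }
  }
  # mutual proposals: keep the higher-frequency parent; exact ties drop both
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      if (adj[i, j] && adj[j, i]) {
        if (freq[i] > freq[j]) adj[j, i] <- FALSE
        else if (freq[j] > freq[i]) adj[i, j] <- FALSE
        else adj[i, j] <- adj[j, i] <- FALSE
      }
    }
  }
  # longer cycles require equal frequencies all around; drop intra-SCC edges
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "directed")
  comp <- igraph::components(g, mode = "strong")$membership
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      if (adj[i, j] && comp[i] == comp[j]) adj[i, j] <- FALSE
    }
  }
  root <- colSums(adj) == 0
  dag <- structure(list(genes = genes,
                        root = stats::setNames(root, genes), adj = adj),
                   class = "restriction_dag")
  transitive_reduction(dag)
}

#' Import a DAG inferred by external software
#'
#' Reads the edge-list dialect of [read_dag()] and always transitively
#' reduces (external tools may report both direct and indirect edges).
#'
#' @inheritParams read_dag
#' @return a reduced [restriction_dag()].
#' @export
import_dag <- function(path, genes = NULL) {
  transitive_reduction(read_dag(path, genes = genes))
}
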