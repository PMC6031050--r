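# Synthetic fixtures: small worked DAG/landscape pairs and simulated
# stand-in cohorts emulating published cross-sectional cancer datasets
# (which are not redistributable), with their generating ground truth
# retained for parameter-recovery tests.

#' Worked example DAG/landscape fixtures
#'
#' Two classic restriction structures with representable landscapes built
#' by [dag_derived_landscape()], plus a non-representable variant:
#' * `chain`: 5 genes, `Root->A, A->B` and the indirect-dependency chain
#'   `Root->F, F->G, G->H`;
#' * `conjunction`: 4 genes, `A` and `B` both parents of `D` (AND), `C`
#'   unconstrained;
#' * `knockout`: the `conjunction` landscape with genotype `{A, C}` made
#'   non-viable -- reciprocal sign epistasis between `A` and `C` that no
#'   DAG of restrictions can represent.
#'
#' @param seed seed for the landscape effect draws (default 1).
#' @return named list of lists with elements `dag` and `landscape`
#'   (`knockout` shares the `conjunction` DAG).
#' @export
example_fixtures <- function(seed = 1) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  chain_dag <- restriction_dag(rbind(c("Root", "A"), c("A", "B"),
                                     c("Root", "F"), c("F", "G"),
                                     c("G", "H")),
                               genes = c("A", "B", "F", "G", "H"))
  chain_fl <- dag_derived_landscape(chain_dag, gen_params(m = 5))
  conj_dag <- restriction_dag(rbind(c("Root", "A"), c("Root", "B"),
                                    c("Root", "C"), c("A", "D"),
                                    c("B", "D")),
                              genes = c("A", "B", "C", "D"))
  conj_fl <- dag_derived_landscape(conj_dag, gen_params(m = 4))
  ko_fl <- conj_fl
  ac <- genotype_index(c(1, 0, 1, 0))  # genotype {A, C}
  ko_fl$fitness[ac + 1L] <- 1e-9
  list(chain = list(dag = chain_dag, landscape = chain_fl),
       conjunction = list(dag = conj_dag, landscape = conj_fl),
       knockout = list(dag = conj_dag, landscape = ko_fl))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Simulate a synthetic stand-in cohort
#'
#' Simulates a patients-by-genes binary matrix from a known source
#' landscape (see [simulate_nonzero_cohort()]), keeping the generating
#' landscape and settings as attributes so downstream inferences can be
#' scored against ground truth.  With `require_nonzero` every patient has
#' at least one mutation, as in empirical cohorts restricted to patients
#' with mutations.
#'
#' @param n_patients number of patients.
#' @param landscape source [fitness_landscape()].
#' @param params a [sim_params()].
#' @param require_nonzero discard all-zero samples (default `TRUE`).
#' @return cohort matrix with attributes `landscape` and `sim_params`.
#' @export
synthetic_cohort <- function(n_patients, landscape, params = sim_params(),
                             require_nonzero = TRUE) {
  cohort <- if (require_nonzero) {
    simulate_nonzero_cohort(landscape, params, n_samples = n_patients)
  } else {
    simulate_dataset(landscape, params, n_samples = n_patients)
  }
  attr(cohort, "landscape") <- landscape
  attr(cohort, "sim_params") <- params
  cohort
}

#' Synthetic stand-in for an empirical cancer cohort
#'
#' Emulates the shape of published cross-sectional datasets -- pancreatic
#' (90 patients, 7 genes), colorectal (90 patients, 8 genes) and
#' glioblastoma (67 patients, 8 genes), each patient with at least one
#' mutation -- by simulating from a seeded random DAG-derived landscape.
#' These are synthetic stand-ins, not the original matrices; the
#' generating landscape travels with the cohort as ground truth.
#'
#' @param dataset one of `"pancreatic"`, `"colorectal"`, `"glioblastoma"`.
#' @param seed seed controlling landscape generation and simulation.
#' @param params a [sim_params()]; smaller `N0` makes generation cheaper
#'   without changing the cohort schema.
#' @return cohort matrix with attributes `landscape`, `dag` and
#'   `sim_params`.
#' @export
synthetic_cancer_cohort <- function(dataset = c("pancreatic", "colorectal",
                                                "glioblastoma"),
                                    seed = 1, params = sim_params()) {
  dataset <- match.arg(dataset)
  dims <- switch(dataset,
                 pancreatic = c(n = 90, m = 7),
                 colorectal = c(n = 90, m = 8),
                 glioblastoma = c(n = 67, m = 8))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  gp <- gen_params(m = dims[["m"]])
  dag <- random_restriction_dag(gp)
  fl <- dag_derived_landscape(dag, gp)
  cohort <- synthetic_cohort(dims[["n"]], fl, params)
  attr(cohort, "dag") <- dag
  cohort
}
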