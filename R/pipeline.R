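# Orchestration of the factorial experiments: generate landscapes,
# simulate cohorts per mutation/detection condition, split into replicate
# sets, learn DAGs, and score mispredictions and variability.  Defaults
# are desk scale; the published-study scale (500 landscapes, 20 000
# simulated genotypes per condition split into 20 sets of 1000) is just a
# larger configuration.

#' Configuration of a landscape study
#'
#' @param n_representable,n_nonrepresentable,n_rmf number of landscapes
#'   per family (study scale: 100, 200, 200).
#' @param gen a [gen_params()] shared by the generators.
#' @param schemes mutation schemes to cross (subset of the
#'   [sim_params()] menu).
#' @param regimes detection regimes to cross.
#' @param sims_per_condition simulated tumors per landscape-by-condition
#'   cell (study scale: 20 000); must be divisible by `n_splits`.
#' @param n_splits replicate sets per cell (study scale: 20 sets of 1000).
#' @param sim a [sim_params()] template (its scheme/regime fields are
#'   overridden per condition).
#' @param learner a [learner_config()] for the baseline DAG learner.
#' @param min_freq observability cut-off for the PND reference set.
#' @return a list of class `experiment_config`.
#' @export
experiment_config <- function(n_representable = 2, n_nonrepresentable = 2,
                              n_rmf = 2, gen = gen_params(),
                              schemes = c("common_1e-5"),
                              regimes = c("fast"),
                              sims_per_condition = 100, n_splits = 4,
                              sim = sim_params(), learner = learner_config(),
                              min_freq = 0.005) {
  if (sims_per_condition %% n_splits != 0)
    stop("sims_per_condition must be divisible by n_splits")
  structure(list(n_representable = n_representable,
                 n_nonrepresentable = n_nonrepresentable, n_rmf = n_rmf,
                 gen = gen, schemes = schemes, regimes = regimes,
                 sims_per_condition = sims_per_condition,
                 n_splits = n_splits, sim = sim, learner = learner,
                 min_freq = min_freq),
            class = "experiment_config")
}

generate_study_landscapes <- function(config) {
  gp <- config$gen
  out <- list()
  add <- function(fl, dag, family) {
    out[[length(out) + 1]] <<- list(id = length(out) + 1, family = family,
                                    landscape = fl, dag = dag)
  }
  for (i in seq_len(config$n_representable)) {
    dag <- random_restriction_dag(gp)
    add(dag_derived_landscape(dag, gp), dag, "representable")
  }
  for (i in seq_len(config$n_nonrepresentable)) {
    nr <- random_nonrepresentable_landscape(gp)
    add(nr$landscape, nr$dag, "nonrepresentable")
  }
  for (i in seq_len(config$n_rmf)) {
    add(rmf_landscape(gp), NULL, "rmf")
  }
  out
}

#' Run the landscape factorial study
#'
#' For every generated landscape and every mutation-scheme-by-detection
#' condition: simulate `sims_per_condition` tumors, split them into
#' `n_splits` replicate cohorts, learn a DAG of restrictions from each
#' replicate, and score each DAG (PFD; PND against the
#' observability-corrected reference measured on the full condition
#' dataset).  Variability of the replicate DAGs is summarized within each
#' condition and across conditions of each landscape.
#'
#' @param config an [experiment_config()].
#' @return list of tidy data frames: `landscapes` (per-landscape summary:
#'   family, reciprocal sign epistasis fraction, accessible set size,
#'   accessible peak count), `metrics` (one row per landscape x condition
#'   x replicate: pfd, pnd), `variability` (per landscape x condition
#'   plus the pooled across-condition row per landscape), and `failures`
#'   (cells whose simulation failed, with provenance; `NULL` if none).
#' @export
run_landscape_study <- function(config = experiment_config()) {
  specs <- generate_study_landscapes(config)
  land_rows <- list(); metric_rows <- list(); var_rows <- list()
  fail_rows <- list()
  for (spec in specs) {
    fl <- spec$landscape
    acc <- setdiff(accessible_genotypes(fl), 0L)
    land_rows[[length(land_rows) + 1]] <- data.frame(
      landscape = spec$id, family = spec$family,
      rse = rse_fraction(fl), n_accessible = length(acc),
      n_peaks = length(landscape_peaks(fl)))
    all_dags <- list(); all_groups <- character(0)
    for (scheme in config$schemes) {
      for (regime in config$regimes) {
        sp <- config$sim
        sp$mutation_scheme <- scheme
        sp$detection_regime <- regime
        big <- tryCatch(
          simulate_dataset(fl, sp, config$sims_per_condition),
          error = function(e) {
            fail_rows[[length(fail_rows) + 1]] <<- data.frame(
              landscape = spec$id, family = spec$family, scheme = scheme,
              regime = regime, error = conditionMessage(e))
            NULL
          })
        if (is.null(big)) next
        observable <- observable_accessible(fl, big, config$min_freq)
        split_id <- rep(seq_len(config$n_splits),
                        each = nrow(big) / config$n_splits)
        cond <- paste(scheme, regime, sep = "/")
        dags <- list()
        for (s in seq_len(config$n_splits)) {
          sub <- big[split_id == s, , drop = FALSE]
          dag <- tryCatch(learn_conjunctive_dag(sub, config$learner),
                          error = function(e) NULL)
          if (is.null(dag)) next
          dags[[length(dags) + 1]] <- dag
          metric_rows[[length(metric_rows) + 1]] <- data.frame(
            landscape = spec$id, family = spec$family, scheme = scheme,
            regime = regime, split = s,
            pfd = pfd(dag, fl),
            pnd = pnd(dag, fl,
                      observable = if (length(observable)) observable else NULL))
        }
        if (length(dags) >= 2) {
          var_rows[[length(var_rows) + 1]] <- data.frame(
            landscape = spec$id, family = spec$family, condition = cond,
            n = length(dags),
            mean_rel_distance = mean_pairwise_dag_distance(dags),
            gini_simpson = gini_simpson(dags))
        }
        all_dags <- c(all_dags, dags)
        all_groups <- c(all_groups, rep(cond, length(dags)))
      }
    }
    if (length(all_dags) >= 2 && length(unique(all_groups)) > 1) {
      var_rows[[length(var_rows) + 1]] <- data.frame(
        landscape = spec$id, family = spec$family, condition = "all",
        n = length(all_dags),
        mean_rel_distance = mean_pairwise_dag_distance(all_dags),
        gini_simpson = gini_simpson(all_dags))
    }
  }
  list(landscapes = do.call(rbind, land_rows),
       metrics = do.call(rbind, metric_rows),
       variability = do.call(rbind, var_rows),
       failures = if (length(fail_rows)) do.call(rbind, fail_rows) else NULL)
}

#' Run the cancer-cohort matching study
#'
#' The empirical-data workflow: find landscapes (plus simulation settings)
#' whose simulated genotype frequencies match the observed cohort
#' ([find_matched_landscapes()]); then, for each accepted landscape,
#' simulate replicate cohorts, learn a DAG from each, and summarize
#' within-landscape DAG variability, between-landscape DAG distances
#' (averaging over all cross pairs of replicate DAGs) and pairwise
#' accessible-set differences between the accepted landscapes.
#'
#' @param observed cohort matrix of mutated samples.
#' @param criteria a [match_criteria()].
#' @param n_target accepted landscapes to collect.
#' @param n_splits replicate cohorts (and learned DAGs) per landscape.
#' @param split_size samples per replicate cohort (defaults to
#'   `nrow(observed)`).
#' @param params a [gen_params()] for candidate generation.
#' @param sim_template a [sim_params()] template.
#' @param learner a [learner_config()].
#' @param max_candidates passed to [find_matched_landscapes()].
#' @param max_draws per-repetition simulation cap, see [evaluate_match()].
#' @return list: `accepted` (the matched candidates), `within`
#'   (per-landscape DAG variability), `between_landscapes` (data frame of
#'   pairwise accessible-set differences and mean cross-pair DAG
#'   distances).
#' @export
run_cancer_study <- function(observed, criteria = match_criteria(),
                             n_target = 3, n_splits = 4, split_size = NULL,
                             params = gen_params(),
                             sim_template = sim_params(),
                             learner = learner_config(),
                             max_candidates = 200,
                             max_draws = 50 * nrow(observed)) {
  observed <- as_cohort(observed)
  if (is.null(split_size)) split_size <- nrow(observed)
  accepted <- find_matched_landscapes(observed, criteria, n_target,
                                      params = params,
                                      sim_template = sim_template,
                                      max_candidates = max_candidates,
                                      max_draws = max_draws)
  dag_sets <- list(); within_rows <- list()
  for (i in seq_along(accepted)) {
    cand <- accepted[[i]]
    dags <- list()
    for (s in seq_len(n_splits)) {
      dag <- tryCatch(
        learn_conjunctive_dag(
          simulate_nonzero_cohort(cand$landscape, cand$sim_params,
                                  n_samples = split_size,
                                  max_draws = max_draws),
          learner),
        error = function(e) NULL)
      if (!is.null(dag)) dags[[length(dags) + 1]] <- dag
    }
    dag_sets[[i]] <- dags
    within_rows[[i]] <- data.frame(
      landscape = i, n = length(dags),
      mean_rel_distance = if (length(dags) >= 2)
        mean_pairwise_dag_distance(dags) else NA_real_,
      gini_simpson = if (length(dags) >= 2) gini_simpson(dags) else NA_real_)
  }
  between_rows <- list()
  if (length(accepted) >= 2) {
    for (a in 1:(length(accepted) - 1)) {
      for (b in (a + 1):length(accepted)) {
        asd <- accessible_set_difference(accepted[[a]]$landscape,
                                         accepted[[b]]$landscape)
        cross <- NA_real_
        if (length(dag_sets[[a]]) >= 1 && length(dag_sets[[b]]) >= 1) {
          dd <- outer(seq_along(dag_sets[[a]]), seq_along(dag_sets[[b]]),
                      Vectorize(function(x, y) {
                        dag_distance(dag_sets[[a]][[x]],
                                     dag_sets[[b]][[y]])[["relative"]]
                      }))
          cross <- mean(dd)
        }
        between_rows[[length(between_rows) + 1]] <- data.frame(
          landscape_a = a, landscape_b = b,
          accessible_diff_count = asd[["count"]],
          accessible_diff_relative = asd[["relative"]],
          mean_cross_dag_distance = cross)
      }
    }
  }
  list(accepted = accepted,
       within = do.call(rbind, within_rows),
       between_landscapes = if (length(between_rows))
         do.call(rbind, between_rows) else NULL)
}
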