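# Matching fitness landscapes to an observed cohort: the acceptance loop
# that retains candidate landscapes (plus mutation/detection settings)
# whose simulated genotype frequencies are statistically indistinguishable
# from the observed ones.

#' Matching acceptance criteria
#'
#' A candidate landscape is simulated `n_reps` times; each repetition
#' passes if both the asymptotic and the permutation p-value of the
#' genotype-frequency test exceed `p_threshold` and (optionally) every
#' gene is mutated in at least one simulated sample.  The candidate is
#' accepted if at least `min_pass` repetitions pass -- requiring several
#' passes guards against keeping a landscape that only occasionally
#' produces data resembling the observed cohort.
#'
#' @param n_reps repetitions per candidate (default 10).
#' @param min_pass minimum passing repetitions (default 3).
#' @param p_threshold minimum p-value, strict (default 0.6).
#' @param n_perm permutations for the permutation test (default 1000).
#' @param require_all_genes require every gene observed mutated in each
#'   passing repetition (default `TRUE`).
#' @return a list of class `match_criteria`.
#' @export
match_criteria <- function(n_reps = 10, min_pass = 3, p_threshold = 0.6,
                           n_perm = 1000, require_all_genes = TRUE) {
  stopifnot(min_pass >= 0, min_pass <= n_reps,
            p_threshold > 0, p_threshold < 1, n_perm >= 1)
  structure(list(n_reps = as.integer(n_reps), min_pass = as.integer(min_pass),
                 p_threshold = p_threshold, n_perm = as.integer(n_perm),
                 require_all_genes = isTRUE(require_all_genes)),
            class = "match_criteria")
}

chi2_stat <- function(tab) {
  # Pearson statistic of a 2 x k table, no continuity correction
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E, na.rm = TRUE)
}

#' Compare genotype distributions of two cohorts
#'
#' Builds a 2-by-k contingency table over the distinct genotypes present
#' in either cohort (no pooling of low-count cells) and computes the
#' Pearson chi-squared statistic.  The asymptotic p-value uses the
#' chi-squared reference distribution with k - 1 degrees of freedom; the
#' permutation p-value reshuffles the cohort labels over the pooled
#' samples (the stated remedy for low-count cells).
#'
#' @param observed,simulated cohort matrices over the same genes.
#' @param n_perm number of label permutations (default 1000).
#' @return named numeric vector `c(statistic, p_asymptotic,
#'   p_permutation)`.
#' @export
genotype_chi2_test <- function(observed, simulated, n_perm = 1000) {
  observed <- as_cohort(observed)
  simulated <- as_cohort(simulated)
  if (ncol(observed) != ncol(simulated))
    stop("cohorts must be over the same genes")
  if (nrow(observed) == 0 || nrow(simulated) == 0)
    stop("cohorts must be non-empty")
  g1 <- genotype_index(observed)
  g2 <- genotype_index(simulated)
  cats <- sort(unique(c(g1, g2)))
  if (length(cats) == 1) {
    return(c(statistic = 0, p_asymptotic = 1, p_permutation = 1))
  }
  pooled <- factor(c(g1, g2), levels = cats)
  grp <- rep(1:2, c(length(g1), length(g2)))
  tab <- table(grp, pooled)
  stat <- chi2_stat(tab)
  p_asym <- stats::pchisq(stat, df = length(cats) - 1, lower.tail = FALSE)
  perm <- vapply(seq_len(n_perm), function(i) {
    chi2_stat(table(sample(grp), pooled))
  }, numeric(1))
  p_perm <- (1 + sum(perm >= stat - 1e-12)) / (n_perm + 1)
  c(statistic = stat, p_asymptotic = p_asym, p_permutation = p_perm)
}

random_sim_params <- function(template = sim_params()) {
  sim_params(N0 = template$N0,
             mutation_scheme = sample(c("common_1e-5", "common_1e-6",
                                        "variable"), 1),
             detection_regime = sample(c("fast", "slow"), 1),
             sample_threshold = template$sample_threshold,
             max_attempts = template$max_attempts,
             backend = template$backend, tau = template$tau,
             detection_interval = template$detection_interval,
             max_time = template$max_time)
}

#' Evaluate one candidate landscape against the matching criteria
#'
#' Simulates `criteria$n_reps` cohorts of `nrow(observed)` mutated samples
#' under the candidate landscape and settings, tests each against the
#' observed genotype distribution, and applies the acceptance rule.  The
#' acceptance decision is a deterministic function of the returned log.
#'
#' @param landscape candidate [fitness_landscape()].
#' @param sim a [sim_params()].
#' @param observed cohort matrix of mutated samples.
#' @param criteria a [match_criteria()].
#' @param max_draws cap on tumors simulated per repetition while collecting
#'   the mutated samples (see [simulate_nonzero_cohort()]); a repetition
#'   that exhausts it is logged as failed.
#' @return list with `accept` (logical) and `log` (data frame of
#'   per-repetition `p_asymptotic`, `p_permutation`, `all_genes`, `pass`).
#' @export
evaluate_match <- function(landscape, sim, observed,
                           criteria = match_criteria(),
                           max_draws = 50 * nrow(observed)) {
  observed <- as_cohort(observed)
  n_obs <- nrow(observed)
  log <- data.frame(rep = seq_len(criteria$n_reps), p_asymptotic = NA_real_,
                    p_permutation = NA_real_, all_genes = NA, pass = NA)
  for (r in seq_len(criteria$n_reps)) {
    simc <- tryCatch(
      simulate_nonzero_cohort(landscape, sim, n_samples = n_obs,
                              max_draws = max_draws),
      error = function(e) NULL)
    if (is.null(simc)) {
      log[r, c("all_genes", "pass")] <- list(FALSE, FALSE)
      next
    }
    tst <- genotype_chi2_test(observed, simc, n_perm = criteria$n_perm)
    all_genes <- all(colSums(simc) > 0)
    pass <- tst[["p_asymptotic"]] > criteria$p_threshold &&
      tst[["p_permutation"]] > criteria$p_threshold &&
      (!criteria$require_all_genes || all_genes)
    log[r, 2:5] <- list(tst[["p_asymptotic"]], tst[["p_permutation"]],
                        all_genes, pass)
  }
  list(accept = sum(log$pass, na.rm = TRUE) >= criteria$min_pass, log = log)
}

#' Find fitness landscapes matching an observed cohort
#'
#' Repeatedly draws candidate landscapes from [matched_rmf_landscape()]
#' together with random simulation settings (mutation scheme and detection
#' regime drawn uniformly), simulates `criteria$n_reps` cohorts of the
#' same size as the observed one (mutated samples only), and retains
#' candidates meeting the [match_criteria()].  The per-repetition
#' p-values and gene-coverage flags are logged with every candidate, so
#' the acceptance decision is replayable from the log.
#'
#' @param observed cohort matrix of mutated samples.
#' @param criteria a [match_criteria()].
#' @param n_target number of accepted landscapes to collect.
#' @param params a [gen_params()] for the candidate generator.
#' @param sim_template a [sim_params()] supplying the non-randomized
#'   simulation settings (population size, backend, ...).
#' @param max_candidates abort (with diagnostics) after this many
#'   candidates if `n_target` has not been reached.
#' @param max_draws per-repetition simulation cap, see [evaluate_match()].
#' @return list of accepted candidates, each a list with `landscape`,
#'   `sim_params` and `log` (data frame of per-repetition `p_asymptotic`,
#'   `p_permutation`, `all_genes`, `pass`).
#' @export
find_matched_landscapes <- function(observed, criteria = match_criteria(),
                                    n_target = 5,
                                    params = gen_params(),
                                    sim_template = sim_params(),
                                    max_candidates = 200,
                                    max_draws = 50 * nrow(observed)) {
  observed <- as_cohort(observed)
  accepted <- list()
  tried <- 0
  while (length(accepted) < n_target) {
    if (tried >= max_candidates) {
      stop(sprintf(paste0("matching aborted: %d/%d landscapes accepted ",
                          "after %d candidates"),
                   length(accepted), n_target, tried))
    }
    tried <- tried + 1
    fl <- tryCatch(matched_rmf_landscape(observed, params),
                   error = function(e) NULL)
    if (is.null(fl)) next
    sp <- random_sim_params(sim_template)
    ev <- evaluate_match(fl, sp, observed, criteria, max_draws = max_draws)
    if (ev$accept) {
      accepted[[length(accepted) + 1]] <-
        list(landscape = fl, sim_params = sp, log = ev$log)
    }
  }
  attr(accepted, "n_candidates") <- tried
  accepted
}
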