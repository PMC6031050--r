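# Continuous-time clonal birth-death simulation on a fitness landscape.
#
# Per-cell birth rate = landscape fitness of the clone's genotype;
# per-cell death rate D(N) = log(1 + N/K), identical across clones and
# increasing in total population size N, with K = N0/(e - 1) so that
# D(N0) = 1: a wild-type population (birth rate 1) starts at equilibrium.
# At each division the daughter can gain a mutation in one of its
# unmutated genes (per-gene rates; no back mutation; simultaneous double
# mutations are neglected as their probability is O(u^2)).  Detection is
# checked on a fixed schedule with probability increasing in N, calibrated
# so that p(detect at a check | N = 2 N0) is 0.1 ("fast") or 0.01
# ("slow").

#' Simulation parameters
#'
#' @param N0 initial population size (wild-type cells; default 2000).
#' @param mutation_scheme `"common_1e-5"`, `"common_1e-6"` or `"variable"`
#'   (gene-specific rates, see [gene_mutation_rates()]).
#' @param detection_regime `"fast"` or `"slow"`: detection probability per
#'   check of 0.1 or 0.01 when the tumor is at twice the initial size.
#' @param sample_threshold cell fraction at or above which a mutation is
#'   called in a whole-tumor sample (default 0.5).
#' @param max_attempts restart budget when the population goes extinct
#'   before detection.
#' @param backend `"tau"` (tau-leaping, default) or `"gillespie"` (exact
#'   event-by-event simulation, practical for small populations).
#' @param tau leap length in time units for the tau backend (default 0.05;
#'   with per-capita rates of order 1 this keeps per-step event
#'   probabilities a few percent per cell).
#' @param detection_interval time between detection checks (default 20).
#' @param max_time give up (with an error) if detection has not occurred
#'   by this time.
#' @return a list of class `sim_params`.
#' @export
sim_params <- function(N0 = 2000,
                       mutation_scheme = c("common_1e-5", "common_1e-6",
                                           "variable"),
                       detection_regime = c("fast", "slow"),
                       sample_threshold = 0.5, max_attempts = 100,
                       backend = c("tau", "gillespie"), tau = 0.05,
                       detection_interval = 20, max_time = 10000) {
  mutation_scheme <- match.arg(mutation_scheme)
  detection_regime <- match.arg(detection_regime)
  backend <- match.arg(backend)
  stopifnot(N0 > 0, sample_threshold > 0, sample_threshold <= 1,
            max_attempts >= 1, tau > 0, detection_interval > 0,
            max_time > 0)
  structure(list(N0 = N0, mutation_scheme = mutation_scheme,
                 detection_regime = detection_regime,
                 sample_threshold = sample_threshold,
                 max_attempts = as.integer(max_attempts),
                 backend = backend, tau = tau,
                 detection_interval = detection_interval,
                 max_time = max_time),
            class = "sim_params")
}

#' Per-gene mutation rates
#'
#' The `"variable"` scheme returns `m` gene-specific rates geometrically
#' spaced between 2e-6 and 5e-5 inclusive (maximum spread between
#' successive values), whose geometric mean is exactly
#' `sqrt(2e-6 * 5e-5) = 1e-5`; the rates are assigned to genes in random
#' order.  The common schemes return constant vectors.
#'
#' @param m gene count.
#' @param scheme one of `"common_1e-5"`, `"common_1e-6"`, `"variable"`.
#' @return numeric vector of `m` per-gene rates.
#' @export
gene_mutation_rates <- function(m, scheme = c("common_1e-5", "common_1e-6",
                                              "variable")) {
  scheme <- match.arg(scheme)
  stopifnot(m >= 1)
  switch(scheme,
         "common_1e-5" = rep(1e-5, m),
         "common_1e-6" = rep(1e-6, m),
         "variable" = {
           if (m < 2) stop("variable scheme needs at least 2 genes")
           sample(exp(seq(log(2e-6), log(5e-5), length.out = m)))
         })
}

detection_k <- function(regime) {
  # p(N) = 1 - exp(-k * max(0, N/N0 - 1)); anchors p(2 N0) = 0.1 / 0.01
  switch(regime, fast = -log(0.9), slow = -log(0.99))
}

detection_prob <- function(N, N0, regime) {
  1 - exp(-detection_k(regime) * pmax(0, N / N0 - 1))
}

# Poisson / binomial draws that stay numerically safe for the very large
# event counts reached by fit clones between detection checks (normal
# approximation above 1e8 expected events, where rpois/rbinom overflow).
rpois_big <- function(n, lambda) {
  out <- numeric(n)
  big <- lambda > 1e8
  if (any(!big)) out[!big] <- stats::rpois(sum(!big), lambda[!big])
  if (any(big)) out[big] <- pmax(0, round(stats::rnorm(sum(big), lambda[big],
                                                       sqrt(lambda[big]))))
  out
}

rbinom_big <- function(n, size, prob) {
  out <- numeric(n)
  big <- size > 1e8
  if (any(!big)) out[!big] <- stats::rbinom(sum(!big), size[!big], prob[!big])
  if (any(big)) out[big] <- rpois_big(sum(big), size[big] * prob[big])
  pmin(out, size)
}

# Per-genotype total mutation rate and single-gain targets.
mutation_table <- function(m, rates) {
  idx <- 0:(2^m - 1)
  bits <- genotype_bits(idx, m)
  mu_tot <- as.numeric((1 - bits) %*% rates)
  targets <- lapply(idx, function(g) {
    free <- which(bitwAnd(bitwShiftR(g, 0:(m - 1)), 1L) == 0L)
    list(genes = free, rates = rates[free],
         to = bitwOr(g, bitwShiftL(1L, free - 1L)))
  })
  list(mu_tot = mu_tot, targets = targets)
}

new_tumor_population <- function(clones, t, attempts, detected) {
  structure(list(clones = clones, t = t, N = sum(clones),
                 attempts = attempts, detected = detected),
            class = "tumor_population")
}

#' @export
print.tumor_population <- function(x, ...) {
  cat(sprintf("Tumor population: N = %g cells in %d clones, t = %.2f%s\n",
              x$N, length(x$clones), x$t,
              if (isTRUE(x$detected)) " (detected)" else ""))
  invisible(x)
}

#' Simulate tumor growth until stochastic detection
#'
#' Runs the multitype birth-death process described above from `N0`
#' wild-type cells until a detection check fires, restarting (up to
#' `max_attempts` times) if the population goes extinct first.
#'
#' @param landscape a [fitness_landscape()] supplying birth rates.
#' @param params a [sim_params()].
#' @param rates optional per-gene mutation rates; defaults to
#'   [gene_mutation_rates()] under `params$mutation_scheme`.
#' @return a `tumor_population`: fields `clones` (named count vector, names
#'   are genotype indices), `t`, `N`, `attempts`, `detected`.
#' @export
simulate_to_detection <- function(landscape, params = sim_params(),
                                  rates = NULL) {
  stopifnot_landscape(landscape)
  m <- landscape$m
  if (is.null(rates)) rates <- gene_mutation_rates(m, params$mutation_scheme)
  stopifnot(length(rates) == m, all(rates >= 0))
  mt <- mutation_table(m, rates)
  for (attempt in seq_len(params$max_attempts)) {
    res <- if (params$backend == "tau") {
      .sim_once_tau(landscape, params, mt)
    } else {
      .sim_once_gillespie(landscape, params, mt)
    }
    if (res$status == "detected") {
      return(new_tumor_population(res$clones, res$t, attempt, TRUE))
    }
    if (res$status == "timeout") {
      stop("detection not reached by max_time = ", params$max_time)
    }
    # extinct: restart
  }
  stop("population went extinct in all ", params$max_attempts, " attempts")
}

.sim_once_tau <- function(landscape, params, mt, detect = TRUE) {
  f <- landscape$fitness
  N0 <- params$N0
  K <- N0 / (exp(1) - 1)
  counts <- stats::setNames(as.numeric(N0), "0")
  t <- 0
  repeat {
    next_check <- t + params$detection_interval
    while (t < next_check - 1e-12) {
      tau <- min(params$tau, next_check - t)
      N <- sum(counts)
      if (N == 0) return(list(status = "extinct"))
      gid <- as.integer(names(counts)) + 1L
      b <- f[gid]
      D <- log1p(N / K)
      births <- rpois_big(length(counts), counts * b * tau)
      deaths <- rpois_big(length(counts), counts * D * tau)
      n_mut <- rbinom_big(length(counts), births, pmin(1, mt$mu_tot[gid]))
      counts <- pmax(counts + births - deaths - n_mut, 0)
      for (i in which(n_mut > 0)) {
        tg <- mt$targets[[gid[i]]]
        alloc <- if (length(tg$genes) == 1) {
          n_mut[i]
        } else if (n_mut[i] < 1e8) {
          as.numeric(stats::rmultinom(1, n_mut[i], tg$rates))
        } else {
          round(n_mut[i] * tg$rates / sum(tg$rates))
        }
        keys <- as.character(tg$to)
        for (j in which(alloc > 0)) {
          key <- keys[j]
          counts[key] <- (if (key %in% names(counts)) counts[[key]] else 0) +
            alloc[j]
        }
      }
      t <- t + tau
    }
    counts <- counts[counts > 0]
    N <- sum(counts)
    if (N == 0) return(list(status = "extinct"))
    if (detect &&
        stats::runif(1) < detection_prob(N, N0, params$detection_regime)) {
      return(list(status = "detected", clones = counts, t = t))
    }
    if (t >= params$max_time) {
      return(if (detect) list(status = "timeout")
             else list(status = "stopped", clones = counts, t = t))
    }
  }
}

.sim_once_gillespie <- function(landscape, params, mt, detect = TRUE) {
  f <- landscape$fitness
  N0 <- params$N0
  K <- N0 / (exp(1) - 1)
  counts <- stats::setNames(as.numeric(N0), "0")
  t <- 0
  next_check <- params$detection_interval
  repeat {
    counts <- counts[counts > 0]
    N <- sum(counts)
    if (N == 0) return(list(status = "extinct"))
    gid <- as.integer(names(counts)) + 1L
    b <- f[gid]
    D <- log1p(N / K)
    brates <- counts * b
    drates <- counts * D
    R <- sum(brates) + sum(drates)
    dt <- stats::rexp(1, R)
    if (t + dt >= next_check) {
      t <- next_check
      next_check <- next_check + params$detection_interval
      if (detect &&
          stats::runif(1) < detection_prob(N, N0, params$detection_regime)) {
        return(list(status = "detected", clones = counts, t = t))
      }
      if (t >= params$max_time) {
        return(if (detect) list(status = "timeout")
               else list(status = "stopped", clones = counts, t = t))
      }
      next
    }
    t <- t + dt
    u <- stats::runif(1) * R
    cum <- cumsum(c(brates, drates))
    ev <- which(u <= cum)[1]
    L <- length(counts)
    if (ev <= L) {
      # birth on clone ev; daughter may mutate one unmutated gene
      if (stats::runif(1) < mt$mu_tot[gid[ev]]) {
        tg <- mt$targets[[gid[ev]]]
        k <- if (length(tg$genes) == 1) 1L else
          sample.int(length(tg$genes), 1, prob = tg$rates)
        key <- as.character(tg$to[k])
        counts[key] <- (if (key %in% names(counts)) counts[[key]] else 0) + 1
      } else {
        counts[ev] <- counts[ev] + 1
      }
    } else {
      counts[ev - L] <- counts[ev - L] - 1
    }
  }
}

#' Simulate for a fixed time horizon (no detection)
#'
#' Runs the same birth-death process as [simulate_to_detection()] but
#' simply returns the population state at `horizon`, with no detection
#' checks and no restart on extinction.  Used for calibration checks
#' (neutral equilibrium, backend agreement).
#'
#' @inheritParams simulate_to_detection
#' @param horizon stopping time.
#' @return a `tumor_population` (`detected = FALSE`; `N` may be 0).
#' @export
simulate_fixed_time <- function(landscape, params = sim_params(),
                                horizon = 10, rates = NULL) {
  stopifnot_landscape(landscape)
  m <- landscape$m
  if (is.null(rates)) rates <- gene_mutation_rates(m, params$mutation_scheme)
  mt <- mutation_table(m, rates)
  p2 <- params
  p2$detection_interval <- horizon
  p2$max_time <- horizon
  res <- if (params$backend == "tau") {
    .sim_once_tau(landscape, p2, mt, detect = FALSE)
  } else {
    .sim_once_gillespie(landscape, p2, mt, detect = FALSE)
  }
  clones <- if (res$status == "extinct") stats::setNames(numeric(0), character(0))
            else res$clones
  new_tumor_population(clones, horizon, 1, FALSE)
}

#' Whole-tumor sample of a population
#'
#' Calls gene `i` mutated iff the fraction of cells carrying a mutation in
#' `i` is at least `threshold`, collapsing the population to a single
#' genotype per tumor.
#'
#' @param pop a `tumor_population` (see [simulate_to_detection()]).
#' @param threshold calling threshold in `(0, 1]` (default 0.5).
#' @param m gene count (needed to decode clone genotypes).
#' @return integer 0/1 vector of length `m`.
#' @export
whole_tumor_sample <- function(pop, threshold = 0.5, m = NULL) {
  if (!inherits(pop, "tumor_population")) stop("expected a tumor_population")
  if (pop$N <= 0) stop("cannot sample an empty population")
  idx <- as.integer(names(pop$clones))
  if (is.null(m)) m <- max(1, ceiling(log2(max(idx) + 1)))
  bits <- genotype_bits(idx, m)
  frac <- as.numeric(crossprod(bits, pop$clones)) / pop$N
  as.integer(frac >= threshold)
}

#' Simulate a cross-sectional cohort
#'
#' Draws `n_samples` independent tumors ([simulate_to_detection()] followed
#' by [whole_tumor_sample()]) under one set of per-gene mutation rates
#' (drawn once per dataset for the `"variable"` scheme).
#'
#' @inheritParams simulate_to_detection
#' @param n_samples number of tumors.
#' @return a cohort matrix (`n_samples` rows, `m` 0/1 gene columns) with
#'   attributes `detection_N`, `detection_t`, `attempts` (per-sample) and
#'   `mutation_rates`.
#' @export
simulate_dataset <- function(landscape, params = sim_params(),
                             n_samples = 100, rates = NULL) {
  stopifnot(n_samples >= 1)
  m <- landscape$m
  if (is.null(rates)) rates <- gene_mutation_rates(m, params$mutation_scheme)
  out <- matrix(0L, n_samples, m, dimnames = list(NULL, landscape$genes))
  det_N <- det_t <- att <- numeric(n_samples)
  for (s in seq_len(n_samples)) {
    pop <- simulate_to_detection(landscape, params, rates = rates)
    out[s, ] <- whole_tumor_sample(pop, params$sample_threshold, m = m)
    det_N[s] <- pop$N
    det_t[s] <- pop$t
    att[s] <- pop$attempts
  }
  structure(out, detection_N = det_N, detection_t = det_t, attempts = att,
            mutation_rates = rates)
}

#' Simulate a cohort of mutated samples only
#'
#' Repeatedly simulates tumors, discarding wild-type (all-zero) samples,
#' until `n_samples` samples with at least one mutation are collected;
#' mirrors empirical cohorts restricted to patients with at least one
#' mutation.
#'
#' @inheritParams simulate_dataset
#' @param max_draws cap on total tumors simulated (default `50 *
#'   n_samples`).
#' @return a cohort matrix with no all-zero rows.
#' @export
simulate_nonzero_cohort <- function(landscape, params = sim_params(),
                                    n_samples = 100, rates = NULL,
                                    max_draws = 50 * n_samples) {
  m <- landscape$m
  if (is.null(rates)) rates <- gene_mutation_rates(m, params$mutation_scheme)
  rows <- matrix(0L, 0, m, dimnames = list(NULL, landscape$genes))
  drawn <- 0
  while (nrow(rows) < n_samples) {
    if (drawn >= max_draws)
      stop("exceeded max_draws = ", max_draws,
           " before collecting ", n_samples, " mutated samples")
    pop <- simulate_to_detection(landscape, params, rates = rates)
    g <- whole_tumor_sample(pop, params$sample_threshold, m = m)
    drawn <- drawn + 1
    if (sum(g) > 0) rows <- rbind(rows, g)
  }
  rownames(rows) <- NULL
  structure(rows, mutation_rates = rates, n_drawn = drawn)
}
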