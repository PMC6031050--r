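# Random generation of fitness landscapes: DAG-derived representable,
# DAG-derived non-representable (random synthetic-lethal knockouts), and
# Rough Mount Fuji (RMF), plus the matched-RMF family constrained to make
# the genotypes of an observed cohort accessible.

#' Generation parameters for random landscapes
#'
#' @param m gene count (default 7).
#' @param s_range support of the per-gene multiplicative fitness effects
#'   drawn for DAG-derived landscapes (uniform; default `c(0.1, 0.7)`).
#' @param lethal_fitness fitness assigned to non-viable genotypes
#'   (default `1e-9`).
#' @param edge_prob probability of including each forward edge when drawing
#'   a random DAG (default 0.28).
#' @param rmf_slope_range support of the per-landscape additive slope `c`
#'   of the RMF model (uniform draw; default `c(0, 1.15)`).
#' @param rmf_noise_sd standard deviation of the i.i.d. House-of-Cards
#'   noise of the RMF model (default 1).
#' @param rmf_sigma scale of the exponential map from raw RMF values to
#' birth rates (default 0.3, which keeps birth rates on the same order
#'   as the multiplicative DAG-derived family; the map is strictly
#'   monotone, so accessibility, peaks and epistasis-sign statistics do
#'   not depend on it).
#' @param max_tries retry budget for generators with validity constraints.
#' @return a list of class `gen_params`.
#' @export
gen_params <- function(m = 7, s_range = c(0.1, 0.7), lethal_fitness = 1e-9,
                       edge_prob = 0.28, rmf_slope_range = c(0, 1.15),
                       rmf_noise_sd = 1, rmf_sigma = 0.3, max_tries = 100) {
  stopifnot(m >= 2, length(s_range) == 2, all(s_range > 0),
            lethal_fitness < 1, edge_prob >= 0, edge_prob <= 1,
            rmf_noise_sd >= 0, max_tries >= 1)
  structure(list(m = as.integer(m), s_range = s_range,
                 lethal_fitness = lethal_fitness, edge_prob = edge_prob,
                 rmf_slope_range = rmf_slope_range,
                 rmf_noise_sd = rmf_noise_sd, rmf_sigma = rmf_sigma,
                 max_tries = as.integer(max_tries)),
            class = "gen_params")
}

#' Random transitively reduced DAG of restrictions
#'
#' Draws a uniform random topological order over the genes, includes each
#' forward edge independently with probability `edge_prob`, attaches every
#' parentless gene to Root, and transitively reduces.
#'
#' @param params a [gen_params()].
#' @param genes optional gene names (default `LETTERS[1:m]`).
#' @return a reduced [restriction_dag()] with every gene reachable from
#'   Root.
#' @export
random_restriction_dag <- function(params = gen_params(), genes = NULL) {
  m <- params$m
  if (is.null(genes)) genes <- make_gene_names(m)
  ord <- sample.int(m)
  adj <- matrix(FALSE, m, m, dimnames = list(genes, genes))
  for (a in 1:(m - 1)) {
    for (b in (a + 1):m) {
      if (stats::runif(1) < params$edge_prob) adj[ord[a], ord[b]] <- TRUE
    }
  }
  root <- colSums(adj) == 0
  dag <- structure(list(genes = genes, root = stats::setNames(root, genes),
                        adj = adj),
                   class = "restriction_dag")
  transitive_reduction(dag)
}

#' DAG-derived (representable) fitness landscape
#'
#' Multiplicative fitness for genotypes compatible with the DAG: each gene
#' `i` gets an effect `s_i ~ U(s_range)` and a compatible genotype's
#' fitness is the product of `1 + s_i` over its mutated genes.  Genotypes
#' incompatible with the DAG get `lethal_fitness`.  The resulting landscape
#' is representable by the generating DAG.
#'
#' @param dag a [restriction_dag()].
#' @param params a [gen_params()] (`s_range`, `lethal_fitness`).
#' @return a [fitness_landscape()] over `dag$genes`.
#' @export
dag_derived_landscape <- function(dag, params = gen_params()) {
  stopifnot_dag(dag)
  m <- length(dag$genes)
  s <- stats::runif(m, params$s_range[1], params$s_range[2])
  idx <- 0:(2^m - 1)
  bits <- genotype_bits(idx, m)
  fitness <- exp(as.numeric(bits %*% log1p(s)))
  comp <- compatible_genotypes(dag)
  fitness[setdiff(idx, comp) + 1L] <- params$lethal_fitness
  fitness_landscape(fitness, dag$genes,
                    lethal_threshold = params$lethal_fitness)
}

landscape_gene_coverage_ok <- function(landscape) {
  acc <- accessible_genotypes(landscape)
  all(colSums(genotype_bits(acc, landscape$m)) > 0)
}

#' Turn a representable landscape into a non-representable one
#'
#' A randomly chosen subset of genotypes with two or more mutations and
#' accessible under the landscape is made non-viable (fitness set to
#' `lethal_fitness`), creating synthetic lethals and hence reciprocal sign
#' epistasis.  The subset size is uniform between 1 and the number of
#' eligible genotypes.  The draw is retried until every gene remains
#' present in at least one accessible genotype.
#'
#' @param landscape a representable [fitness_landscape()].
#' @param params a [gen_params()].
#' @return a [fitness_landscape()]; fails with an error if no valid subset
#'   is found within `params$max_tries` draws.
#' @export
make_non_representable <- function(landscape, params = gen_params()) {
  stopifnot_landscape(landscape)
  m <- landscape$m
  acc <- accessible_genotypes(landscape)
  eligible <- acc[n_mutations(acc, m) >= 2]
  if (length(eligible) == 0)
    stop("no accessible genotypes with >= 2 mutations to knock out")
  kmax <- length(eligible)
  for (try in seq_len(params$max_tries)) {
    k <- sample.int(kmax, 1)
    drop <- eligible[sample.int(length(eligible), k)]
    out <- landscape
    out$fitness[drop + 1L] <- params$lethal_fitness
    if (landscape_gene_coverage_ok(out)) {
      return(out)
    }
  }
  stop("could not find a knockout subset keeping all genes accessible ",
       "within ", params$max_tries, " tries")
}

#' Draw a DAG-derived non-representable landscape
#'
#' Convenience generator for the non-representable family: draws a random
#' DAG, derives a representable landscape from it, and knocks out a random
#' accessible subset ([make_non_representable()]).  If the knockout step
#' cannot satisfy the gene-coverage check for a particular landscape, the
#' whole landscape is redrawn.
#'
#' @inheritParams random_restriction_dag
#' @return list with `landscape` (a [fitness_landscape()]) and `dag` (the
#'   generating [restriction_dag()]).
#' @export
random_nonrepresentable_landscape <- function(params = gen_params(),
                                              genes = NULL) {
  for (try in seq_len(params$max_tries)) {
    dag <- random_restriction_dag(params, genes = genes)
    fl <- tryCatch(
      make_non_representable(dag_derived_landscape(dag, params), params),
      error = function(e) NULL)
    if (!is.null(fl)) return(list(landscape = fl, dag = dag))
  }
  stop("could not draw a non-representable landscape within ",
       params$max_tries, " redraws")
}

#' Rough Mount Fuji (RMF) fitness landscape
#'
#' Raw value `F(g) = -c * d(g, reference) + eps_g` with the reference
#' genotype uniform over all genotypes, slope `c ~ U(rmf_slope_range)` and
#' noise `eps_g ~ N(0, rmf_noise_sd)` i.i.d. per genotype.  Raw values are
#' mapped to positive birth rates `exp(rmf_sigma * F)` and normalized so
#' the wild type has fitness 1; the map is strictly monotone, so
#' accessibility and the sign pattern of every epistasis square depend only
#' on the raw values.  Draws are retried until every gene is present in at
#' least one accessible genotype.  Depending on the slope/noise ratio the
#' family spans close-to-additive to House-of-Cards landscapes.
#'
#' @param params a [gen_params()].
#' @param genes optional gene names.
#' @return a [fitness_landscape()].
#' @export
rmf_landscape <- function(params = gen_params(), genes = NULL) {
  m <- params$m
  if (is.null(genes)) genes <- make_gene_names(m)
  idx <- 0:(2^m - 1)
  for (try in seq_len(params$max_tries)) {
    ref <- sample(idx, 1)
    cc <- stats::runif(1, params$rmf_slope_range[1], params$rmf_slope_range[2])
    eps <- stats::rnorm(2^m, 0, params$rmf_noise_sd)
    d <- n_mutations(bitwXor(idx, ref), m)
    raw <- -cc * d + eps
    fitness <- exp(params$rmf_sigma * (raw - raw[1]))
    fl <- fitness_landscape(fitness, genes,
                            lethal_threshold = params$lethal_fitness)
    if (landscape_gene_coverage_ok(fl)) return(fl)
  }
  stop("could not draw an RMF landscape with all genes accessible within ",
       params$max_tries, " tries")
}

#' RMF landscape matched to an observed cohort
#'
#' Draws an RMF landscape and then applies minimal monotone fitness bumps
#' so that every distinct mutated genotype present in the observed cohort
#' is accessible: for each observed genotype a uniformly random maximal
#' mutation-gain chain from the wild type is chosen and any non-increasing
#' step along it is raised to the previous fitness times `1 + delta`,
#' `delta ~ U(0.01, 0.1)`.  Because a bump can disturb a previously fixed
#' chain, accessibility of all observed genotypes is re-verified and the
#' whole construction retried if needed.
#'
#' @param observed binary patients-by-genes cohort matrix (see
#'   [read_cohort()]); its column count fixes `m`.
#' @param params a [gen_params()] (its `m` is overridden by the cohort).
#' @return a [fitness_landscape()] in which every observed mutated genotype
#'   is accessible.
#' @export
matched_rmf_landscape <- function(observed, params = gen_params()) {
  observed <- as_cohort(observed)
  m <- ncol(observed)
  genes <- colnames(observed)
  params$m <- as.integer(m)
  targets <- setdiff(unique(genotype_index(observed)), 0L)
  for (try in seq_len(params$max_tries)) {
    fl <- tryCatch(rmf_landscape(params, genes = genes),
                   error = function(e) NULL)
    if (is.null(fl)) next
    f <- fl$fitness
    for (g in targets) {
      loci <- which(genotype_bits(g, m)[1, ] == 1)
      chain <- if (length(loci) == 1) loci else sample(loci)
      cur <- 0L
      prev <- f[1L]
      for (k in chain) {
        cur <- bitwOr(cur, bitwShiftL(1L, k - 1L))
        if (f[cur + 1L] <= prev)
          f[cur + 1L] <- prev * (1 + stats::runif(1, 0.01, 0.1))
        prev <- f[cur + 1L]
      }
    }
    fl$fitness <- f
    acc <- accessible_genotypes(fl)
    if (all(targets %in% acc) && landscape_gene_coverage_ok(fl)) return(fl)
  }
  stop("could not construct a matched RMF landscape within ",
       params$max_tries, " tries")
}
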