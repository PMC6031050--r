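test_that("PFD and PND vanish for the generating DAG of a representable landscape", {
  set.seed(401)
  gp <- gen_params(m = 5)
  dag <- random_restriction_dag(gp)
  fl <- dag_derived_landscape(dag, gp)
  expect_equal(pfd(dag, fl), 0)
  expect_equal(pnd(dag, fl), 0)
})

test_that("the empty-restrictions DAG has the forced PFD", {
  set.seed(402)
  m <- 4
  fl <- random_small_landscape(m)
  free <- restriction_dag(cbind("Root", LETTERS[1:m]))
  a <- length(setdiff(accessible_genotypes(fl), 0L))
  expect_equal(pfd(free, fl), (2^m - 1 - a) / (2^m - 1))
})

test_that("a chain DAG fails to predict observable off-chain single mutants", {
  # chain A->B->C->D on a landscape where all single mutants are accessible
  fl <- make_additive_landscape(c(0.2, 0.3, 0.4, 0.5))
  chain <- restriction_dag(rbind(c("Root", "A"), c("A", "B"), c("B", "C"),
                                 c("C", "D")))
  singles <- c(1L, 2L, 4L, 8L)
  got <- pnd(chain, fl, observable = singles)
  expect_equal(got, 3 / 4)  # all single mutants but A are mispredicted
})

test_that("PFD/PND match brute-force set arithmetic on random cases", {
  set.seed(403)
  for (rep in 1:25) {
    m <- sample(3:5, 1)
    fl <- random_small_landscape(m)
    dag <- random_small_dag(m)
    comp <- setdiff(compatible_genotypes(dag), 0L)
    acc <- setdiff(oracle_accessible(fl), 0L)
    if (length(comp) > 0) {
      expect_equal(pfd(dag, fl), length(setdiff(comp, acc)) / length(comp))
    }
    if (length(acc) > 0) {
      expect_equal(pnd(dag, fl), length(setdiff(acc, comp)) / length(acc))
      obs <- sort(acc[sample.int(length(acc), max(1, length(acc) %/% 2))])
      expect_equal(pnd(dag, fl, observable = obs),
                   length(setdiff(obs, comp)) / length(obs))
    }
  }
})

test_that("undefined ratios are flagged as NA and bad references rejected", {
  fl <- fitness_landscape(c(1, 0.5, 0.4, 0.3), genes = c("A", "B"))
  dag <- restriction_dag(rbind(c("Root", "A"), c("A", "B")))
  expect_true(is.na(pnd(dag, fl)))  # nothing accessible beyond WT
  expect_error(pnd(dag, fl, observable = 3L), "subset")
})

test_that("observability filtering keeps frequent accessible genotypes only", {
  fl <- make_additive_landscape(c(0.2, 0.3))
  co <- as_cohort(rbind(matrix(rep(c(1L, 0L), 60), ncol = 2, byrow = TRUE),
                        matrix(rep(c(1L, 1L), 39), ncol = 2, byrow = TRUE),
                        c(0L, 1L)))
  obs <- observable_accessible(fl, co, min_freq = 0.005)
  expect_setequal(obs, c(1L, 2L, 3L))  # {B} at 1/100 clears the 5-in-1000 bar
  obs2 <- observable_accessible(fl, co, min_freq = 0.05)
  expect_setequal(obs2, c(1L, 3L))     # ...but not a 5% bar
  # wild-type-only cohorts observe nothing
  expect_identical(observable_accessible(fl, as_cohort(matrix(0L, 5, 2))),
                   integer(0))
})

test_that("the 5-in-1000 cut-off bounds the miss probability by 1%", {
  p_miss <- (1 - 0.005)^1000
  expect_lt(p_miss, 0.01)
  expect_equal(p_miss, 0.0067, tolerance = 0.01)
})

test_that("Gini-Simpson diversity follows the plug-in formula", {
  d1 <- restriction_dag(rbind(c("Root", "A"), c("A", "B")))
  d2 <- restriction_dag(rbind(c("Root", "A"), c("Root", "B")))
  expect_equal(gini_simpson(rep(list(d1), 20)), 0)
  dags <- c(rep(list(d1), 10), rep(list(d2), 10))
  expect_equal(gini_simpson(dags), 0.5)
  expect_equal(gini_simpson(dags, corrected = TRUE), 0.5 * 20 / 19)
  expect_error(gini_simpson(list(d1)), "at least 2")
  # all distinct: 1 - 1/n, and permutation invariant
  set.seed(404)
  distinct <- list()
  while (length(distinct) < 6) {
    cand <- random_small_dag(4)
    keys <- vapply(distinct, cpmland:::canonical_dag_key, character(1))
    if (!cpmland:::canonical_dag_key(cand) %in% keys)
      distinct[[length(distinct) + 1]] <- cand
  }
  expect_equal(gini_simpson(distinct), 1 - 1 / 6)
  expect_equal(gini_simpson(distinct[sample(6)]), 1 - 1 / 6)
})

test_that("variability summaries separate within from across conditions", {
  d1 <- restriction_dag(rbind(c("Root", "A"), c("A", "B")))
  d2 <- restriction_dag(rbind(c("Root", "A"), c("Root", "B")))
  v <- dag_variability(c(rep(list(d1), 3), rep(list(d2), 3)),
                       groups = rep(c("c1", "c2"), each = 3))
  expect_equal(v$within$mean_rel_distance, c(0, 0))
  expect_equal(v$within$gini_simpson, c(0, 0))
  expect_gt(v$across[["mean_rel_distance"]], 0)
  expect_gt(v$across[["gini_simpson"]], 0)
  # identical everywhere: all zeros
  v0 <- dag_variability(rep(list(d1), 4), groups = rep(c("c1", "c2"), 2))
  expect_equal(v0$across[["mean_rel_distance"]], 0)
})

test_that("mean pairwise distance agrees with direct enumeration", {
  set.seed(405)
  dags <- replicate(5, random_small_dag(4), simplify = FALSE)
  direct <- mean(apply(utils::combn(5, 2), 2, function(p) {
    dag_distance(dags[[p[1]]], dags[[p[2]]])[["relative"]]
  }))
  expect_equal(mean_pairwise_dag_distance(dags), direct)
})

test_that("accessible-set differences are symmetric and normalized", {
  set.seed(406)
  l1 <- random_small_landscape(4)
  l2 <- random_small_landscape(4)
  d12 <- accessible_set_difference(l1, l2)
  d21 <- accessible_set_difference(l2, l1)
  expect_equal(d12, d21)
  expect_equal(accessible_set_difference(l1, l1), c(count = 0, relative = 0))
  a1 <- setdiff(oracle_accessible(l1), 0L)
  a2 <- setdiff(oracle_accessible(l2), 0L)
  expect_equal(d12[["count"]],
               length(setdiff(a1, a2)) + length(setdiff(a2, a1)))
  # disjoint accessible sets: relative difference 1
  la <- fitness_landscape(c(1, 1.5, 0.8, 0.7), genes = c("A", "B"))
  lb <- fitness_landscape(c(1, 0.8, 1.5, 0.7), genes = c("A", "B"))
  expect_equal(accessible_set_difference(la, lb)[["relative"]], 1)
})
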