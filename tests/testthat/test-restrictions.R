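chain_edges <- rbind(c("Root", "A"), c("A", "B"))

test_that("constructor validates DAG structure", {
  expect_error(restriction_dag(rbind(c("A", "A"), c("Root", "A"))), "self")
  expect_error(restriction_dag(rbind(c("A", "Root"))), "into Root")
  expect_error(restriction_dag(rbind(c("Root", "A"), c("A", "B"), c("B", "A"))),
               "cycle")
  expect_error(restriction_dag(rbind(c("A", "B")),
                               genes = c("A", "B")), "unreachable")
  expect_error(restriction_dag(chain_edges, genes = c("A")), "unknown gene")
})

test_that("compatibility implements conjunctive (AND) semantics", {
  d <- restriction_dag(chain_edges)
  expect_setequal(genotype_label(compatible_genotypes(d), d$genes),
                  c("WT", "A", "AB"))
  conj <- restriction_dag(rbind(c("Root", "A"), c("Root", "B"),
                                c("Root", "C"), c("A", "D"), c("B", "D")),
                          genes = c("A", "B", "C", "D"))
  lab <- genotype_label(compatible_genotypes(conj), conj$genes)
  expect_true(all(c("ABD", "ABCD") %in% lab))
  expect_false(any(c("AD", "BD", "CD", "D") %in% lab))
  # all genes off Root: no restrictions at all
  free <- restriction_dag(cbind("Root", LETTERS[1:3]))
  expect_identical(compatible_genotypes(free), 0:7)
})

test_that("compatible sets are closed under removing childless mutations", {
  set.seed(13)
  for (rep in 1:10) {
    d <- random_small_dag(4)
    comp <- compatible_genotypes(d)
    for (g in setdiff(comp, 0L)) {
      loci <- which(genotype_bits(g, 4)[1, ] == 1)
      # a mutated gene none of whose children are mutated can be dropped
      droppable <- loci[vapply(loci, function(k) {
        kids <- which(d$adj[k, ])
        !any(genotype_bits(g, 4)[1, kids] == 1)
      }, logical(1))]
      expect_true(all((g - 2^(droppable - 1)) %in% comp))
    }
  }
})

test_that("transitive reduction removes shortcuts and is idempotent", {
  d <- restriction_dag(rbind(c("Root", "F"), c("F", "G"), c("G", "H"),
                             c("F", "H")), genes = c("F", "G", "H"))
  r <- transitive_reduction(d)
  expect_identical(dag_edges(r),
                   expected_edges(c("F", "G"), c("G", "H"), c("Root", "F")))
  expect_identical(dag_edges(transitive_reduction(r)), dag_edges(r))
  # Root edge to a gene that also has a gene parent disappears on reduction
  d2 <- restriction_dag(rbind(c("Root", "A"), c("Root", "B"), c("A", "B")))
  expect_identical(dag_edges(transitive_reduction(d2)),
                   expected_edges(c("A", "B"), c("Root", "A")))
})

test_that("transitive reduction preserves reachability and is minimal", {
  set.seed(14)
  for (rep in 1:20) {
    m <- sample(3:6, 1)
    d <- random_small_dag(m)
    r <- transitive_reduction(d)
    expect_identical(oracle_reach(r$adj), oracle_reach(d$adj))
    # minimality: removing any kept edge changes reachability
    kept <- which(r$adj, arr.ind = TRUE)
    for (e in seq_len(nrow(kept))) {
      adj2 <- r$adj
      adj2[kept[e, 1], kept[e, 2]] <- FALSE
      expect_false(identical(oracle_reach(adj2), oracle_reach(d$adj)))
    }
  }
})

test_that("dag_distance matches the symmetric-difference definition", {
  d1 <- restriction_dag(chain_edges)
  expect_equal(dag_distance(d1, d1), c(count = 0, relative = 0))
  d2 <- restriction_dag(rbind(c("Root", "A"), c("Root", "B")))
  # reduced sets {Root->A, A->B} vs {Root->A, Root->B}
  expect_equal(dag_distance(d1, d2), c(count = 2, relative = 2 / 3))
  d3 <- restriction_dag(rbind(chain_edges, c("Root", "C")))
  expect_error(dag_distance(d1, restriction_dag(cbind("Root", c("X", "Y")))),
               "same gene set")
  expect_error(dag_distance(d1, d3), "same gene set")
})

test_that("dag_distance is a metric on reduced DAGs", {
  set.seed(15)
  dags <- replicate(6, random_small_dag(4), simplify = FALSE)
  d <- function(a, b) dag_distance(a, b)[["count"]]
  for (i in 1:6) for (j in 1:6) {
    expect_equal(d(dags[[i]], dags[[j]]), d(dags[[j]], dags[[i]]))
    if (i != j) {
      reduced_equal <- identical(dag_edges(transitive_reduction(dags[[i]])),
                                 dag_edges(transitive_reduction(dags[[j]])))
      expect_equal(d(dags[[i]], dags[[j]]) == 0, reduced_equal)
    }
    for (k in 1:6) {
      expect_lte(d(dags[[i]], dags[[j]]),
                 d(dags[[i]], dags[[k]]) + d(dags[[k]], dags[[j]]))
    }
  }
})

test_that("root edges can be excluded from distances", {
  d1 <- restriction_dag(chain_edges)
  d2 <- restriction_dag(rbind(c("Root", "A"), c("Root", "B")))
  expect_equal(dag_distance(d1, d2, include_root = FALSE)[["count"]], 1)
})

test_that("representability is exact equality of accessible and compatible sets", {
  set.seed(16)
  gp <- gen_params(m = 4)
  d <- random_restriction_dag(gp)
  fl <- dag_derived_landscape(d, gp)
  expect_true(is_representable(fl, d))
  # knocking out one accessible multi-mutant breaks representability
  acc <- accessible_genotypes(fl)
  multi <- acc[n_mutations(acc, 4) >= 2]
  fl2 <- fl
  fl2$fitness[multi[1] + 1] <- 1e-9
  expect_false(is_representable(fl2, d))
  expect_error(is_representable(fl, restriction_dag(cbind("Root", LETTERS[1:3]))),
               "same genes")
})

test_that("DAG files round-trip and malformed input is diagnosed", {
  d <- restriction_dag(rbind(c("Root", "A"), c("A", "B"), c("Root", "C")))
  path <- withr::local_tempfile(fileext = ".txt")
  write_dag(d, path)
  d2 <- read_dag(path)
  expect_identical(dag_edges(d2), dag_edges(d))
  writeLines(c("Root A", "A B extra"), path)
  expect_error(read_dag(path), "line 2")
  writeLines(c("Root A", "A B", "B A"), path)
  expect_error(read_dag(path), "cycle")
  writeLines(c("Root A", "A D"), path)
  expect_error(read_dag(path, genes = c("A", "B")), "unknown")
})
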