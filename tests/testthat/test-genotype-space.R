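test_that("genotype encoding round-trips and labels genotypes", {
  m <- 4
  idx <- 0:(2^m - 1)
  bits <- genotype_bits(idx, m)
  expect_identical(genotype_index(bits), idx)
  expect_identical(genotype_label(c(0L, 1L, 6L), LETTERS[1:4]),
                   c("WT", "A", "BC"))
  expect_identical(n_mutations(c(0L, 7L, 8L), 4), c(0L, 3L, 1L))
})

test_that("landscape constructor validates and normalizes", {
  expect_error(fitness_landscape(c(1, 2, 3)), "power of 2")
  expect_error(fitness_landscape(c(1, -1, 2, 3)), "positive")
  fl <- fitness_landscape(c(2, 4, 2, 6), normalize = TRUE)
  expect_equal(fl$fitness[1], 1)
  expect_equal(fl$m, 2L)
})

test_that("a dependency landscape makes the dependent single mutant inaccessible", {
  # A freely mutable, B beneficial only on an A background
  fl <- fitness_landscape(c(1, 1.3, 0.7, 1.8), genes = c("A", "B"))
  acc <- accessible_genotypes(fl)
  expect_setequal(acc, c(0L, 1L, 3L))        # WT, {A}, {A,B}; not {B}
  expect_false(2L %in% acc)
})

test_that("strictly additive landscapes are fully accessible with one endpoint", {
  fl <- make_additive_landscape(c(0.2, 0.35, 0.5))
  expect_setequal(accessible_genotypes(fl), 0:7)
  expect_identical(landscape_peaks(fl), 7L)
  expect_identical(landscape_peaks(fl, neighbors = "all"), 7L)
})

test_that("constant landscapes have no strict peaks and nothing accessible", {
  fl <- fitness_landscape(rep(1, 8))
  expect_identical(landscape_peaks(fl, accessible_only = FALSE,
                                   neighbors = "all"), integer(0))
  expect_identical(accessible_genotypes(fl), 0L)
})

test_that("square classification covers the four epistasis classes", {
  # individually beneficial, jointly deleterious: reciprocal sign
  fl <- fitness_landscape(c(1, 1.3, 1.3, 0.5), genes = c("A", "B"))
  expect_identical(classify_square(fl, "A", "B"), "reciprocal_sign")
  expect_identical(rse_fraction(fl), 1)
  # additive: no epistasis anywhere
  add <- make_additive_landscape(c(0.2, 0.4, 0.3))
  for (bg in c(0L, 4L)) {
    expect_identical(classify_square(add, 1, 2, background = bg),
                     "no_epistasis")
  }
  expect_identical(rse_fraction(add), 0)
  # one-sided reversal: sign epistasis
  fl2 <- fitness_landscape(c(1, 1.3, 0.8, 1.6), genes = c("A", "B"))
  expect_identical(classify_square(fl2, "B", "A"), "sign")
  # multiplicative effects: magnitude epistasis, no reversal
  fl3 <- fitness_landscape(c(1, 1.2, 1.5, 1.8), genes = c("A", "B"))
  expect_identical(classify_square(fl3, "A", "B"), "magnitude")
})

test_that("square classification rejects invalid loci and backgrounds", {
  fl <- random_small_landscape(3)
  expect_error(classify_square(fl, 1, 1), "differ")
  expect_error(classify_square(fl, 1, 2, background = 1L), "unmutated")
  expect_error(classify_square(fl, "A", "Z"), "unknown gene")
})

test_that("accessibility, peaks, squares and rse agree with brute force", {
  set.seed(42)
  for (rep in 1:25) {
    m <- sample(2:5, 1)
    fl <- random_small_landscape(m)
    expect_identical(accessible_genotypes(fl), oracle_accessible(fl))
    expect_identical(landscape_peaks(fl), oracle_peaks(fl))
    expect_identical(landscape_peaks(fl, neighbors = "all"),
                     oracle_peaks(fl, neighbors = "all"))
    expect_equal(rse_fraction(fl), oracle_rse_fraction(fl))
    for (k in 1:4) {
      ij <- sample(m, 2)
      free <- (0:(2^m - 1))[
        genotype_bits(0:(2^m - 1), m)[, ij[1]] == 0 &
          genotype_bits(0:(2^m - 1), m)[, ij[2]] == 0]
      bg <- sample(free, 1)
      f <- fl$fitness
      bi <- 2^(ij[1] - 1); bj <- 2^(ij[2] - 1)
      expect_identical(
        classify_square(fl, ij[1], ij[2], background = bg),
        oracle_square(f[bg + 1], f[bg + bi + 1], f[bg + bj + 1],
                      f[bg + bi + bj + 1]))
    }
  }
})

test_that("every accessible genotype has an accessible lower-fitness predecessor", {
  set.seed(7)
  for (rep in 1:10) {
    fl <- random_small_landscape(4)
    acc <- accessible_genotypes(fl)
    for (g in setdiff(acc, 0L)) {
      loci <- which(genotype_bits(g, 4)[1, ] == 1)
      preds <- g - 2^(loci - 1)
      ok <- any(preds %in% acc & fl$fitness[preds + 1] < fl$fitness[g + 1])
      expect_true(ok)
    }
  }
})

test_that("rse_fraction is invariant to gene relabeling and monotone maps", {
  set.seed(8)
  for (rep in 1:10) {
    m <- 4
    fl <- random_small_landscape(m)
    base <- rse_fraction(fl)
    # monotone transform of fitness
    fl2 <- fl
    fl2$fitness <- fl$fitness^1.7 + 0.5
    expect_equal(rse_fraction(fl2), base)
    # relabeling = permuting loci consistently
    perm <- sample(m)
    idx <- 0:(2^m - 1)
    bits <- genotype_bits(idx, m)
    new_idx <- genotype_index(bits[, perm])
    f3 <- numeric(2^m)
    f3[new_idx + 1] <- fl$fitness
    fl3 <- fitness_landscape(f3, LETTERS[1:m])
    expect_equal(rse_fraction(fl3), base)
  }
})

test_that("per-pair aggregation bounds the per-square fraction", {
  set.seed(9)
  for (rep in 1:10) {
    fl <- random_small_landscape(4)
    expect_gte(rse_fraction(fl, per = "pair"), rse_fraction(fl, per = "square"))
  }
})

test_that("non-viable genotypes are never accessible", {
  set.seed(10)
  fl <- random_small_landscape(4)
  fl$fitness[c(4, 9, 14)] <- 1e-9
  expect_false(any(c(3L, 8L, 13L) %in% accessible_genotypes(fl)))
})

test_that("landscape CSV round-trips", {
  set.seed(11)
  fl <- random_small_landscape(3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_landscape(fl, path)
  fl2 <- read_landscape(path)
  expect_identical(fl2$genes, fl$genes)
  expect_equal(fl2$fitness, fl$fitness)
  expect_error(suppressWarnings(
    read_landscape(file.path(tempdir(), "does-not-exist.csv"))))
})
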