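# Genotype space over m biallelic loci.
#
# A genotype is encoded as an integer in 0:(2^m - 1): bit k (0-based) is the
# state of gene k, with gene order fixed by the landscape's `genes` vector.
# The wild type (WT) is 0.  All genotype sets returned by this package are
# integer vectors of such indices.

#' Bit matrix of genotype indices
#'
#' Expand integer-encoded genotypes into a 0/1 matrix with one column per
#' gene (column k corresponds to bit k - 1).
#'
#' @param idx integer vector of genotype indices in `0:(2^m - 1)`.
#' @param m number of loci.
#' @return integer matrix with `length(idx)` rows and `m` columns.
#' @export
genotype_bits <- function(idx, m) {
  stopifnot(m >= 1, all(idx >= 0), all(idx < 2^m))
  bits <- outer(as.integer(idx), 0:(m - 1),
                function(g, k) bitwAnd(bitwShiftR(g, k), 1L))
  storage.mode(bits) <- "integer"
  bits
}

#' Genotype indices from a 0/1 matrix or vector
#'
#' @param bits 0/1 matrix (rows = genotypes) or a single 0/1 vector.
#' @return integer vector of genotype indices.
#' @export
genotype_index <- function(bits) {
  if (is.null(dim(bits))) bits <- matrix(bits, nrow = 1)
  m <- ncol(bits)
  as.integer(bits %*% 2^(0:(m - 1)))
}

#' Number of mutations of each genotype
#' @inheritParams genotype_bits
#' @return integer vector of mutation counts.
#' @export
n_mutations <- function(idx, m) {
  as.integer(rowSums(genotype_bits(idx, m)))
}

#' Human-readable genotype labels
#'
#' Mutated gene names pasted together ("AB" style); the wild type is "WT".
#'
#' @inheritParams genotype_bits
#' @param genes character vector of gene names, one per locus.
#' @export
genotype_label <- function(idx, genes) {
  m <- length(genes)
  bits <- genotype_bits(idx, m)
  vapply(seq_along(idx), function(r) {
    mut <- genes[bits[r, ] == 1]
    if (length(mut) == 0) "WT" else paste(mut, collapse = "")
  }, character(1))
}

#' Construct a fitness landscape
#'
#' A complete genotype-fitness map over `2^m` biallelic genotypes.  Fitness
#' values are birth rates: positive, with the wild type at 1.  Genotypes at
#' or below `lethal_threshold` are treated as effectively non-viable.
#'
#' @param fitness numeric vector of length `2^m`, element `g + 1` being the
#'   fitness of genotype `g` (integer encoding, see [genotype_bits()]).
#' @param genes gene names; defaults to `LETTERS[1:m]`.
#' @param lethal_threshold fitness at or below which a genotype is treated
#'   as non-viable (default `1e-9`).
#' @param normalize divide all fitness values by the WT fitness so that
#'   `fitness[WT] == 1`.
#' @return an object of class `fitness_landscape` with fields `m`, `genes`,
#'   `fitness`, `lethal_threshold`.
#' @export
fitness_landscape <- function(fitness, genes = NULL, lethal_threshold = 1e-9,
                              normalize = FALSE) {
  n <- length(fitness)
  m <- as.integer(round(log2(n)))
  if (2^m != n) stop("length(fitness) must be a power of 2")
  if (any(!is.finite(fitness)) || any(fitness <= 0))
    stop("all fitness values must be positive and finite")
  if (normalize) fitness <- fitness / fitness[1]
  if (is.null(genes)) genes <- make_gene_names(m)
  if (length(genes) != m) stop("length(genes) must equal log2(length(fitness))")
  structure(list(m = m, genes = as.character(genes),
                 fitness = as.numeric(fitness),
                 lethal_threshold = lethal_threshold),
            class = "fitness_landscape")
}

make_gene_names <- function(m) {
  if (m <= 26) LETTERS[seq_len(m)] else paste0("G", seq_len(m))
}

#' @export
print.fitness_landscape <- function(x, ...) {
  acc <- accessible_genotypes(x)
  cat(sprintf("Fitness landscape: %d genes (%s), %d genotypes\n",
              x$m, paste(x$genes, collapse = ","), 2^x$m))
  cat(sprintf("  accessible genotypes (incl. WT): %d; peaks: %d\n",
              length(acc), length(landscape_peaks(x))))
  invisible(x)
}

stopifnot_landscape <- function(landscape) {
  if (!inherits(landscape, "fitness_landscape"))
    stop("expected a 'fitness_landscape' object")
}

#' Accessible genotypes of a fitness landscape
#'
#' A genotype is accessible if it can be reached from the wild type through
#' single-mutation-gain steps along which fitness strictly increases (no
#' back mutation).  The wild type is always part of the returned set.
#'
#' @param landscape a [fitness_landscape()].
#' @return sorted integer vector of accessible genotype indices (WT = 0
#'   included).
#' @export
accessible_genotypes <- function(landscape) {
  stopifnot_landscape(landscape)
  m <- landscape$m
  f <- landscape$fitness
  n <- 2^m
  idx <- 0:(n - 1)
  k <- n_mutations(idx, m)
  acc <- logical(n)
  acc[1] <- TRUE
  for (g in idx[order(k)][-1]) {
    bits <- which(bitwAnd(bitwShiftR(g, 0:(m - 1)), 1L) == 1L) - 1L
    preds <- bitwXor(g, bitwShiftL(1L, bits))
    if (any(acc[preds + 1L] & f[g + 1L] > f[preds + 1L])) acc[g + 1L] <- TRUE
  }
  idx[acc]
}

#' Fitness peaks
#'
#' Local fitness maxima of the landscape.  Because the evolutionary model
#' has no back mutation, adaptation moves only through mutation-gain
#' steps, so the default peak notion (`neighbors = "gain"`) is a genotype
#' whose fitness is strictly greater than that of every single
#' mutation-gain neighbor: the possible end points of adaptive walks.
#' `neighbors = "all"` instead requires strict superiority over all
#' Hamming-distance-1 neighbors (gain and loss directions), the classical
#' landscape-theory peak.  By default the returned set is restricted to
#' accessible genotypes, the quantity used when summarizing landscape
#' ruggedness.
#'
#' @inheritParams accessible_genotypes
#' @param accessible_only intersect the peak set with
#'   [accessible_genotypes()] (default `TRUE`).
#' @param neighbors `"gain"` (default) or `"all"`, see above.
#' @return sorted integer vector of genotype indices.
#' @export
landscape_peaks <- function(landscape, accessible_only = TRUE,
                            neighbors = c("gain", "all")) {
  stopifnot_landscape(landscape)
  neighbors <- match.arg(neighbors)
  m <- landscape$m
  f <- landscape$fitness
  n <- 2^m
  idx <- 0:(n - 1)
  is_peak <- rep(TRUE, n)
  for (k in 0:(m - 1)) {
    bit <- bitwShiftL(1L, k)
    nb <- bitwXor(idx, bit)
    beats <- f > f[nb + 1L]
    if (neighbors == "gain") {
      # genotypes already mutated at k have no gain neighbor in direction k
      beats <- beats | bitwAnd(idx, bit) == bit
    }
    is_peak <- is_peak & beats
  }
  peaks <- idx[is_peak]
  if (accessible_only) peaks <- intersect(peaks, accessible_genotypes(landscape))
  sort(peaks)
}

# Sign of a fitness difference with a relative dead-band: exact ties (and
# differences that are ties up to floating noise) count as "no sign change".
.delta_sign <- function(delta, scale) {
  tol <- 1e-9 * scale
  ifelse(delta > tol, 1L, ifelse(delta < -tol, -1L, 0L))
}

#' Classify the epistasis of a two-locus square
#'
#' For loci `i`, `j` on a fixed genetic background `b` (both loci unmutated
#' in `b`), the four genotypes `b`, `b+i`, `b+j`, `b+i+j` form a square.
#' With the focal-mutation effects `delta_i(b) = f(b+i) - f(b)` and
#' `delta_i(b+j) = f(b+i+j) - f(b+j)` (and likewise for `j`):
#' * `reciprocal_sign`: both `delta_i` and `delta_j` strictly reverse sign
#'   across the other locus's background;
#' * `sign`: exactly one of the two reverses sign;
#' * `magnitude`: no reversal but a non-zero interaction
#'   (`f(b+i+j) - f(b+j) != f(b+i) - f(b)`);
#' * `no_epistasis`: additive square.
#'
#' Zero (or numerically negligible) differences are treated as no sign
#' change.
#'
#' @inheritParams accessible_genotypes
#' @param locus_i,locus_j gene names or 1-based locus positions; must differ.
#' @param background genotype index with both loci unmutated.
#' @return one of `"no_epistasis"`, `"magnitude"`, `"sign"`,
#'   `"reciprocal_sign"`.
#' @export
classify_square <- function(landscape, locus_i, locus_j, background = 0L) {
  stopifnot_landscape(landscape)
  i <- resolve_locus(landscape, locus_i)
  j <- resolve_locus(landscape, locus_j)
  if (i == j) stop("locus_i and locus_j must differ")
  bi <- bitwShiftL(1L, i - 1L)
  bj <- bitwShiftL(1L, j - 1L)
  b <- as.integer(background)
  if (bitwAnd(b, bi) != 0L || bitwAnd(b, bj) != 0L)
    stop("background must have both loci unmutated")
  f <- landscape$fitness
  f00 <- f[b + 1L]
  f10 <- f[bitwOr(b, bi) + 1L]
  f01 <- f[bitwOr(b, bj) + 1L]
  f11 <- f[bitwOr(bitwOr(b, bi), bj) + 1L]
  classify_square_values(f00, f10, f01, f11)
}

classify_square_values <- function(f00, f10, f01, f11) {
  scale <- pmax(abs(f00), abs(f10), abs(f01), abs(f11))
  si0 <- .delta_sign(f10 - f00, scale)
  si1 <- .delta_sign(f11 - f01, scale)
  sj0 <- .delta_sign(f01 - f00, scale)
  sj1 <- .delta_sign(f11 - f10, scale)
  rev_i <- si0 * si1 == -1L
  rev_j <- sj0 * sj1 == -1L
  inter <- .delta_sign((f11 - f01) - (f10 - f00), scale) != 0L
  ifelse(rev_i & rev_j, "reciprocal_sign",
         ifelse(xor(rev_i, rev_j), "sign",
                ifelse(inter, "magnitude", "no_epistasis")))
}

resolve_locus <- function(landscape, locus) {
  if (is.character(locus)) {
    i <- match(locus, landscape$genes)
    if (is.na(i)) stop("unknown gene: ", locus)
    return(i)
  }
  i <- as.integer(locus)
  if (i < 1 || i > landscape$m) stop("locus out of range")
  i
}

#' Fraction of reciprocal sign epistasis in a landscape
#'
#' Classifies every two-locus square (each unordered locus pair on each of
#' its `2^(m-2)` backgrounds) and reports the fraction classified as
#' reciprocal sign epistasis.  With `per = "pair"`, a locus pair counts
#' once if any of its backgrounds shows reciprocal sign epistasis and the
#' fraction is over the `m(m-1)/2` pairs.
#'
#' @inheritParams accessible_genotypes
#' @param per aggregation unit: `"square"` (default) or `"pair"`.
#' @return fraction in `[0, 1]`.
#' @export
rse_fraction <- function(landscape, per = c("square", "pair")) {
  stopifnot_landscape(landscape)
  per <- match.arg(per)
  m <- landscape$m
  if (m < 2) stop("rse_fraction requires at least 2 loci")
  f <- landscape$fitness
  idx <- 0:(2^m - 1)
  pair_any <- 0
  n_rse <- 0
  n_sq <- 0
  for (i in 1:(m - 1)) {
    for (j in (i + 1):m) {
      bi <- bitwShiftL(1L, i - 1L)
      bj <- bitwShiftL(1L, j - 1L)
      b <- idx[bitwAnd(idx, bi) == 0L & bitwAnd(idx, bj) == 0L]
      cls <- classify_square_values(f[b + 1L], f[bitwOr(b, bi) + 1L],
                                    f[bitwOr(b, bj) + 1L],
                                    f[bitwOr(bitwOr(b, bi), bj) + 1L])
      hits <- sum(cls == "reciprocal_sign")
      n_rse <- n_rse + hits
      n_sq <- n_sq + length(b)
      if (hits > 0) pair_any <- pair_any + 1
    }
  }
  if (per == "square") n_rse / n_sq else pair_any / (m * (m - 1) / 2)
}

#' Write / read a fitness landscape as CSV
#'
#' One row per genotype: `m` 0/1 gene columns (header = gene names) plus a
#' `fitness` column.  The 0/1 part round-trips bit-exactly.
#'
#' @param landscape a [fitness_landscape()].
#' @param path file path.
#' @export
write_landscape <- function(landscape, path) {
  stopifnot_landscape(landscape)
  idx <- 0:(2^landscape$m - 1)
  bits <- genotype_bits(idx, landscape$m)
  colnames(bits) <- landscape$genes
  df <- data.frame(bits, fitness = landscape$fitness, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_landscape
#' @param lethal_threshold passed to [fitness_landscape()].
#' @export
read_landscape <- function(path, lethal_threshold = 1e-9) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"fitness" %in% names(df)) stop("landscape CSV needs a 'fitness' column")
  genes <- setdiff(names(df), "fitness")
  m <- length(genes)
  bits <- as.matrix(df[genes])
  if (!all(bits %in% c(0, 1))) stop("gene columns must be 0/1")
  idx <- genotype_index(bits)
  if (length(unique(idx)) != 2^m || nrow(df) != 2^m)
    stop("landscape CSV must list each of the 2^m genotypes exactly once")
  fitness <- numeric(2^m)
  fitness[idx + 1] <- df$fitness
  fitness_landscape(fitness, genes, lethal_threshold = lethal_threshold)
}
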