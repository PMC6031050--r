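# Independent brute-force oracles, written against the definitions rather
# than the package implementation: path enumeration for accessibility,
# per-genotype neighbor scans for peaks, an explicit sign table for
# epistasis squares, and edge-subset search for transitive reduction.

oracle_bits <- function(g, m) {
  vapply(0:(m - 1), function(k) (g %/% 2^k) %% 2, numeric(1))
}

# Accessibility by explicit depth-first enumeration of strictly increasing
# mutation-gain paths from WT.
oracle_accessible <- function(fl) {
  m <- fl$m
  f <- fl$fitness
  seen <- new.env()
  walk <- function(g) {
    key <- as.character(g)
    if (!is.null(seen[[key]])) return(invisible())
    seen[[key]] <- TRUE
    b <- oracle_bits(g, m)
    for (k in which(b == 0)) {
      h <- g + 2^(k - 1)
      if (f[h + 1] > f[g + 1]) walk(h)
    }
  }
  walk(0)
  sort(as.integer(ls(seen)))
}

oracle_peaks <- function(fl, accessible_only = TRUE,
                         neighbors = c("gain", "all")) {
  neighbors <- match.arg(neighbors)
  m <- fl$m
  f <- fl$fitness
  out <- integer(0)
  for (g in 0:(2^m - 1)) {
    b <- oracle_bits(g, m)
    dirs <- if (neighbors == "gain") which(b == 0) else 1:m
    nb <- vapply(dirs, function(k) bitwXor(g, as.integer(2^(k - 1))),
                 integer(1))
    if (all(f[nb + 1] < f[g + 1])) out <- c(out, g)
  }
  if (accessible_only) out <- intersect(out, oracle_accessible(fl))
  sort(out)
}

# Sign table for one square, spelled out case by case.
oracle_square <- function(f00, f10, f01, f11) {
  s <- function(x) if (x > 0) 1 else if (x < 0) -1 else 0
  di0 <- s(f10 - f00); di1 <- s(f11 - f01)
  dj0 <- s(f01 - f00); dj1 <- s(f11 - f10)
  flip_i <- (di0 == 1 && di1 == -1) || (di0 == -1 && di1 == 1)
  flip_j <- (dj0 == 1 && dj1 == -1) || (dj0 == -1 && dj1 == 1)
  if (flip_i && flip_j) return("reciprocal_sign")
  if (flip_i || flip_j) return("sign")
  if ((f11 - f01) != (f10 - f00)) return("magnitude")
  "no_epistasis"
}

oracle_rse_fraction <- function(fl) {
  m <- fl$m
  f <- fl$fitness
  hits <- 0
  total <- 0
  for (i in 1:(m - 1)) for (j in (i + 1):m) {
    for (g in 0:(2^m - 1)) {
      b <- oracle_bits(g, m)
      if (b[i] == 1 || b[j] == 1) next
      total <- total + 1
      cls <- oracle_square(f[g + 1], f[g + 2^(i - 1) + 1],
                           f[g + 2^(j - 1) + 1],
                           f[g + 2^(i - 1) + 2^(j - 1) + 1])
      if (cls == "reciprocal_sign") hits <- hits + 1
    }
  }
  hits / total
}

# Reachability (genes only) by explicit path search.
oracle_reach <- function(adj) {
  m <- nrow(adj)
  reach <- adj
  for (k in 1:m) for (i in 1:m) for (j in 1:m) {
    if (reach[i, k] && reach[k, j]) reach[i, j] <- TRUE
  }
  reach
}

# Random fitness landscape over m loci (positive values, WT = 1).
random_small_landscape <- function(m) {
  f <- exp(stats::rnorm(2^m))
  f <- f / f[1]
  fitness_landscape(f, LETTERS[1:m])
}

# Random valid restriction DAG via random adjacency, keeping acyclic draws.
random_small_dag <- function(m, p = 0.4) {
  genes <- LETTERS[1:m]
  repeat {
    adj <- matrix(stats::runif(m * m) < p, m, m)
    diag(adj) <- FALSE
    edges <- which(adj, arr.ind = TRUE)
    e <- matrix(c(genes[edges[, 1]], genes[edges[, 2]]), ncol = 2)
    root_genes <- genes[colSums(adj) == 0]
    if (length(root_genes) > 0)
      e <- rbind(matrix(c(rep("Root", length(root_genes)), root_genes),
                        ncol = 2), e)
    dag <- tryCatch(restriction_dag(e, genes = genes),
                    error = function(err) NULL)
    if (!is.null(dag)) return(dag)
  }
}

make_additive_landscape <- function(effects) {
  m <- length(effects)
  idx <- 0:(2^m - 1)
  bits <- genotype_bits(idx, m)
  fitness_landscape(1 + as.numeric(bits %*% effects), LETTERS[1:m])
}

expected_edges <- function(...) {
  e <- rbind(...)
  dimnames(e) <- list(NULL, c("parent", "child"))
  e
}
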