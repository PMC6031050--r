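# DAGs of restrictions: directed acyclic graphs over genes plus a
# distinguished Root node.  An edge i -> j means a mutation in j requires a
# mutation in i; nodes with multiple parents have conjunctive (AND)
# semantics.  Internally a DAG is stored as a logical gene-by-gene
# adjacency matrix plus a logical vector marking Root -> gene edges.

#' Construct a DAG of restrictions
#'
#' @param edges two-column character matrix or data frame of directed edges
#'   `(parent, child)`; the literal `"Root"` denotes the root node.
#' @param genes gene names fixing locus order.  Defaults to the sorted set
#'   of gene names appearing in `edges`.
#' @return an object of class `restriction_dag` with fields `genes`,
#'   `root` (logical: Root -> gene edge present) and `adj` (logical
#'   gene-parent by gene-child adjacency matrix).
#' @details Validity requires: no self edges, no edges into Root,
#'   acyclicity, and every gene reachable from Root (in particular, every
#'   gene without gene parents must carry an explicit Root edge).
#' @export
restriction_dag <- function(edges, genes = NULL) {
  edges <- as.matrix(edges)
  if (length(edges) == 0) edges <- matrix(character(0), ncol = 2)
  if (ncol(edges) != 2) stop("edges must have two columns (parent, child)")
  mode(edges) <- "character"
  if (is.null(genes))
    genes <- sort(setdiff(unique(c(edges)), "Root"))
  genes <- as.character(genes)
  m <- length(genes)
  if (m == 0) stop("a restriction DAG needs at least one gene")
  if (anyDuplicated(genes)) stop("duplicated gene names")
  unknown <- setdiff(unique(c(edges)), c(genes, "Root"))
  if (length(unknown) > 0)
    stop("unknown gene name(s) in edges: ", paste(unknown, collapse = ", "))
  if (any(edges[, 2] == "Root")) stop("edges into Root are not allowed")
  if (any(edges[, 1] == edges[, 2])) stop("self edges are not allowed")
  root <- stats::setNames(logical(m), genes)
  adj <- matrix(FALSE, m, m, dimnames = list(genes, genes))
  for (r in seq_len(nrow(edges))) {
    p <- edges[r, 1]; ch <- edges[r, 2]
    if (p == "Root") root[ch] <- TRUE else adj[p, ch] <- TRUE
  }
  dag <- structure(list(genes = genes, root = root, adj = adj),
                   class = "restriction_dag")
  if (dag_has_cycle(dag)) stop("edges contain a cycle")
  no_parent <- colSums(adj) == 0
  if (any(no_parent & !root))
    stop("gene(s) unreachable from Root: ",
         paste(genes[no_parent & !root], collapse = ", "))
  dag
}

dag_has_cycle <- function(dag) {
  # Kahn's algorithm on the gene-gene adjacency
  adj <- dag$adj
  indeg <- colSums(adj)
  queue <- which(indeg == 0)
  seen <- 0
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]
    seen <- seen + 1
    kids <- which(adj[v, ])
    indeg[kids] <- indeg[kids] - 1
    queue <- c(queue, kids[indeg[kids] == 0])
  }
  seen < length(dag$genes)
}

stopifnot_dag <- function(dag) {
  if (!inherits(dag, "restriction_dag"))
    stop("expected a 'restriction_dag' object")
}

#' Edge list of a restriction DAG
#'
#' @param dag a [restriction_dag()].
#' @param include_root include `Root ->` edges.
#' @return two-column character matrix `(parent, child)`.
#' @export
dag_edges <- function(dag, include_root = TRUE) {
  stopifnot_dag(dag)
  e <- which(dag$adj, arr.ind = TRUE)
  out <- cbind(parent = dag$genes[e[, 1]], child = dag$genes[e[, 2]])
  if (include_root && any(dag$root))
    out <- rbind(cbind(parent = "Root", child = dag$genes[dag$root]), out)
  out[order(out[, 1], out[, 2]), , drop = FALSE]
}

#' @export
print.restriction_dag <- function(x, ...) {
  e <- dag_edges(x)
  cat(sprintf("Restriction DAG: %d genes (%s), %d edges\n",
              length(x$genes), paste(x$genes, collapse = ","), nrow(e)))
  cat(paste0("  ", e[, 1], " -> ", e[, 2], collapse = "\n"), "\n")
  invisible(x)
}

#' Genotypes compatible with a DAG of restrictions
#'
#' A genotype is compatible if every mutated gene has all of its (non-Root)
#' parents mutated as well (AND semantics).  The wild type is always
#' compatible.
#'
#' @param dag a [restriction_dag()].
#' @param exclude_wt drop the wild type from the returned set.
#' @return sorted integer vector of genotype indices (see
#'   [genotype_bits()] for the encoding; gene k = bit k - 1 in the order of
#'   `dag$genes`).
#' @export
compatible_genotypes <- function(dag, exclude_wt = FALSE) {
  stopifnot_dag(dag)
  m <- length(dag$genes)
  idx <- 0:(2^m - 1)
  ok <- rep(TRUE, 2^m)
  for (j in seq_len(m)) {
    parents <- which(dag$adj[, j])
    if (length(parents) == 0) next
    pmask <- sum(bitwShiftL(1L, parents - 1L))
    jbit <- bitwShiftL(1L, j - 1L)
    ok <- ok & (bitwAnd(idx, jbit) == 0L | bitwAnd(idx, pmask) == pmask)
  }
  out <- idx[ok]
  if (exclude_wt) out <- setdiff(out, 0L)
  out
}

#' Transitive reduction of a restriction DAG
#'
#' Returns the unique minimal edge set with the same reachability relation
#' as the input.  Root edges are recomputed so that exactly the genes
#' without gene parents (after reduction) carry a Root edge.
#'
#' @param dag a [restriction_dag()].
#' @return a reduced [restriction_dag()].
#' @export
transitive_reduction <- function(dag) {
  stopifnot_dag(dag)
  adj <- dag$adj
  m <- nrow(adj)
  reach <- adj
  if (m > 1) {
    # Boolean transitive closure (small m; repeated squaring is plenty)
    repeat {
      nxt <- reach | ((reach %*% reach) > 0)
      if (identical(nxt, reach)) break
      reach <- nxt
    }
  }
  red <- adj
  for (i in seq_len(m)) {
    for (j in which(adj[i, ])) {
      via <- which(adj[i, ] & reach[, j])
      if (length(setdiff(via, c(i, j))) > 0) red[i, j] <- FALSE
    }
  }
  root <- colSums(red) == 0
  structure(list(genes = dag$genes,
                 root = stats::setNames(root, dag$genes), adj = red),
            class = "restriction_dag")
}

edge_keys <- function(dag, include_root = TRUE) {
  e <- dag_edges(dag, include_root = include_root)
  paste(e[, 1], e[, 2], sep = "->")
}

#' Distance between two DAGs of restrictions
#'
#' Both DAGs are transitively reduced; the distance is the number of edges
#' in the symmetric difference of the reduced edge sets, and the relative
#' distance divides by the number of distinct edges in the union of the two
#' reduced sets.
#'
#' @param d1,d2 [restriction_dag()]s over the same gene set.
#' @param include_root count `Root ->` edges (default `TRUE`).
#' @return named numeric vector `c(count = ..., relative = ...)`.
#' @export
dag_distance <- function(d1, d2, include_root = TRUE) {
  stopifnot_dag(d1); stopifnot_dag(d2)
  if (!setequal(d1$genes, d2$genes))
    stop("DAGs must be over the same gene set")
  e1 <- edge_keys(transitive_reduction(d1), include_root)
  e2 <- edge_keys(transitive_reduction(d2), include_root)
  sd <- length(setdiff(e1, e2)) + length(setdiff(e2, e1))
  un <- length(union(e1, e2))
  c(count = sd, relative = if (un == 0) 0 else sd / un)
}

#' Is a fitness landscape representable by a DAG of restrictions?
#'
#' `TRUE` iff the accessible genotypes of the landscape are exactly the
#' genotypes compatible with the DAG (the wild type, trivially in both
#' sets, does not affect the comparison).
#'
#' @param landscape a [fitness_landscape()].
#' @param dag a [restriction_dag()] over the same genes, in the same order.
#' @export
is_representable <- function(landscape, dag) {
  stopifnot_landscape(landscape)
  stopifnot_dag(dag)
  if (!identical(landscape$genes, dag$genes))
    stop("landscape and DAG must share the same genes in the same order")
  setequal(accessible_genotypes(landscape), compatible_genotypes(dag))
}

#' Read / write DAG edge-list files
#'
#' Plain-text dialect: one `parent child` pair per line (whitespace
#' separated), with the literal `Root` for the root node; `#` starts a
#' comment.  Used both for fixtures and to import DAGs inferred by external
#' cancer progression model software.
#'
#' @param path file path.
#' @param genes optional gene set; names in the file outside it are an
#'   error.
#' @return [read_dag()] returns a [restriction_dag()].
#' @export
read_dag <- function(path, genes = NULL) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  toks <- strsplit(trimws(lines[keep]), "\\s+")
  bad <- which(lengths(toks) != 2)
  if (length(bad) > 0)
    stop("malformed edge at line ", which(keep)[bad[1]], " of ", path,
         ": expected 'parent child'")
  edges <- do.call(rbind, toks)
  tryCatch(restriction_dag(edges, genes = genes),
           error = function(e) stop("invalid DAG in ", path, ": ",
                                    conditionMessage(e), call. = FALSE))
}

#' @rdname read_dag
#' @param dag a [restriction_dag()].
#' @export
write_dag <- function(dag, path) {
  stopifnot_dag(dag)
  e <- dag_edges(dag)
  writeLines(paste(e[, 1], e[, 2]), path)
  invisible(path)
}
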