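# Cross-sectional cohort matrices: binary patients-by-genes mutation data.

#' Validate / coerce a cohort matrix
#'
#' A cohort is an integer 0/1 matrix, rows = patients (tumor samples),
#' columns = genes, with gene names as column names.
#'
#' @param x matrix or data frame of 0/1 entries.
#' @return integer matrix with column names.
#' @export
as_cohort <- function(x) {
  x <- as.matrix(x)
  if (!all(x %in% c(0, 1))) stop("cohort entries must be 0/1")
  storage.mode(x) <- "integer"
  if (is.null(colnames(x))) colnames(x) <- make_gene_names(ncol(x))
  x
}

#' Read / write a cohort as CSV
#'
#' Rows = samples, columns = gene names, entries 0/1.
#'
#' @param path file path.
#' @export
read_cohort <- function(path) {
  as_cohort(utils::read.csv(path, check.names = FALSE))
}

#' @rdname read_cohort
#' @param cohort a cohort matrix (see [as_cohort()]).
#' @export
write_cohort <- function(cohort, path) {
  cohort <- as_cohort(cohort)
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Genotype frequency table of a cohort
#'
#' @param cohort a cohort matrix.
#' @return named numeric vector of genotype frequencies; names are
#'   genotype indices as characters.
#' @export
cohort_genotype_freq <- function(cohort) {
  cohort <- as_cohort(cohort)
  idx <- genotype_index(cohort)
  tab <- table(idx) / nrow(cohort)
  stats::setNames(as.numeric(tab), names(tab))
}
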