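#' Expression cohort container
#'
#' Bundles a genes-by-samples matrix of log-scale intensities with a binary
#' phenotype (1 = tumor, 0 = control) per sample. This is the unit of data
#' every pipeline stage consumes and returns.
#'
#' @param values numeric matrix, genes in rows (unique rownames), samples in
#'   columns (unique colnames). Missing values allowed.
#' @param phenotype integer vector of 0/1, named by sample or in column
#'   order.
#' @return An object of class \code{"expr_cohort"} with elements
#'   \code{values} and \code{phenotype} (named, aligned to columns).
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' ec <- expr_cohort(m, c(1, 1, 0, 0))
#' dim(ec$values)
#' @export
expr_cohort <- function(values, phenotype) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' needs gene rownames and sample colnames")
  if (anyDuplicated(rownames(values))) stop("duplicate gene ids")
  if (anyDuplicated(colnames(values))) stop("duplicate sample ids")
  if (is.null(names(phenotype))) {
    if (length(phenotype) != ncol(values))
      stop("phenotype length must match sample count")
    names(phenotype) <- colnames(values)
  }
  if (!all(colnames(values) %in% names(phenotype)))
    stop("phenotype missing for some samples")
  phenotype <- phenotype[colnames(values)]
  if (!all(phenotype %in% c(0L, 1L)))
    stop("phenotype must be binary 0/1")
  structure(list(values = values,
                 phenotype = stats::setNames(as.integer(phenotype),
                                             names(phenotype))),
            class = "expr_cohort")
}

#' @export
print.expr_cohort <- function(x, ...) {
  ph <- x$phenotype
  cat(sprintf("expr_cohort: %d genes x %d samples (%d tumor, %d control)\n",
              nrow(x$values), ncol(x$values), sum(ph == 1), sum(ph == 0)))
  nm <- sum(is.na(x$values))
  if (nm > 0)
    cat(sprintf("  missing values: %d (%.2f%%)\n", nm,
                100 * nm / length(x$values)))
  invisible(x)
}

#' @export
dim.expr_cohort <- function(x) dim(x$values)

# row subset keeping phenotype alignment
subset_genes <- function(cohort, genes) {
  expr_cohort(cohort$values[genes, , drop = FALSE], cohort$phenotype)
}

#' Read / write an expression cohort as TSV
#'
#' Expression is a TSV with gene ids in the first column and one column per
#' sample; the phenotype file is a two-column TSV (\code{sample_id},
#' \code{status}) with status 0/1.
#'
#' @param expr_path,phenotype_path file paths.
#' @return \code{read_expression} returns an \code{\link{expr_cohort}}.
#' @export
read_expression <- function(expr_path, phenotype_path) {
  tab <- utils::read.delim(expr_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- as.character(tab[[1]])
  ph <- utils::read.delim(phenotype_path, stringsAsFactors = FALSE)
  status <- as.integer(ph[[2]])
  names(status) <- as.character(ph[[1]])
  expr_cohort(m, status)
}

#' @rdname read_expression
#' @param cohort an \code{expr_cohort}.
#' @export
write_expression <- function(cohort, expr_path, phenotype_path) {
  tab <- data.frame(gene_id = rownames(cohort$values),
                    cohort$values, check.names = FALSE)
  utils::write.table(tab, expr_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  ph <- data.frame(sample_id = colnames(cohort$values),
                   status = cohort$phenotype)
  utils::write.table(ph, phenotype_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(expr_path, phenotype_path))
}
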