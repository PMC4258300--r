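#' Gene-set collection
#'
#' An ordered collection of named gene sets (as used for GO_BP terms,
#' candidate-gene evidence sets and regulator target sets), with optional
#' per-set descriptions and a category tag.
#'
#' @param sets named list of character vectors (duplicate genes within a
#'   set are dropped).
#' @param descriptions optional character vector parallel to \code{sets}.
#' @param category one of \code{"go_bp"}, \code{"evidence"},
#'   \code{"regulator"} (or any label).
#' @return An object of class \code{"gene_set_collection"}.
#' @export
gene_set_collection <- function(sets, descriptions = NULL,
                                category = "go_bp") {
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("sets must have unique names")
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (any(!lengths(sets))) stop("empty gene set")
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  structure(list(sets = sets, descriptions = descriptions,
                 category = category),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection [%s]: %d sets, sizes %d-%d\n",
              x$category, length(x$sets),
              if (length(x$sets)) min(lengths(x$sets)) else 0,
              if (length(x$sets)) max(lengths(x$sets)) else 0))
  invisible(x)
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

#' @export
`[.gene_set_collection` <- function(x, i) {
  gene_set_collection(x$sets[i], x$descriptions[i], x$category)
}

#' Read a GMT gene-set file
#'
#' One set per line: name, description and member genes, tab-separated
#' (MSigDB dialect). Duplicate genes within a line are dropped; empty lines
#' are skipped.
#'
#' @param path GMT file path.
#' @param category collection category tag.
#' @return A \code{\link{gene_set_collection}}.
#' @export
read_gmt <- function(path, category = "go_bp") {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  sets <- list(); desc <- character()
  for (i in which(keep)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop(sprintf("malformed GMT line %d: fewer than 3 fields", i))
    sets[[f[1]]] <- unique(f[-(1:2)])
    desc <- c(desc, f[2])
  }
  gene_set_collection(sets, desc, category)
}

#' @rdname read_gmt
#' @param collection a \code{\link{gene_set_collection}}.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(seq_along(collection$sets), function(i) {
    paste(c(names(collection$sets)[i], collection$descriptions[i],
            collection$sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Filter gene sets by measured-gene count
#'
#' Each set is first intersected with the measured genes; sets are kept iff
#' the intersection size lies in \code{[min_size, max_size]} (inclusive) and
#' are returned with the intersected membership. The defaults reproduce the
#' 50-500 measured-gene eligibility window for GO_BP terms.
#'
#' @param collection a \code{\link{gene_set_collection}}.
#' @param expr_genes character vector of measured gene ids.
#' @param min_size,max_size inclusive size bounds.
#' @return The filtered \code{\link{gene_set_collection}} (input order
#'   preserved).
#' @export
filter_by_size <- function(collection, expr_genes, min_size = 50,
                           max_size = 500) {
  stopifnot(min_size <= max_size)
  inter <- lapply(collection$sets, intersect, y = expr_genes)
  keep <- lengths(inter) >= max(min_size, 1) & lengths(inter) <= max_size
  gene_set_collection(inter[keep], collection$descriptions[keep],
                      collection$category)
}

#' Extract a term's expression submatrix
#'
#' @param cohort an \code{\link{expr_cohort}}.
#' @param genes character vector (a gene set's members).
#' @return An \code{\link{expr_cohort}} restricted to the measured set
#'   genes, samples untouched.
#' @export
term_expression <- function(cohort, genes) {
  g <- intersect(genes, rownames(cohort$values))
  if (length(g) < 2) stop("fewer than 2 measured genes in set")
  subset_genes(cohort, g)
}
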