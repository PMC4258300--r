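#' Eigengene-trait association
#'
#' Pearson correlation between a module eigengene and the binary disease
#' status (1 = tumor, 0 = control), with the two-sided p-value from the
#' t-statistic \code{t = r * sqrt((n - 2) / (1 - r^2))} on \code{n - 2}
#' degrees of freedom.
#'
#' @param eigengene per-sample eigengene values (named by sample id when
#'   the phenotype is named).
#' @param phenotype binary 0/1 vector.
#' @return List with \code{r}, \code{p}, \code{n}.
#' @export
trait_association <- function(eigengene, phenotype) {
  if (!is.null(names(eigengene)) && !is.null(names(phenotype)))
    phenotype <- phenotype[names(eigengene)]
  ok <- !is.na(eigengene) & !is.na(phenotype)
  e <- eigengene[ok]; ph <- phenotype[ok]
  n <- length(e)
  if (n < 4) stop("need at least 4 samples")
  if (length(unique(ph)) < 2) stop("phenotype has a single class")
  r <- stats::cor(e, ph)
  if (abs(r) >= 1) {
    p <- 0
  } else {
    t_stat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(abs(t_stat), df = n - 2, lower.tail = FALSE)
  }
  list(r = r, p = min(p, 1), n = n)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values with monotonicity enforcement; invariant
#' under permutation of the input order.
#'
#' @param pvalues numeric vector in [0, 1] (NAs passed through).
#' @return Adjusted values, same order as input.
#' @export
bh_fdr <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Hypergeometric over-representation test
#'
#' Upper-tail probability of observing at least the realized overlap
#' between a module and an evidence gene set, conditioned on the measured
#' gene universe (the evidence set is intersected with the universe
#' first). Identical to a one-sided Fisher's exact test on the 2x2 table.
#'
#' @param module_genes module member genes (subset of universe).
#' @param evidence_set evidence gene set.
#' @param universe measured gene universe.
#' @return List of class \code{"enrichment_record"}: \code{k} (overlap),
#'   \code{m} (module size), \code{K} (evidence size in universe),
#'   \code{N} (universe size), \code{p}, \code{overlap_genes}.
#' @export
hypergeometric_enrichment <- function(module_genes, evidence_set, universe) {
  universe <- unique(universe)
  module_genes <- unique(module_genes)
  if (!length(universe) || !length(module_genes))
    stop("empty module or universe")
  if (!all(module_genes %in% universe))
    stop("module genes must lie in the universe")
  ev <- intersect(unique(evidence_set), universe)
  ov <- intersect(module_genes, ev)
  k <- length(ov); m <- length(module_genes)
  K <- length(ev); N <- length(universe)
  p <- stats::phyper(k - 1, K, N - K, m, lower.tail = FALSE)
  structure(list(k = k, m = m, K = K, N = N, p = p, overlap_genes = ov),
            class = "enrichment_record")
}

#' Two-sided Fisher's exact test of module overlap
#'
#' @param module_a,module_b gene sets (subsets of universe).
#' @param universe gene universe.
#' @return List with \code{odds_ratio}, \code{p}, \code{k} (overlap size).
#' @export
module_overlap_fisher <- function(module_a, module_b, universe) {
  universe <- unique(universe)
  a <- intersect(unique(module_a), universe)
  b <- intersect(unique(module_b), universe)
  if (!length(a) || !length(b)) stop("empty module")
  k <- length(intersect(a, b))
  tab <- matrix(c(k, length(a) - k, length(b) - k,
                  length(universe) - length(a) - length(b) + k), 2, 2)
  ft <- stats::fisher.test(tab)
  list(odds_ratio = unname(ft$estimate), p = ft$p.value, k = k)
}

#' Call candidate modules from multi-evidence enrichment
#'
#' A module (already trait-significant and preserved: the two-step gate)
#' becomes a candidate when its enrichment FDR is below \code{fdr_cut} in
#' at least \code{min_categories} distinct evidence categories
#' (cis-eQTL and trans-eQTL count as distinct). The alternative rule
#' \code{"eqtl_plus_other"} requires one significant eQTL category plus
#' one of SCNA / mutation / prognostic.
#'
#' @param enrichment_table data.frame with columns \code{module},
#'   \code{category}, \code{fdr} (one row per module-category test).
#' @param fdr_cut significance level (default 0.05).
#' @param min_categories minimum qualifying categories (default 2).
#' @param rule \code{"min_categories"} (default) or
#'   \code{"eqtl_plus_other"}.
#' @return data.frame: module, n_qualifying, qualifying categories
#'   (comma-joined), candidate flag.
#' @export
call_candidates <- function(enrichment_table, fdr_cut = 0.05,
                            min_categories = 2,
                            rule = c("min_categories", "eqtl_plus_other")) {
  rule <- match.arg(rule)
  sig <- enrichment_table[!is.na(enrichment_table$fdr) &
                            enrichment_table$fdr < fdr_cut, , drop = FALSE]
  mods <- unique(enrichment_table$module)
  rows <- lapply(mods, function(m) {
    cats <- unique(sig$category[sig$module == m])
    ok <- if (rule == "min_categories") {
      length(cats) >= min_categories
    } else {
      any(cats %in% c("cis_eqtl", "trans_eqtl")) &&
        any(cats %in% c("scna", "mutation", "prognostic"))
    }
    data.frame(module = m, n_qualifying = length(cats),
               categories = paste(sort(cats), collapse = ","),
               candidate = ok, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Merge candidate modules with significant gene overlap
#'
#' Pairwise two-sided Fisher tests between candidate gene sets; pairs
#' significant after Bonferroni correction over all pairs (p * n_pairs <
#' alpha) are linked, connected components are merged and their gene sets
#' unioned. Order-independent.
#'
#' @param candidates named list of candidate module gene vectors.
#' @param universe gene universe.
#' @param alpha Bonferroni-adjusted significance level (default 0.01).
#' @return List with \code{merged} (named list of gene vectors; merged
#'   names join members with \code{"+"}), \code{components} (membership
#'   map) and \code{pairs} (pairwise test table).
#' @export
merge_overlapping_candidates <- function(candidates, universe,
                                         alpha = 0.01) {
  nm <- names(candidates)
  n <- length(candidates)
  if (n < 2)
    return(list(merged = candidates,
                components = stats::setNames(seq_len(n), nm),
                pairs = NULL))
  comb <- utils::combn(n, 2)
  n_pairs <- ncol(comb)
  pairs <- data.frame(a = nm[comb[1, ]], b = nm[comb[2, ]],
                      p = NA_real_, significant = FALSE,
                      stringsAsFactors = FALSE)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (j in seq_len(n_pairs)) {
    ft <- module_overlap_fisher(candidates[[comb[1, j]]],
                                candidates[[comb[2, j]]], universe)
    pairs$p[j] <- ft$p
    if (ft$p * n_pairs < alpha) {
      pairs$significant[j] <- TRUE
      ra <- find(comb[1, j]); rb <- find(comb[2, j])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  comp <- match(roots, sort(unique(roots)))
  merged <- lapply(sort(unique(comp)), function(cc) {
    sort(unique(unlist(candidates[comp == cc])))
  })
  names(merged) <- vapply(sort(unique(comp)), function(cc) {
    paste(sort(nm[comp == cc]), collapse = "+")
  }, character(1))
  list(merged = merged, components = stats::setNames(comp, nm),
       pairs = pairs)
}

#' Rank regulator (TF / miRNA) target-set enrichment
#'
#' Hypergeometric enrichment of one module against every regulator target
#' set; overlaps below \code{min_overlap} genes are discarded before
#' BH-FDR adjustment across the remaining regulator sets; regulators with
#' FDR below \code{fdr_cut} are kept and the top \code{top_n} are reported,
#' ordered by FDR, then p, then name.
#'
#' @param module_genes candidate module gene set.
#' @param regulator_sets a \code{\link{gene_set_collection}} or named list
#'   of target gene vectors.
#' @param universe measured gene universe.
#' @param fdr_cut FDR threshold (default 0.01).
#' @param min_overlap minimum overlap genes per category (default 2).
#' @param top_n number of regulators reported (default 5).
#' @return data.frame: regulator, k, K, p, fdr, overlap genes
#'   (comma-joined), at most \code{top_n} rows.
#' @export
regulator_enrichment <- function(module_genes, regulator_sets, universe,
                                 fdr_cut = 0.01, min_overlap = 2,
                                 top_n = 5) {
  sets <- if (inherits(regulator_sets, "gene_set_collection"))
    regulator_sets$sets else regulator_sets
  rows <- lapply(names(sets), function(nm) {
    er <- hypergeometric_enrichment(module_genes, sets[[nm]], universe)
    data.frame(regulator = nm, k = er$k, K = er$K, p = er$p,
               overlap_genes = paste(sort(er$overlap_genes),
                                     collapse = ","),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[tab$k >= min_overlap, , drop = FALSE]
  if (!nrow(tab) || top_n < 1)
    return(data.frame(regulator = character(), k = integer(),
                      K = integer(), p = numeric(), fdr = numeric(),
                      overlap_genes = character(),
                      stringsAsFactors = FALSE))
  tab$fdr <- bh_fdr(tab$p)
  tab <- tab[tab$fdr < fdr_cut, , drop = FALSE]
  tab <- tab[order(tab$fdr, tab$p, tab$regulator), , drop = FALSE]
  tab <- utils::head(tab, top_n)
  rownames(tab) <- NULL
  tab[, c("regulator", "k", "K", "p", "fdr", "overlap_genes")]
}
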