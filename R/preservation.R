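#' Permutation Z_summary preservation of a gene set
#'
#' Measures how well the co-expression structure a gene set shows in a
#' reference cohort replicates in a testing cohort. Observed statistics are
#' computed in the TEST data using structure defined in the REFERENCE data
#' (eigengene gene weights come from the reference PCA and are projected
#' onto the test samples). Density statistics: mean off-diagonal
#' correlation, mean off-diagonal adjacency, eigengene variance fraction,
#' mean kME. Connectivity statistics: cross-cohort correlation of
#' intramodular connectivity, of the vectorized correlation matrices, and
#' of the kME vectors. The null re-evaluates every statistic on
#' \code{n_perm} equal-size random gene sets drawn from the shared gene
#' universe; \code{Z = (obs - null mean) / null sd} per statistic,
#' \code{Z_density} and \code{Z_connectivity} are the medians of their
#' groups and \code{Z_summary} their mean. Interpretation bands: < 2 no
#' evidence, 2-10 weak-to-moderate, > 10 strong evidence of preservation.
#'
#' @param genes gene set (>= 10 genes present in both cohorts).
#' @param reference,test \code{\link{expr_cohort}}s sharing a gene
#'   universe.
#' @param beta_ref,beta_test soft-threshold powers for the two cohorts
#'   (default 6).
#' @param n_perm permutation count (default 200, minimum 50).
#' @param seed integer seed; results are reproducible from it.
#' @param dump_null keep the per-permutation statistic draws in the result
#'   (for audit / independent recomputation of the Z scores).
#' @return Object of class \code{"preservation_stats"}: data.frame
#'   \code{table} (statistic, group, observed, null mean, null sd, Z),
#'   \code{Z_density}, \code{Z_connectivity}, \code{Z_summary},
#'   \code{n_permutations}, \code{seed} and optionally \code{null_draws}.
#' @export
preservation_zsummary <- function(genes, reference, test, beta_ref = 6,
                                  beta_test = 6, n_perm = 200, seed = 1,
                                  dump_null = FALSE) {
  if (n_perm < 50) stop("n_perm must be at least 50")
  universe <- intersect(rownames(reference$values), rownames(test$values))
  genes <- unique(genes)
  if (!all(genes %in% universe))
    genes <- intersect(genes, universe)
  if (length(genes) < 10) stop("gene set must have >= 10 genes in both cohorts")

  # missing values are imputed to gene means once; every statistic (observed
  # and null) is then a dense matrix operation on standardized rows
  zr <- standardize_rows(reference$values[universe, , drop = FALSE])
  zt <- standardize_rows(test$values[universe, , drop = FALSE])
  obs <- preservation_statistics(genes, zr, zt, beta_ref, beta_test)
  set.seed(seed)
  draws <- matrix(NA_real_, n_perm, length(obs),
                  dimnames = list(NULL, names(obs)))
  for (b in seq_len(n_perm)) {
    rnd <- sample(universe, length(genes))
    draws[b, ] <- preservation_statistics(rnd, zr, zt, beta_ref, beta_test)
  }
  null_mean <- colMeans(draws, na.rm = TRUE)
  null_sd <- apply(draws, 2, stats::sd, na.rm = TRUE)
  z <- (obs - null_mean) / null_sd
  degenerate <- !is.finite(null_sd) | null_sd < 1e-12
  if (any(degenerate)) {
    warning("degenerate null sd; statistic(s) dropped: ",
            paste(names(obs)[degenerate], collapse = ", "))
    z[degenerate] <- NA_real_
  }
  group <- c(meanCor = "density", meanAdj = "density",
             propVarExplained = "density", meanKME = "density",
             cor_kIM = "connectivity", cor_cor = "connectivity",
             cor_kME = "connectivity")[names(obs)]
  z_density <- stats::median(z[group == "density"], na.rm = TRUE)
  z_connectivity <- stats::median(z[group == "connectivity"], na.rm = TRUE)
  z_summary <- mean(c(z_density, z_connectivity), na.rm = TRUE)
  structure(list(
    table = data.frame(statistic = names(obs), group = group,
                       observed = obs, null_mean = null_mean,
                       null_sd = null_sd, Z = z, row.names = NULL,
                       stringsAsFactors = FALSE),
    Z_density = z_density, Z_connectivity = z_connectivity,
    Z_summary = z_summary, n_permutations = n_perm, seed = seed,
    n_genes = length(genes),
    null_draws = if (dump_null) draws else NULL),
    class = "preservation_stats")
}

# the 4 density + 3 connectivity statistics for one gene set, computed from
# pre-standardized (row mean 0 / sd 1, mean-imputed) cohort matrices
preservation_statistics <- function(genes, zr_full, zt_full,
                                    beta_ref, beta_test) {
  zr <- zr_full[genes, , drop = FALSE]
  zt <- zt_full[genes, , drop = FALSE]
  nr <- ncol(zr); nt <- ncol(zt)
  cor_r <- tcrossprod(zr) / (nr - 1)
  cor_t <- tcrossprod(zt) / (nt - 1)
  cor_r[cor_r > 1] <- 1; cor_r[cor_r < -1] <- -1
  cor_t[cor_t > 1] <- 1; cor_t[cor_t < -1] <- -1
  off <- lower.tri(cor_t)

  adj_r <- abs(cor_r)^beta_ref; diag(adj_r) <- 1
  adj_t <- abs(cor_t)^beta_test; diag(adj_t) <- 1

  # reference-defined eigengene: first left/right singular pair in reference
  sv <- svd(zr, nu = 1, nv = 1)
  w <- sv$u[, 1]
  if (sum(sv$v[, 1] * colMeans(zr)) < 0) w <- -w
  e_ref <- drop(crossprod(zr, w)); e_ref <- e_ref / sqrt(sum(e_ref^2))
  scores <- drop(crossprod(zt, w))
  pve <- sum(scores^2) / sum(zt^2)
  e_test <- if (sum(scores^2) > 0) scores / sqrt(sum(scores^2)) else scores

  std1 <- function(v) {
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) rep(0, length(v)) else (v - mean(v)) / s
  }
  kme_r <- drop(zr %*% std1(e_ref)) / (nr - 1)
  kme_t <- drop(zt %*% std1(e_test)) / (nt - 1)
  kim_r <- rowSums(adj_r) - 1
  kim_t <- rowSums(adj_t) - 1

  c(meanCor = mean(cor_t[off]),
    meanAdj = mean(adj_t[off]),
    propVarExplained = pve,
    meanKME = mean(kme_t),
    cor_kIM = suppressWarnings(stats::cor(kim_r, kim_t)),
    cor_cor = suppressWarnings(stats::cor(cor_r[off], cor_t[off])),
    cor_kME = suppressWarnings(stats::cor(kme_r, kme_t)))
}

#' @export
print.preservation_stats <- function(x, ...) {
  cat(sprintf(
    "preservation (n=%d genes, %d permutations): Z_summary = %.2f\n",
    x$n_genes, x$n_permutations, x$Z_summary))
  cat(sprintf("  Z_density = %.2f, Z_connectivity = %.2f, band = %s\n",
              x$Z_density, x$Z_connectivity,
              classify_preservation(x)$band))
  invisible(x)
}

#' Classify a preservation score into evidence bands
#'
#' Bands follow the standard interpretation: \code{Z_summary < 2} no
#' evidence, \code{2 < Z_summary < 10} weak-to-moderate, \code{Z_summary >
#' 10} strong. Selection for downstream analysis uses the strict rule
#' \code{Z_summary > select_cut} (default 5), so a score of exactly 5 is
#' not selected.
#'
#' @param stats a \code{\link{preservation_zsummary}} result or a bare
#'   Z_summary value.
#' @param select_cut selection threshold (default 5).
#' @return List with \code{band} (\code{"none"}, \code{"weak_moderate"},
#'   \code{"strong"}), \code{selected} and \code{threshold}.
#' @export
classify_preservation <- function(stats, select_cut = 5) {
  z <- if (inherits(stats, "preservation_stats")) stats$Z_summary else stats
  band <- if (is.na(z)) NA_character_
    else if (z < 2) "none"
    else if (z > 10) "strong"
    else "weak_moderate"
  list(band = band, selected = isTRUE(z > select_cut),
       threshold = select_cut)
}

#' Screen GO terms for cross-cohort preservation
#'
#' Applies \code{\link{preservation_zsummary}} to every term of a
#' (size-filtered) collection with per-term seeds derived from the master
#' seed, and keeps the terms whose \code{Z_summary} exceeds
#' \code{select_cut}.
#'
#' @param collection a \code{\link{gene_set_collection}}.
#' @param train,test \code{\link{expr_cohort}}s.
#' @param select_cut strict selection threshold (default 5).
#' @param n_perm permutations per term (default 200).
#' @param seed master seed; per-term seeds come from
#'   \code{\link{derive_seed}}.
#' @param beta soft-threshold power used in both cohorts (default 6).
#' @return List with \code{selected} (filtered collection) and
#'   \code{stats} (per-term data.frame: term, n_genes, Z_density,
#'   Z_connectivity, Z_summary, band, selected, error).
#' @export
screen_go_terms <- function(collection, train, test, select_cut = 5,
                            n_perm = 200, seed = 1, beta = 6) {
  rows <- list()
  for (nm in names(collection$sets)) {
    res <- tryCatch(
      preservation_zsummary(collection$sets[[nm]], train, test,
                            beta_ref = beta, beta_test = beta,
                            n_perm = n_perm,
                            seed = derive_seed(seed, "term_preservation", nm)),
      error = function(e) e)
    if (inherits(res, "error")) {
      rows[[nm]] <- data.frame(term = nm, n_genes = NA_integer_,
                               Z_density = NA_real_,
                               Z_connectivity = NA_real_,
                               Z_summary = NA_real_, band = NA_character_,
                               selected = FALSE,
                               error = conditionMessage(res),
                               stringsAsFactors = FALSE)
    } else {
      cl <- classify_preservation(res, select_cut)
      rows[[nm]] <- data.frame(term = nm, n_genes = res$n_genes,
                               Z_density = res$Z_density,
                               Z_connectivity = res$Z_connectivity,
                               Z_summary = res$Z_summary, band = cl$band,
                               selected = cl$selected, error = NA_character_,
                               stringsAsFactors = FALSE)
    }
  }
  stats <- do.call(rbind, rows)
  rownames(stats) <- NULL
  keep <- stats$term[stats$selected]
  list(selected = if (length(keep)) collection[keep] else
         structure(list(sets = list(), descriptions = character(),
                        category = collection$category),
                   class = "gene_set_collection"),
       stats = stats)
}
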