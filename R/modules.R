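#' Module eigengene (first principal component)
#'
#' Gene rows are standardized (mean 0, sd 1; missing values imputed to the
#' gene mean) and the first right singular vector over samples is the
#' eigengene, scaled to unit norm. The sign is fixed so the eigengene
#' correlates non-negatively with the module's mean standardized profile.
#'
#' @param term an \code{\link{expr_cohort}} or genes-by-samples matrix.
#' @param genes module member genes.
#' @return List with \code{eigengene} (named unit-norm vector over
#'   samples), \code{weights} (gene loadings defining the component),
#'   \code{variance_explained} (first-eigenvalue fraction).
#' @export
module_eigengene <- function(term, genes = NULL) {
  x <- if (inherits(term, "expr_cohort")) term$values else term
  if (!is.null(genes)) x <- x[genes, , drop = FALSE]
  if (nrow(x) < 2 || ncol(x) < 3)
    stop("eigengene needs >= 2 genes and >= 3 samples")
  z <- standardize_rows(x)
  if (all(z == 0)) stop("constant module: eigengene undefined")
  sv <- svd(z, nu = 1, nv = 1)
  e <- sv$v[, 1]
  w <- sv$u[, 1]
  mean_profile <- colMeans(z)
  s <- stats::cor(e, mean_profile)
  if (!is.na(s) && s < 0) { e <- -e; w <- -w }
  names(e) <- colnames(x)
  names(w) <- rownames(x)
  list(eigengene = e, weights = w,
       variance_explained = sv$d[1]^2 / sum(sv$d^2))
}

#' Module membership (kME)
#'
#' Pearson correlation between each gene's expression and a module
#' eigengene; computable for any term gene, member or not.
#'
#' @param term an \code{\link{expr_cohort}} or genes-by-samples matrix.
#' @param eigengene per-sample eigengene vector (named by sample).
#' @return Named numeric vector of kME per gene (NA for zero-variance
#'   genes).
#' @export
compute_kme <- function(term, eigengene) {
  x <- if (inherits(term, "expr_cohort")) term$values else term
  if (!is.null(names(eigengene))) {
    stopifnot(all(colnames(x) %in% names(eigengene)))
    eigengene <- eigengene[colnames(x)]
  }
  kme <- suppressWarnings(
    stats::cor(t(x), eigengene, use = "pairwise.complete.obs"))[, 1]
  names(kme) <- rownames(x)
  kme
}

#' Detect modules by static-cut scan of the TOM dendrogram
#'
#' Genes are clustered by average-linkage hierarchical clustering on the
#' TOM dissimilarity (1 - TOM). Merge heights are scanned downward from
#' 0.99 of the dendrogram's maximum on a fixed grid (step 0.01); the static
#' cut maximizing the number of clusters with at least
#' \code{min_module_size} genes defines the modules (ties resolve to the
#' highest such cut). All other genes are unassigned ("grey", label 0).
#' Deterministic given its input.
#'
#' @param tom_diss TOM dissimilarity matrix (1 - TOM) with gene dimnames.
#' @param min_module_size minimum module size (default 10).
#' @param grid_step height-grid step (default 0.01).
#' @return Named integer label vector (0 = grey; modules labeled 1..K by
#'   decreasing size) with the \code{hclust} tree as attribute
#'   \code{"dendro"}.
#' @export
detect_modules <- function(tom_diss, min_module_size = 10,
                           grid_step = 0.01) {
  stopifnot(min_module_size >= 2)
  genes <- rownames(tom_diss)
  n <- length(genes)
  labels <- stats::setNames(integer(n), genes)
  if (n < min_module_size) return(labels)
  hc <- stats::hclust(stats::as.dist(tom_diss), method = "average")
  h_max <- max(hc$height)
  heights <- seq(0.99 * h_max, 0, by = -grid_step)
  best_n <- 0L; best_h <- NA_real_
  for (h in heights) {
    cl <- stats::cutree(hc, h = h)
    n_big <- sum(table(cl) >= min_module_size)
    if (n_big > best_n) { best_n <- n_big; best_h <- h }
  }
  if (best_n > 0L) {
    cl <- stats::cutree(hc, h = best_h)
    sizes <- table(cl)
    big <- names(sizes)[sizes >= min_module_size]
    # size-ranked labels; ties by first appearance in the tree order
    big <- big[order(-sizes[big], as.integer(big))]
    for (i in seq_along(big)) labels[cl == as.integer(big[i])] <- i
  }
  attr(labels, "dendro") <- hc
  attr(labels, "cut_height") <- best_h
  labels
}

# build Module records (eigengene, kME, variance explained) for a label set
build_modules <- function(term, labels) {
  x <- if (inherits(term, "expr_cohort")) term$values else term
  mods <- list()
  for (lab in sort(unique(labels[labels > 0]))) {
    genes <- names(labels)[labels == lab]
    eg <- module_eigengene(x, genes)
    kme <- compute_kme(x[genes, , drop = FALSE], eg$eigengene)
    mods[[as.character(lab)]] <- list(
      label = lab, genes = genes, eigengene = eg$eigengene,
      weights = eg$weights, kme = kme,
      variance_explained = eg$variance_explained)
  }
  mods
}

#' Merge modules with correlated eigengenes
#'
#' Average-linkage clustering of module eigengenes on the dissimilarity
#' \code{1 - cor(E_a, E_b)}; branches below \code{cut_height} merge into a
#' single module whose eigengene and kME are recomputed from the gene
#' union. Idempotent at a fixed cut height.
#'
#' @param term expression (\code{\link{expr_cohort}} or matrix).
#' @param labels named integer label vector (0 = grey).
#' @param cut_height merge height (default 0.25, i.e. eigengene
#'   correlation above 0.75 merges).
#' @return Relabeled named integer vector (size-ranked).
#' @export
merge_close_modules <- function(term, labels, cut_height = 0.25) {
  labs <- sort(unique(labels[labels > 0]))
  if (length(labs) < 2 || cut_height <= 0) return(labels)
  mods <- build_modules(term, labels)
  eg <- vapply(mods, `[[`, numeric(length(mods[[1]]$eigengene)), "eigengene")
  diss <- 1 - stats::cor(eg)
  hc <- stats::hclust(stats::as.dist(diss), method = "average")
  grp <- stats::cutree(hc, h = cut_height)
  new_labels <- labels
  for (g in unique(grp)) {
    members <- as.integer(names(grp)[grp == g])
    new_labels[labels %in% members] <- min(members)
  }
  relabel_by_size(new_labels)
}

#' Prune weakly connected genes from modules
#'
#' Genes whose module membership satisfies \code{kME <= kme_cut}
#' (inclusive removal, reproducing the "kME <= 0.3 to grey" rule) are
#' reassigned to grey in a single pass; eigengenes and kME are recomputed
#' once afterwards. Emptied modules are deleted.
#'
#' @param term expression (\code{\link{expr_cohort}} or matrix).
#' @param labels named integer label vector.
#' @param kme_cut inclusive removal threshold (default 0.3).
#' @param kme optional named kME vector overriding the internally computed
#'   module membership (e.g. memberships recomputed elsewhere).
#' @return Pruned, size-ranked label vector.
#' @export
prune_low_kme <- function(term, labels, kme_cut = 0.3, kme = NULL) {
  mods <- build_modules(term, labels)
  new_labels <- labels
  for (m in mods) {
    v <- if (is.null(kme)) m$kme else kme[m$genes]
    drop <- m$genes[is.na(v) | v <= kme_cut]
    new_labels[drop] <- 0L
  }
  relabel_by_size(new_labels)
}

relabel_by_size <- function(labels) {
  out <- stats::setNames(integer(length(labels)), names(labels))
  labs <- labels[labels > 0]
  if (!length(labs)) return(out)
  sizes <- sort(table(labs), decreasing = TRUE)
  for (i in seq_along(sizes))
    out[labels == as.integer(names(sizes)[i])] <- i
  out
}

#' K-means clustering baseline
#'
#' K-means (Euclidean, 10 restarts) on standardized gene profiles with the
#' module count fixed externally (e.g. to the number of modules the
#' network-based fit found for the same term); clusters below
#' \code{min_module_size} become grey.
#'
#' @param term expression (\code{\link{expr_cohort}} or matrix).
#' @param k number of clusters.
#' @param seed integer seed.
#' @param min_module_size clusters below this size become grey.
#' @return Named integer label vector, size-ranked.
#' @export
kmeans_baseline <- function(term, k, seed = 1, min_module_size = 10) {
  x <- if (inherits(term, "expr_cohort")) term$values else term
  if (k < 1 || k > nrow(x)) stop("k must be in [1, n_genes]")
  z <- standardize_rows(x)
  set.seed(seed)
  km <- stats::kmeans(z, centers = k, nstart = 10)
  labels <- stats::setNames(km$cluster, rownames(x))
  sizes <- table(labels)
  labels[labels %in% as.integer(names(sizes)[sizes < min_module_size])] <- 0L
  relabel_by_size(labels)
}

#' Fit co-expression modules to one term's expression matrix
#'
#' The model underlying each module is a one-factor summary: the module
#' eigengene (first principal component of the standardized member-gene
#' profiles) approximates every member gene up to its kME. Fitting runs
#' the full network path: Pearson correlation, soft-threshold adjacency
#' \code{|r|^beta}, topological overlap, average-linkage clustering with a
#' static-cut scan (minimum module size 10), eigengene-correlation merging
#' (cut height 0.25) and single-pass kME pruning (kME <= 0.3 to grey).
#'
#' @param term an \code{\link{expr_cohort}} (phenotype kept for plotting
#'   and trait association) or a genes-by-samples matrix.
#' @param power soft-threshold power (default 6) or \code{"auto"} to select
#'   by scale-free fit.
#' @param min_module_size minimum module size at creation (default 10).
#' @param merge_height eigengene-dissimilarity merge height (default 0.25).
#' @param kme_cut inclusive kME pruning threshold (default 0.3).
#' @param candidate_powers,r2_cut passed to
#'   \code{\link{pick_soft_threshold}} when \code{power = "auto"}.
#' @param term_name optional label stored on the fit.
#' @return An object of class \code{"comod"}: a list with \code{labels}
#'   (named integer vector, 0 = grey), \code{modules} (per-module gene
#'   lists, eigengenes, weights, kME, variance explained), \code{kme}
#'   (genes-by-modules kME matrix over all term genes), \code{power},
#'   \code{dendro}, \code{params}, \code{phenotype} (if available).
#' @examples
#' cfg <- sim_config(n_genes = 120, n_go_terms = 1, go_size_range = c(60, 60),
#'                   planted_modules = list(planted_module(1, size = 15)),
#'                   noise_sd = 0.3, missing_rate = 0, seed = 42)
#' sim <- simulate_cohorts(cfg)
#' tm <- term_expression(sim$train, sim$truth$term_genes[[1]])
#' fit <- fit_modules(tm)
#' fit
#' @export
fit_modules <- function(term, power = 6, min_module_size = 10,
                        merge_height = 0.25, kme_cut = 0.3,
                        candidate_powers = 1:20, r2_cut = 0.80,
                        term_name = NULL) {
  x <- if (inherits(term, "expr_cohort")) term$values else term
  phenotype <- if (inherits(term, "expr_cohort")) term$phenotype else NULL
  r <- suppressWarnings(correlation_matrix(x))
  fallback <- FALSE
  if (identical(power, "auto")) {
    ps <- tryCatch(pick_soft_threshold(r, candidate_powers, r2_cut),
                   warning = function(w) {
                     res <- suppressWarnings(
                       pick_soft_threshold(r, candidate_powers, r2_cut))
                     res$fallback <- TRUE
                     res
                   })
    power <- ps$power
    fallback <- isTRUE(ps$fallback)
  }
  a <- suppressWarnings(adjacency_matrix(r, power))
  tom <- tom_similarity(a)
  labels <- detect_modules(1 - tom, min_module_size)
  dendro <- attr(labels, "dendro")
  labels <- merge_close_modules(x, labels, merge_height)
  labels <- prune_low_kme(x, labels, kme_cut)
  modules <- build_modules(x, labels)
  kme <- if (length(modules)) {
    vapply(modules, function(m) compute_kme(x, m$eigengene),
           numeric(nrow(x)))
  } else matrix(numeric(0), nrow(x), 0, dimnames = list(rownames(x), NULL))
  if (length(modules))
    colnames(kme) <- paste0("M", vapply(modules, `[[`, 0L, "label"))
  structure(list(labels = labels, modules = modules, kme = kme,
                 correlation = r, power = power,
                 power_fallback = fallback, dendro = dendro,
                 term_name = term_name %||% "term",
                 phenotype = phenotype, values = x,
                 params = list(min_module_size = min_module_size,
                               merge_height = merge_height,
                               kme_cut = kme_cut)),
            class = "comod")
}

#' @export
print.comod <- function(x, ...) {
  k <- length(x$modules)
  cat(sprintf("comod fit '%s': %d genes, %d module(s), %d grey\n",
              x$term_name, length(x$labels), k, sum(x$labels == 0)))
  if (k) {
    for (m in x$modules)
      cat(sprintf("  M%d: %d genes, var explained %.2f\n",
                  m$label, length(m$genes), m$variance_explained))
  }
  invisible(x)
}

#' @export
summary.comod <- function(object, ...) {
  rows <- lapply(object$modules, function(m) {
    r <- p <- NA_real_
    if (!is.null(object$phenotype)) {
      ta <- trait_association(m$eigengene, object$phenotype)
      r <- ta$r; p <- ta$p
    }
    data.frame(term = object$term_name, module = paste0("M", m$label),
               size = length(m$genes),
               variance_explained = m$variance_explained,
               mean_kme = mean(m$kme, na.rm = TRUE),
               trait_r = r, trait_p = p, stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(term = character(), module = character(), size = integer(),
               variance_explained = numeric(), mean_kme = numeric(),
               trait_r = numeric(), trait_p = numeric())
  rownames(out) <- NULL
  class(out) <- c("summary.comod", "data.frame")
  out
}

#' @export
coef.comod <- function(object, ...) object$kme

#' Project module eigengenes onto new samples
#'
#' Applies the gene weights that define each module eigengene in the fitted
#' (reference) cohort to new standardized expression, yielding per-sample
#' eigengene scores in the new cohort (unit norm per module). This is how
#' reference-defined eigengenes are evaluated in a testing cohort.
#'
#' @param object a \code{\link{fit_modules}} fit.
#' @param newdata an \code{\link{expr_cohort}} or matrix containing the
#'   module genes.
#' @param ... unused.
#' @return Samples-by-modules matrix of eigengene scores.
#' @export
predict.comod <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$values else
    if (inherits(newdata, "expr_cohort")) newdata$values else newdata
  out <- sapply(object$modules, function(m) {
    project_eigengene(x, m$weights)
  })
  if (!is.matrix(out)) out <- matrix(out, ncol = length(object$modules))
  dimnames(out) <- list(colnames(x),
                        paste0("M", vapply(object$modules, `[[`, 0L, "label")))
  out
}

# score = standardized expression of the weight genes projected on the
# stored loadings, rescaled to unit norm
project_eigengene <- function(x, weights) {
  genes <- names(weights)
  missing <- setdiff(genes, rownames(x))
  if (length(missing))
    stop("newdata lacks module genes: ", paste(missing[1:min(3, length(missing))],
                                               collapse = ", "))
  z <- standardize_rows(x[genes, , drop = FALSE])
  e <- drop(crossprod(z, weights))
  nrm <- sqrt(sum(e^2))
  if (nrm > 0) e <- e / nrm
  stats::setNames(e, colnames(x))
}

#' @export
residuals.comod <- function(object, ...) {
  z <- standardize_rows(object$values)
  for (m in object$modules) {
    e <- m$eigengene
    proj <- z[m$genes, , drop = FALSE] %*% e
    z[m$genes, ] <- z[m$genes, , drop = FALSE] - proj %*% t(e)
  }
  z
}

#' Plot module eigengenes by phenotype
#'
#' Boxplots of each module eigengene split into tumor and control samples
#' (the case/control eigengene view used to inspect disease-associated
#' modules).
#'
#' @param x a \code{\link{fit_modules}} fit with phenotype.
#' @param ... passed to \code{boxplot}.
#' @export
plot.comod <- function(x, ...) {
  if (!length(x$modules)) {
    plot.new(); title("no modules"); return(invisible(x))
  }
  if (is.null(x$phenotype)) stop("fit has no phenotype")
  k <- length(x$modules)
  op <- graphics::par(mfrow = c(1, k))
  on.exit(graphics::par(op))
  for (m in x$modules) {
    graphics::boxplot(m$eigengene ~ factor(x$phenotype,
                                           labels = c("control", "tumor")),
                      main = sprintf("%s M%d", x$term_name, m$label),
                      xlab = "", ylab = "eigengene", ...)
  }
  invisible(x)
}
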