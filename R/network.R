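#' Pairwise Pearson correlation matrix for a term
#'
#' @param term an \code{\link{expr_cohort}} or genes-by-samples matrix.
#' @return Symmetric correlation matrix with unit diagonal; correlations of
#'   zero-variance genes are \code{NA} and flagged via the
#'   \code{"zero_variance"} attribute.
#' @export
correlation_matrix <- function(term) {
  x <- if (inherits(term, "expr_cohort")) term$values else term
  r <- suppressWarnings(stats::cor(t(x), use = "pairwise.complete.obs"))
  diag(r) <- 1
  zv <- rownames(x)[apply(x, 1, function(v) {
    v <- v[!is.na(v)]
    length(v) < 2 || stats::sd(v) == 0
  })]
  if (length(zv)) {
    r[zv, ] <- NA; r[, zv] <- NA
    diag(r) <- 1
    warning(sprintf("%d zero-variance gene(s); correlations set missing",
                    length(zv)))
  }
  attr(r, "zero_variance") <- zv
  r
}

#' Soft-threshold adjacency
#'
#' Unsigned weighted adjacency \code{a_ij = |r_ij|^beta} with unit
#' diagonal. Missing correlations (zero-variance genes) become zero
#' adjacency so term networks keep stable dimensions.
#'
#' @param correlation correlation matrix.
#' @param beta soft-threshold power (>= 1).
#' @return Adjacency matrix in [0, 1].
#' @export
adjacency_matrix <- function(correlation, beta) {
  stopifnot(beta >= 1)
  if (anyNA(correlation))
    warning("missing correlations set to zero adjacency")
  a <- abs(correlation)^beta
  a[is.na(a)] <- 0
  diag(a) <- 1
  a
}

#' Select the soft-threshold power by scale-free topology fit
#'
#' For each candidate power the weighted connectivity
#' \code{k_i = sum_j a_ij (j != i)} is computed, \code{log10(k)} is binned
#' into at most 10 equal-width bins and \code{log10 p(k)} is regressed on
#' \code{log10 mean(k)}; the signed fit index is R^2 with the sign of the
#' slope requirement (negative slope required). The smallest power reaching
#' \code{r2_cut} is returned; if none passes, the power maximizing the
#' signed R^2 is returned with a warning and \code{fallback = TRUE}.
#'
#' @param correlation correlation matrix (>= 10 genes).
#' @param candidate_powers integer powers to scan (default 1:20).
#' @param r2_cut signed R^2 threshold (default 0.80).
#' @return List with \code{power}, \code{fit_table} (power, r2, slope) and
#'   \code{fallback}.
#' @export
pick_soft_threshold <- function(correlation, candidate_powers = 1:20,
                                r2_cut = 0.80) {
  if (nrow(correlation) < 10) stop("need at least 10 genes")
  fits <- t(vapply(candidate_powers, function(b) {
    a <- adjacency_matrix(correlation, b)
    k <- rowSums(a) - 1
    scale_free_fit(k)
  }, c(r2 = 0, slope = 0)))
  tab <- data.frame(power = candidate_powers, r2 = fits[, 1],
                    slope = fits[, 2])
  pass <- which(tab$r2 >= r2_cut)
  if (length(pass)) {
    list(power = candidate_powers[pass[1]], fit_table = tab,
         fallback = FALSE)
  } else {
    warning("no candidate power reaches the scale-free fit threshold; ",
            "using the best-fitting power")
    list(power = candidate_powers[which.max(tab$r2)], fit_table = tab,
         fallback = TRUE)
  }
}

# signed scale-free fit index of a connectivity vector: R^2 of
# log10 p(k) ~ log10 mean(k) over <=10 equal-width bins of log10(k),
# negated when the slope is positive. Bins must be equal-width: with
# equal-count bins p(k) is constant by construction and the regression is
# degenerate.
scale_free_fit <- function(k, n_bins = 10) {
  k <- k[k > 0]
  if (length(unique(k)) < 2) stop("all-constant connectivity")
  n_bins <- min(n_bins, length(unique(k)))
  lk <- log10(k)
  cuts <- seq(min(lk), max(lk), length.out = n_bins + 1)
  bin <- cut(lk, cuts, include.lowest = TRUE)
  p_k <- tapply(k, bin, length) / length(k)
  mean_k <- tapply(k, bin, mean)
  ok <- !is.na(p_k) & p_k > 0 & !is.na(mean_k) & mean_k > 0
  if (sum(ok) < 3) return(c(r2 = 0, slope = 0))
  x <- log10(mean_k[ok]); y <- log10(p_k[ok])
  fit <- stats::lm.fit(cbind(1, x), y)
  ssr <- sum(fit$residuals^2)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - ssr / sst else 0
  slope <- fit$coefficients[2]
  c(r2 = ifelse(slope < 0, r2, -r2), slope = slope)
}

#' Topological overlap matrix
#'
#' \code{TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)} for
#' \code{i != j}, where \code{l_ij = sum_u a_iu a_uj} over \code{u} distinct
#' from both, and \code{k_i} is the connectivity; diagonal is 1. The
#' clustering dissimilarity used downstream is \code{1 - TOM}.
#'
#' @param adjacency adjacency matrix in [0, 1], unit diagonal.
#' @return TOM similarity matrix in [0, 1].
#' @export
tom_similarity <- function(adjacency) {
  n <- nrow(adjacency)
  if (n < 2) stop("TOM undefined for a single gene")
  a0 <- adjacency
  diag(a0) <- 0
  l <- a0 %*% a0            # (i,j) entry sums over u != i, j automatically
  k <- rowSums(a0)
  denom <- outer(k, k, pmin) + 1 - a0
  if (any(denom <= 0)) stop("degenerate TOM denominator")
  tom <- (l + a0) / denom
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adjacency)
  tom
}

#' Write a gene-by-gene similarity matrix as TSV
#'
#' @param m square matrix with gene dimnames.
#' @param path output file.
#' @export
write_similarity <- function(m, path) {
  tab <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
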