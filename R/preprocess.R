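#' Per-sample mean inter-array correlation (IAC)
#'
#' For each sample, the mean of its pairwise Pearson correlations (across
#' genes, pairwise-complete over non-missing values) with all other samples
#' of the same phenotype stratum. Low mean IAC flags outlier arrays.
#'
#' @param cohort an \code{\link{expr_cohort}}.
#' @param group optional phenotype value (0 or 1) to restrict to one
#'   stratum; default computes both strata.
#' @return Named numeric vector of mean IAC per sample (stratified).
#' @export
mean_iac <- function(cohort, group = NULL) {
  ph <- cohort$phenotype
  strata <- if (is.null(group)) sort(unique(ph)) else group
  out <- numeric(0)
  for (g in strata) {
    idx <- which(ph == g)
    if (length(idx) < 3)
      stop("need at least 3 samples per phenotype stratum for IAC")
    cc <- stats::cor(cohort$values[, idx, drop = FALSE],
                     use = "pairwise.complete.obs")
    diag(cc) <- NA
    out <- c(out, rowMeans(cc, na.rm = TRUE))
  }
  out[colnames(cohort$values)[colnames(cohort$values) %in% names(out)]]
}

#' Remove outlier arrays by iterative mean-IAC z-score
#'
#' Within each phenotype stratum, any sample whose mean IAC falls more than
#' \code{z_cut} robust standard deviations (median/MAD z-score) below the
#' stratum center is removed; IAC is recomputed and the rule reapplied
#' until a fixed point. A stratum is never reduced below 3 samples.
#' All-missing samples are removed first as degenerate.
#'
#' @param cohort an \code{\link{expr_cohort}}.
#' @param z_cut positive robust z-score threshold (default 5). The
#'   z-score uses the stratum median and MAD, which resist masking when
#'   several outliers share a stratum; 5 MADs is a conservative "clear
#'   outlier" rule. Well-behaved arrays can reach z of -3 to -4 through
#'   ordinary biological heterogeneity, so smaller cuts trim the normal
#'   left tail.
#' @return A list with the cleaned \code{cohort} and a \code{qc} report
#'   (data.frame of removed sample ids with reason and final mean IAC per
#'   kept sample).
#' @export
remove_outlier_samples <- function(cohort, z_cut = 5) {
  stopifnot(z_cut > 0)
  removed <- data.frame(sample_id = character(), reason = character(),
                        stringsAsFactors = FALSE)
  degenerate <- colnames(cohort$values)[
    colSums(!is.na(cohort$values)) == 0]
  if (length(degenerate)) {
    keep <- setdiff(colnames(cohort$values), degenerate)
    cohort <- expr_cohort(cohort$values[, keep, drop = FALSE],
                          cohort$phenotype[keep])
    removed <- rbind(removed, data.frame(sample_id = degenerate,
                                         reason = "degenerate",
                                         stringsAsFactors = FALSE))
  }
  repeat {
    if (is.infinite(z_cut)) break
    iac <- mean_iac(cohort)
    ph <- cohort$phenotype
    drop <- character()
    for (g in sort(unique(ph))) {
      ids <- names(ph)[ph == g]
      if (length(ids) <= 3) next
      v <- iac[ids]
      # robust z: median/MAD resists masking when several outliers share
      # a stratum (they inflate a plain sd enough to hide each other)
      s <- stats::mad(v)
      if (!is.finite(s) || s == 0) s <- stats::sd(v)
      z <- (v - stats::median(v)) / s
      bad <- ids[!is.na(z) & z < -z_cut]
      # never shrink a stratum below 3; drop worst-first if needed
      if (length(bad) > length(ids) - 3)
        bad <- intersect(ids[order(v)], bad)[seq_len(length(ids) - 3)]
      drop <- c(drop, bad)
    }
    if (!length(drop)) break
    removed <- rbind(removed, data.frame(sample_id = drop,
                                         reason = "low_iac",
                                         stringsAsFactors = FALSE))
    keep <- setdiff(colnames(cohort$values), drop)
    cohort <- expr_cohort(cohort$values[, keep, drop = FALSE],
                          cohort$phenotype[keep])
  }
  list(cohort = cohort,
       qc = list(removed_samples = removed,
                 mean_iac = tryCatch(mean_iac(cohort),
                                     error = function(e) NULL)))
}

#' Quantile-normalize samples
#'
#' Maps every sample's empirical distribution onto the across-sample mean
#' of sorted values, optionally after log2 transformation; ties receive the
#' mean of their quantile targets and missing values stay missing (they are
#' excluded from the reference distribution).
#'
#' @param cohort an \code{\link{expr_cohort}}.
#' @param log2 apply \code{log2} first (requires strictly positive values).
#'   Default \code{FALSE}: input is assumed to be on log scale already.
#' @return The normalized \code{\link{expr_cohort}}.
#' @export
quantile_normalize <- function(cohort, log2 = FALSE) {
  x <- cohort$values
  if (log2) {
    if (any(x <= 0, na.rm = TRUE))
      stop("nonpositive values: cannot log2-transform")
    x <- base::log2(x)
  }
  y <- limma::normalizeQuantiles(x, ties = TRUE)
  dimnames(y) <- dimnames(x)
  expr_cohort(y, cohort$phenotype)
}

#' Remove probes with excessive missingness
#'
#' Probes missing in strictly more than \code{max_missing_frac} of samples
#' are removed (the verbatim "more than 30\%" rule: a probe missing in
#' exactly 30\% of samples is retained).
#'
#' @param cohort an \code{\link{expr_cohort}}.
#' @param max_missing_frac maximum tolerated missing fraction (default
#'   0.30).
#' @return Filtered \code{\link{expr_cohort}}.
#' @export
filter_probes <- function(cohort, max_missing_frac = 0.30) {
  stopifnot(max_missing_frac >= 0, max_missing_frac < 1)
  frac <- rowMeans(is.na(cohort$values))
  subset_genes(cohort, rownames(cohort$values)[frac <= max_missing_frac])
}

#' Collapse probes to genes by highest mean intensity
#'
#' For every gene, the probe with the highest mean intensity across samples
#' (missing values excluded) represents the gene; ties resolve to the
#' lexicographically smallest probe id. Probes absent from the map are
#' dropped.
#'
#' @param cohort an \code{\link{expr_cohort}} with probe-level rows.
#' @param probe2gene named character vector mapping probe id to gene id.
#' @return Gene-level \code{\link{expr_cohort}} plus the collapse map, as a
#'   list \code{(cohort, collapse_map)}.
#' @export
collapse_probes <- function(cohort, probe2gene) {
  if (!length(probe2gene) || is.null(names(probe2gene)))
    stop("probe2gene must be a non-empty named character vector")
  probes <- intersect(rownames(cohort$values), names(probe2gene))
  if (!length(probes)) stop("no probes in common with the map")
  means <- rowMeans(cohort$values[probes, , drop = FALSE], na.rm = TRUE)
  df <- data.frame(probe = probes, gene = probe2gene[probes],
                   mean = means[probes], stringsAsFactors = FALSE)
  df <- df[order(df$gene, -df$mean, df$probe), ]
  pick <- df[!duplicated(df$gene), ]
  x <- cohort$values[pick$probe, , drop = FALSE]
  rownames(x) <- pick$gene
  list(cohort = expr_cohort(x, cohort$phenotype),
       collapse_map = stats::setNames(pick$probe, pick$gene))
}

#' Restrict two cohorts to their shared genes
#'
#' @param train,test gene-level \code{\link{expr_cohort}}s.
#' @return List of both cohorts restricted to the sorted common gene set in
#'   identical order.
#' @export
intersect_genes <- function(train, test) {
  common <- sort(intersect(rownames(train$values), rownames(test$values)))
  if (!length(common)) stop("no genes shared between cohorts")
  list(train = subset_genes(train, common),
       test = subset_genes(test, common))
}

#' Full quality-control pipeline for one cohort
#'
#' Fixed order: outlier-array removal (iterative IAC z-score), quantile
#' normalization, missingness-based probe filtering and, when a probe map is
#' supplied, probe-to-gene collapse.
#'
#' @param cohort an \code{\link{expr_cohort}}.
#' @param iac_z IAC robust z-score cut (default 5).
#' @param max_missing maximum per-probe missing fraction (default 0.30).
#' @param log2 log2-transform before quantile normalization.
#' @param probe2gene optional probe-to-gene map.
#' @return List \code{(cohort, qc)}.
#' @export
preprocess_cohort <- function(cohort, iac_z = 5, max_missing = 0.30,
                              log2 = FALSE, probe2gene = NULL) {
  out <- remove_outlier_samples(cohort, z_cut = iac_z)
  cohort <- quantile_normalize(out$cohort, log2 = log2)
  cohort <- filter_probes(cohort, max_missing)
  qc <- out$qc
  if (!is.null(probe2gene)) {
    cl <- collapse_probes(cohort, probe2gene)
    cohort <- cl$cohort
    qc$collapse_map <- cl$collapse_map
  }
  list(cohort = cohort, qc = qc)
}
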