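#' Pipeline configuration
#'
#' Collects the inputs and every stage parameter of the end-to-end module
#' discovery pipeline, with the defaults used throughout: IAC robust z-cut 5,
#' probe missingness 0.30, term size window 50-500, term and module
#' preservation selection Z_summary > 5, minimum module size 10, merge
#' height 0.25, kME pruning 0.3, trait FDR 0.05, evidence-enrichment FDR
#' 0.05 in >= 2 categories, regulator FDR 0.01 (min overlap 2, top 5),
#' 200 permutations.
#'
#' @param train,test \code{\link{expr_cohort}}s (or paths via
#'   \code{\link{read_pipeline_config}}).
#' @param go_bp,evidence,regulators \code{\link{gene_set_collection}}s;
#'   \code{evidence} holds the five candidate-gene categories,
#'   \code{regulators} the TF/miRNA target sets (optional).
#' @param iac_z,max_missing,go_min,go_max,term_select_cut,min_module_size
#'   stage parameters (see description).
#' @param merge_height,kme_cut,trait_fdr,module_select_cut,enrich_fdr
#'   stage parameters.
#' @param min_categories,enrich_rule,alpha_merge,regulator_fdr stage
#'   parameters.
#' @param power soft-threshold power (default 6) or \code{"auto"}.
#' @param n_perm permutations per preservation evaluation.
#' @param seed master seed; every stage seed is derived from it.
#' @param log2 log2-transform expression during QC.
#' @return A list of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(train, test, go_bp, evidence,
                            regulators = NULL,
                            iac_z = 5, max_missing = 0.30,
                            go_min = 50, go_max = 500,
                            term_select_cut = 5, min_module_size = 10,
                            merge_height = 0.25, kme_cut = 0.3,
                            trait_fdr = 0.05, module_select_cut = 5,
                            enrich_fdr = 0.05, min_categories = 2,
                            enrich_rule = "min_categories",
                            alpha_merge = 0.01, regulator_fdr = 0.01,
                            power = 6, n_perm = 200, seed = 1,
                            log2 = FALSE) {
  if (go_min > go_max) stop("go_min must not exceed go_max")
  stopifnot(max_missing >= 0, max_missing < 1, iac_z > 0,
            min_module_size >= 2, merge_height >= 0,
            trait_fdr > 0, trait_fdr <= 1, enrich_fdr > 0, enrich_fdr <= 1,
            regulator_fdr > 0, regulator_fdr <= 1, n_perm >= 50)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Build a pipeline configuration from a YAML file
#'
#' The YAML lists input paths (\code{train_expression},
#' \code{train_phenotype}, \code{test_expression}, \code{test_phenotype},
#' \code{go_bp_gmt}, \code{evidence_gmt}, optional \code{regulators_gmt})
#' plus any \code{\link{pipeline_config}} parameter overrides under
#' \code{params}.
#'
#' @param path YAML file path.
#' @return A \code{\link{pipeline_config}}.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  need <- c("train_expression", "train_phenotype", "test_expression",
            "test_phenotype", "go_bp_gmt", "evidence_gmt")
  miss <- setdiff(need, names(y))
  if (length(miss)) stop("config missing entries: ",
                         paste(miss, collapse = ", "))
  for (f in c(need, if (!is.null(y$regulators_gmt)) "regulators_gmt"))
    if (!file.exists(y[[f]])) stop("no such file: ", y[[f]])
  args <- c(list(
    train = read_expression(y$train_expression, y$train_phenotype),
    test = read_expression(y$test_expression, y$test_phenotype),
    go_bp = read_gmt(y$go_bp_gmt, "go_bp"),
    evidence = read_gmt(y$evidence_gmt, "evidence"),
    regulators = if (!is.null(y$regulators_gmt))
      read_gmt(y$regulators_gmt, "regulator")),
    y$params %||% list())
  do.call(pipeline_config, args)
}

#' Run the full module discovery pipeline
#'
#' Executes, in order: per-cohort QC (outlier arrays, quantile
#' normalization, probe filter), gene intersection, GO-term size filter,
#' term preservation screen (Z_summary > cut), per-term network and module
#' fitting, eigengene-trait association with joint BH-FDR, module
#' preservation in the testing cohort, multi-evidence hypergeometric
#' enrichment and candidate calling, Fisher merging of overlapping
#' candidates (enrichment recomputed on unions), and regulator enrichment.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @param out_dir optional directory: every intermediate table is written
#'   as TSV and stage results are cached (\code{resume = TRUE} reuses
#'   caches).
#' @param resume reuse cached stage results found in \code{out_dir}.
#' @return Object of class \code{"comod_run"}: \code{manifest} (funnel
#'   counts, seeds, warnings, config snapshot), \code{term_stats},
#'   \code{fits}, \code{trait_table}, \code{module_preservation},
#'   \code{enrichment_table}, \code{candidate_table},
#'   \code{regulator_table}, \code{modules} (gene sets of all detected
#'   modules), \code{candidates} (merged candidate gene sets),
#'   \code{train}, \code{test} (post-QC cohorts).
#' @export
run_pipeline <- function(config, out_dir = NULL, resume = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  warnings_log <- character()
  cache_path <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    cache_path <- file.path(out_dir, "stage_cache.rds")
  }
  cache <- if (resume && !is.null(cache_path) && file.exists(cache_path))
    readRDS(cache_path) else list()
  save_cache <- function() if (!is.null(cache_path))
    saveRDS(cache, cache_path)
  stage <- function(name, fun) {
    if (!is.null(cache[[name]])) return(cache[[name]])
    res <- tryCatch(fun(), error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    cache[[name]] <<- res
    save_cache()
    res
  }

  qc <- stage("qc", function() {
    tr <- preprocess_cohort(config$train, iac_z = config$iac_z,
                            max_missing = config$max_missing,
                            log2 = config$log2)
    te <- preprocess_cohort(config$test, iac_z = config$iac_z,
                            max_missing = config$max_missing,
                            log2 = config$log2)
    both <- intersect_genes(tr$cohort, te$cohort)
    list(train = both$train, test = both$test,
         qc_train = tr$qc, qc_test = te$qc)
  })
  universe <- rownames(qc$train$values)

  terms <- stage("terms", function()
    filter_by_size(config$go_bp, universe, config$go_min, config$go_max))

  screen <- stage("screen", function()
    screen_go_terms(terms, qc$train, qc$test,
                    select_cut = config$term_select_cut,
                    n_perm = config$n_perm, seed = config$seed,
                    beta = if (identical(config$power, "auto")) 6 else
                      config$power))

  fits <- stage("fits", function() {
    out <- list()
    for (nm in names(screen$selected$sets)) {
      tm <- term_expression(qc$train, screen$selected$sets[[nm]])
      out[[nm]] <- fit_modules(tm, power = config$power,
                               min_module_size = config$min_module_size,
                               merge_height = config$merge_height,
                               kme_cut = config$kme_cut, term_name = nm)
    }
    out
  })
  for (f in fits)
    if (isTRUE(f$power_fallback))
      warnings_log <- c(warnings_log,
                        sprintf("power fallback in term %s", f$term_name))

  modules <- list()   # module id -> gene set
  eigengenes <- list()
  for (f in fits) {
    for (m in f$modules) {
      id <- sprintf("%s.M%d", f$term_name, m$label)
      modules[[id]] <- m$genes
      eigengenes[[id]] <- m$eigengene
    }
  }

  trait_table <- stage("trait", function() {
    if (!length(modules))
      return(data.frame(module = character(), term = character(),
                        size = integer(), r = numeric(), p = numeric(),
                        fdr = numeric(), stringsAsFactors = FALSE))
    rows <- lapply(names(modules), function(id) {
      ta <- trait_association(eigengenes[[id]], qc$train$phenotype)
      data.frame(module = id, term = sub("\\.M\\d+$", "", id),
                 size = length(modules[[id]]), r = ta$r, p = ta$p,
                 stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    tab$fdr <- bh_fdr(tab$p)   # joint BH over all detected modules
    tab
  })
  trait_sig <- trait_table$module[trait_table$fdr < config$trait_fdr]

  preservation <- stage("module_preservation", function() {
    rows <- list()
    for (id in trait_sig) {
      res <- tryCatch(
        preservation_zsummary(
          modules[[id]], qc$train, qc$test,
          beta_ref = if (identical(config$power, "auto")) 6 else config$power,
          beta_test = if (identical(config$power, "auto")) 6 else config$power,
          n_perm = config$n_perm,
          seed = derive_seed(config$seed, "module_preservation", id)),
        error = function(e) e)
      rows[[id]] <- if (inherits(res, "error")) {
        data.frame(module = id, Z_summary = NA_real_, band = NA_character_,
                   preserved = FALSE, error = conditionMessage(res),
                   stringsAsFactors = FALSE)
      } else {
        cl <- classify_preservation(res, config$module_select_cut)
        data.frame(module = id, Z_summary = res$Z_summary, band = cl$band,
                   preserved = cl$selected, error = NA_character_,
                   stringsAsFactors = FALSE)
      }
    }
    tab <- do.call(rbind, rows) %||%
      data.frame(module = character(), Z_summary = numeric(),
                 band = character(), preserved = logical(),
                 error = character(), stringsAsFactors = FALSE)
    rownames(tab) <- NULL
    tab
  })
  preserved <- preservation$module[preservation$preserved]

  categories <- names(config$evidence$sets)
  enrich_modules <- function(module_sets) {
    rows <- list()
    for (id in names(module_sets)) for (cat in categories) {
      er <- hypergeometric_enrichment(module_sets[[id]],
                                      config$evidence$sets[[cat]], universe)
      rows[[paste(id, cat)]] <- data.frame(
        module = id, category = cat, k = er$k, m = er$m, K = er$K,
        N = er$N, p = er$p,
        overlap_genes = paste(sort(er$overlap_genes), collapse = ","),
        stringsAsFactors = FALSE)
    }
    tab <- do.call(rbind, rows) %||%
      data.frame(module = character(), category = character(),
                 k = integer(), m = integer(), K = integer(), N = integer(),
                 p = numeric(), overlap_genes = character(),
                 stringsAsFactors = FALSE)
    rownames(tab) <- NULL
    if (nrow(tab)) tab$fdr <- bh_fdr(tab$p)  # one batch: module x category
    else tab$fdr <- numeric(0)
    tab
  }

  enrichment_table <- stage("enrichment", function()
    enrich_modules(modules[preserved]))
  calls <- if (nrow(enrichment_table))
    call_candidates(enrichment_table, fdr_cut = config$enrich_fdr,
                    min_categories = config$min_categories,
                    rule = config$enrich_rule)
  else data.frame(module = character(), candidate = logical())
  candidate_ids <- calls$module[calls$candidate]

  merged <- stage("merge", function()
    merge_overlapping_candidates(modules[candidate_ids], universe,
                                 alpha = config$alpha_merge))

  candidate_table <- stage("candidates", function() {
    if (!length(merged$merged))
      return(data.frame(module = character(), description = character(),
                        size = integer(), p_cor = numeric(),
                        Z_summary = numeric(), stringsAsFactors = FALSE))
    en <- enrich_modules(merged$merged)
    rows <- lapply(names(merged$merged), function(id) {
      genes <- merged$merged[[id]]
      eg <- module_eigengene(qc$train, genes)
      ta <- trait_association(eg$eigengene, qc$train$phenotype)
      pz <- preservation_zsummary(
        genes, qc$train, qc$test,
        beta_ref = if (identical(config$power, "auto")) 6 else config$power,
        beta_test = if (identical(config$power, "auto")) 6 else config$power,
        n_perm = config$n_perm,
        seed = derive_seed(config$seed, "candidate_preservation", id))
      row <- data.frame(module = id,
                        description = paste(sort(unique(sub(
                          "\\.M\\d+$", "", strsplit(id, "+",
                                                    fixed = TRUE)[[1]]))),
                          collapse = ";"),
                        size = length(genes), p_cor = ta$p,
                        Z_summary = pz$Z_summary,
                        stringsAsFactors = FALSE)
      for (cat in categories) {
        e <- en[en$module == id & en$category == cat, ]
        row[[paste0(cat, "_k")]] <- e$k
        row[[paste0(cat, "_fdr")]] <- e$fdr
      }
      row
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })

  regulator_table <- stage("regulators", function() {
    if (is.null(config$regulators) || !length(merged$merged))
      return(data.frame(module = character(), regulator = character(),
                        k = integer(), K = integer(), p = numeric(),
                        fdr = numeric(), overlap_genes = character(),
                        stringsAsFactors = FALSE))
    rows <- lapply(names(merged$merged), function(id) {
      tab <- regulator_enrichment(merged$merged[[id]], config$regulators,
                                  universe, fdr_cut = config$regulator_fdr)
      if (nrow(tab)) cbind(module = id, tab, stringsAsFactors = FALSE)
      else NULL
    })
    out <- do.call(rbind, rows) %||%
      data.frame(module = character(), regulator = character(),
                 k = integer(), K = integer(), p = numeric(),
                 fdr = numeric(), overlap_genes = character(),
                 stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
  })

  manifest <- list(
    version = as.character(utils::packageVersion("comod")),
    seed = config$seed,
    started = format(t0), finished = format(Sys.time()),
    counts = list(
      samples_train = ncol(qc$train$values),
      samples_test = ncol(qc$test$values),
      genes_shared = length(universe),
      terms_input = length(config$go_bp$sets),
      terms_size_filtered = length(terms$sets),
      terms_preserved = length(screen$selected$sets),
      modules_detected = length(modules),
      modules_trait_significant = length(trait_sig),
      modules_preserved = length(preserved),
      candidates_premerge = length(candidate_ids),
      candidates = length(merged$merged)),
    warnings = warnings_log,
    params = unclass(config)[setdiff(names(config),
                                     c("train", "test", "go_bp",
                                       "evidence", "regulators"))])

  run <- structure(list(
    manifest = manifest, term_stats = screen$stats, fits = fits,
    trait_table = trait_table, module_preservation = preservation,
    enrichment_table = enrichment_table, candidate_calls = calls,
    candidate_table = candidate_table, regulator_table = regulator_table,
    modules = modules, candidates = merged$merged,
    eigengenes = eigengenes,
    train = qc$train, test = qc$test), class = "comod_run")

  if (!is.null(out_dir)) write_run_tables(run, out_dir)
  run
}

write_run_tables <- function(run, out_dir) {
  wt <- function(x, f) utils::write.table(
    x, file.path(out_dir, f), sep = "\t", quote = FALSE,
    row.names = FALSE)
  wt(run$term_stats, "term_preservation.tsv")
  wt(run$trait_table, "trait_association.tsv")
  wt(run$module_preservation, "module_preservation.tsv")
  wt(run$enrichment_table, "evidence_enrichment.tsv")
  if (nrow(run$candidate_table)) wt(run$candidate_table, "candidates.tsv")
  if (nrow(run$regulator_table)) wt(run$regulator_table, "regulators.tsv")
  mod_rows <- list()
  for (f in run$fits) for (m in f$modules)
    mod_rows[[sprintf("%s.M%d", f$term_name, m$label)]] <- data.frame(
      term = f$term_name, module = sprintf("M%d", m$label),
      gene = m$genes, kme = unname(m$kme[m$genes]),
      stringsAsFactors = FALSE)
  if (length(mod_rows)) wt(do.call(rbind, mod_rows), "module_genes.tsv")
  jsonlite::write_json(run$manifest,
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.comod_run <- function(x, ...) {
  cnt <- x$manifest$counts
  cat("comod pipeline run\n")
  cat(sprintf("  shared genes: %d (train %d / test %d samples)\n",
              cnt$genes_shared, cnt$samples_train, cnt$samples_test))
  cat(sprintf("  terms: %d input -> %d size-eligible -> %d preserved (Z_summary screen)\n",
              cnt$terms_input, cnt$terms_size_filtered,
              cnt$terms_preserved))
  cat(sprintf("  modules: %d detected -> %d trait-significant -> %d preserved -> %d candidate(s)\n",
              cnt$modules_detected, cnt$modules_trait_significant,
              cnt$modules_preserved, cnt$candidates))
  if (length(x$candidates))
    cat("  candidates:", paste(names(x$candidates), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.comod_run <- function(object, ...) object$candidate_table

#' Export a module's network as ranked node and edge lists
#'
#' Nodes are ranked by kME (descending); edges keep gene pairs with
#' \code{|r| > threshold}, weighted by \code{|r|}. Optionally written as
#' TSV edge list and GraphML.
#'
#' @param module_genes module member genes.
#' @param correlation correlation matrix covering the module genes.
#' @param kme named kME vector covering the module genes.
#' @param threshold edge threshold on \code{|r|}, in [0, 1).
#' @param path_prefix optional path prefix; writes
#'   \code{<prefix>_nodes.tsv}, \code{<prefix>_edges.tsv} and
#'   \code{<prefix>.graphml}.
#' @return List with \code{nodes} and \code{edges} data.frames.
#' @export
export_module_network <- function(module_genes, correlation, kme,
                                  threshold = 0, path_prefix = NULL) {
  stopifnot(threshold >= 0, threshold < 1)
  g <- module_genes
  nodes <- data.frame(gene = g, kme = unname(kme[g]),
                      stringsAsFactors = FALSE)
  nodes <- nodes[order(-nodes$kme, nodes$gene), ]
  rownames(nodes) <- NULL
  r <- correlation[g, g, drop = FALSE]
  idx <- which(lower.tri(r) & abs(r) > threshold, arr.ind = TRUE)
  edges <- data.frame(from = g[idx[, "row"]], to = g[idx[, "col"]],
                      weight = abs(r[idx]), stringsAsFactors = FALSE)
  if (!is.null(path_prefix)) {
    utils::write.table(nodes, paste0(path_prefix, "_nodes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(edges, paste0(path_prefix, "_edges.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    gr <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                        vertices = nodes)
    igraph::write_graph(gr, paste0(path_prefix, ".graphml"),
                        format = "graphml")
  }
  list(nodes = nodes, edges = edges)
}

#' Export candidate eigengene profiles in long format
#'
#' One row per (module, sample) with phenotype and eigengene value — the
#' table behind case/control eigengene plots.
#'
#' @param eigengenes named list of per-sample eigengene vectors.
#' @param phenotype named binary phenotype vector.
#' @param path optional TSV output path.
#' @return data.frame: module, sample, phenotype, eigengene.
#' @export
export_eigengene_profiles <- function(eigengenes, phenotype, path = NULL) {
  rows <- lapply(names(eigengenes), function(id) {
    e <- eigengenes[[id]]
    data.frame(module = id, sample = names(e),
               phenotype = unname(phenotype[names(e)]),
               eigengene = unname(e), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows) %||%
    data.frame(module = character(), sample = character(),
               phenotype = integer(), eigengene = numeric())
  rownames(out) <- NULL
  if (!is.null(path))
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  out
}
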