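test_that("mean IAC matches a brute-force double loop over sample pairs", {
  co <- small_cohort(n_genes = 15, n_case = 5, n_ctrl = 5, seed = 2)
  co$values[1, 2] <- NA   # exercise pairwise-complete handling
  iac <- mean_iac(co)
  ph <- co$phenotype
  for (s in colnames(co$values)) {
    peers <- setdiff(names(ph)[ph == ph[s]], s)
    vals <- vapply(peers, function(t)
      stats::cor(co$values[, s], co$values[, t],
                 use = "pairwise.complete.obs"), 0)
    expect_equal(unname(iac[s]), mean(vals), tolerance = 1e-12)
  }
})

test_that("duplicated samples contribute a perfect correlation to each other's IAC", {
  co <- small_cohort(n_genes = 20, n_case = 3, n_ctrl = 3, seed = 3)
  co$values[, "s02"] <- co$values[, "s01"]
  iac <- mean_iac(co, group = 1)
  solo <- stats::cor(co$values[, "s01"], co$values[, "s03"])
  expect_equal(unname(iac["s01"]), mean(c(1, solo)), tolerance = 1e-12)
})

test_that("injected outlier arrays have the lowest IAC of their stratum and are removed exactly", {
  for (s in 1:20) {
    cfg <- sim_config(n_genes = 800, planted_modules = list(),
                      n_outliers = 2, seed = s)
    sim <- simulate_cohorts(cfg)
    iac <- mean_iac(sim$train)
    ph <- sim$train$phenotype
    for (o in sim$truth$outliers_train) {
      stratum <- names(ph)[ph == ph[o]]
      n_out <- sum(sim$truth$outliers_train %in% stratum)
      expect_lte(rank(iac[stratum])[o], n_out)
    }
    out <- remove_outlier_samples(sim$train)
    expect_setequal(out$qc$removed_samples$sample_id,
                    sim$truth$outliers_train)
  }
})

test_that("outlier removal is the identity on clean data and at an infinite cut", {
  co <- small_cohort(n_genes = 40, n_case = 6, n_ctrl = 6, seed = 5)
  out <- remove_outlier_samples(co)
  expect_identical(colnames(out$cohort$values), colnames(co$values))
  expect_identical(nrow(out$qc$removed_samples), 0L)
  expect_identical(
    colnames(remove_outlier_samples(co, z_cut = Inf)$cohort$values),
    colnames(co$values))
})

test_that("all-missing samples are removed as degenerate", {
  co <- small_cohort(n_genes = 30, n_case = 5, n_ctrl = 5, seed = 6)
  co$values[, "s01"] <- NA_real_
  out <- remove_outlier_samples(co)
  rem <- out$qc$removed_samples
  expect_true("s01" %in% rem$sample_id)
  expect_identical(rem$reason[rem$sample_id == "s01"], "degenerate")
})

test_that("quantile normalization maps columns onto the mean sorted profile", {
  # hand-computed 3x3 reference: sorted columns are (2,4,6), (1,5,9),
  # (3,4,8); their elementwise mean is (2, 13/3, 23/3)
  x <- matrix(c(2, 4, 6, 9, 5, 1, 4, 3, 8), 3, 3,
              dimnames = list(paste0("g", 1:3), paste0("s", 1:3)))
  co <- expr_cohort(x, c(1L, 1L, 0L))
  qn <- quantile_normalize(co)$values
  ref <- c(2, 13 / 3, 23 / 3)
  expect_equal(unname(qn[, 1]), ref, tolerance = 1e-12)           # 2,4,6
  expect_equal(unname(qn[, 2]), rev(ref), tolerance = 1e-12)      # 9,5,1
  expect_equal(unname(qn[, 3]), ref[c(2, 1, 3)], tolerance = 1e-12)
})

test_that("quantile normalization is idempotent and equalizes sorted columns", {
  co <- small_cohort(n_genes = 50, n_case = 4, n_ctrl = 4, seed = 7)
  qn <- quantile_normalize(co)
  sorted <- apply(qn$values, 2, sort)
  expect_lt(max(abs(sorted - sorted[, 1])), 1e-12)
  qn2 <- quantile_normalize(qn)
  expect_equal(qn2$values, qn$values, tolerance = 1e-12)
  # already-identical columns are a fixed point
  same <- expr_cohort(matrix(rep(1:5, 3), 5, 3,
                             dimnames = list(paste0("g", 1:5),
                                             paste0("s", 1:3))),
                      c(1L, 1L, 0L))
  expect_equal(quantile_normalize(same)$values, same$values,
               tolerance = 1e-12)
})

test_that("log2 transform rejects nonpositive values", {
  co <- small_cohort(seed = 8)
  co$values[1, 1] <- -1
  expect_error(quantile_normalize(co, log2 = TRUE), "nonpositive")
})

test_that("probe missingness filter uses the strict more-than boundary", {
  n <- 100
  x <- matrix(stats::rnorm(3 * n), 3, n,
              dimnames = list(c("p30", "p31", "p00"), paste0("s", 1:n)))
  x["p30", 1:30] <- NA   # exactly 30%: retained
  x["p31", 1:31] <- NA   # more than 30%: removed
  co <- expr_cohort(x, rep(c(1L, 0L), c(50, 50)))
  kept <- rownames(filter_probes(co, 0.30)$values)
  expect_true("p30" %in% kept)
  expect_false("p31" %in% kept)
  expect_true("p00" %in% kept)
  # fully observed matrix is untouched
  full <- small_cohort(seed = 9)
  expect_identical(rownames(filter_probes(full)$values),
                   rownames(full$values))
})

test_that("probe collapse keeps the highest-mean probe per gene", {
  set.seed(10)
  x <- matrix(stats::rnorm(6 * 4), 6, 4,
              dimnames = list(paste0("p", 1:6), paste0("s", 1:4)))
  x["p1", ] <- x["p1", ] + 7.1
  x["p2", ] <- x["p2", ] + 9.3
  map <- c(p1 = "gA", p2 = "gA", p3 = "gB", p4 = "gB", p5 = "gB",
           p6 = "gC")
  co <- expr_cohort(x, c(1L, 1L, 0L, 0L))
  res <- collapse_probes(co, map)
  expect_identical(unname(res$collapse_map["gA"]), "p2")
  # brute-force max-by-group oracle
  means <- rowMeans(x)
  for (g in unique(map)) {
    probes <- names(map)[map == g]
    best <- probes[order(-means[probes], probes)][1]
    expect_identical(unname(res$collapse_map[g]), best)
    expect_equal(res$cohort$values[g, ], x[best, ], tolerance = 1e-12)
  }
  expect_error(collapse_probes(co, character()), "non-empty")
})

test_that("probe collapse breaks exact ties lexicographically", {
  x <- matrix(5, 2, 3, dimnames = list(c("pB", "pA"), paste0("s", 1:3)))
  co <- expr_cohort(x, c(1L, 0L, 0L))
  res <- collapse_probes(co, c(pB = "g1", pA = "g1"))
  expect_identical(unname(res$collapse_map["g1"]), "pA")
})

test_that("gene intersection restricts both cohorts to the sorted shared set", {
  a <- small_cohort(n_genes = 10, seed = 11)
  b <- small_cohort(n_genes = 10, seed = 12)
  rownames(b$values) <- c(sprintf("g%02d", 6:10), sprintf("x%02d", 1:5))
  both <- intersect_genes(a, b)
  expect_identical(rownames(both$train$values), sprintf("g%02d", 6:10))
  expect_identical(rownames(both$train$values), rownames(both$test$values))
  expect_identical(intersect_genes(a, a)$train$values, a$values)
  rownames(b$values) <- sprintf("y%02d", 1:10)
  expect_error(intersect_genes(a, b), "shared")
})

test_that("QC pipeline preserves sample identity and phenotype alignment", {
  cfg <- sim_config(n_genes = 300, planted_modules = list(), n_outliers = 1,
                    missing_rate = 0.05, seed = 13)
  sim <- simulate_cohorts(cfg)
  out <- preprocess_cohort(sim$train)
  kept <- colnames(out$cohort$values)
  expect_identical(out$cohort$phenotype[kept], sim$train$phenotype[kept])
  expect_length(intersect(out$qc$removed_samples$sample_id, kept), 0)
})
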