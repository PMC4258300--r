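fit_labels <- function(x, min_size = 10, power = 6) {
  r <- suppressWarnings(correlation_matrix(x))
  tom <- tom_similarity(suppressWarnings(adjacency_matrix(r, power)))
  detect_modules(1 - tom, min_size)
}

test_that("noise-free planted modules are recovered exactly", {
  cfg <- sim_config(n_genes = 80, n_go_terms = 1, go_size_range = c(40, 40),
                    planted_modules = list(
                      planted_module(1, size = 15, loading = 0.8),
                      planted_module(1, size = 15, loading = 0.6)),
                    noise_sd = 0, missing_rate = 0, seed = 41)
  sim <- simulate_cohorts(cfg)
  tm <- term_expression(sim$train, sim$truth$term_genes[[1]])
  labels <- fit_labels(tm$values)
  mods <- split(names(labels)[labels > 0], labels[labels > 0])
  expect_length(mods, 2)
  j1 <- max(vapply(mods, jaccard, 0, b = sim$truth$module_genes_train[[1]]))
  j2 <- max(vapply(mods, jaccard, 0, b = sim$truth$module_genes_train[[2]]))
  expect_equal(j1, 1)
  expect_equal(j2, 1)
})

test_that("pure-noise terms stay grey in at least 18 of 20 seeds", {
  grey <- 0
  for (s in 1:20) {
    set.seed(400 + s)
    x <- matrix(stats::rnorm(60 * 40), 60, 40,
                dimnames = list(paste0("g", 1:60), paste0("s", 1:40)))
    labels <- fit_labels(x)
    if (all(labels == 0)) grey <- grey + 1
  }
  expect_gte(grey, 18)
})

test_that("clusters below the minimum module size are left grey", {
  x <- factor_matrix(block_sizes = c(12, 9), n_noise = 0, n_samples = 30,
                     loading = 1, noise_sd = 0.03, seed = 42)
  labels <- fit_labels(x)
  sizes <- table(labels[labels > 0])
  expect_identical(length(sizes), 1L)
  expect_identical(unname(sizes[1]), 12L)   # the 9-gene cluster stays grey
})

test_that("module detection is deterministic", {
  set.seed(43)
  x <- factor_matrix(c(15), 20, 30, loading = 0.9, noise_sd = 0.5)
  expect_identical(fit_labels(x), fit_labels(x))
})

test_that("eigengene equals the explicit covariance eigen-decomposition", {
  set.seed(44)
  x <- matrix(stats::rnorm(5 * 14), 5, 14,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:14)))
  eg <- module_eigengene(x)
  # oracle: eigenvectors of the samples x samples inner-product matrix of
  # standardized rows
  z <- t(scale(t(x)))
  ev <- eigen(crossprod(z))
  e1 <- ev$vectors[, 1]
  if (stats::cor(e1, colMeans(z)) < 0) e1 <- -e1
  expect_equal(unname(eg$eigengene), e1, tolerance = 1e-8)
  expect_equal(eg$variance_explained, ev$values[1] / sum(ev$values),
               tolerance = 1e-10)
  expect_equal(sum(eg$eigengene^2), 1, tolerance = 1e-12)
})

test_that("eigengene sign convention survives global negation and degenerate modules error", {
  set.seed(45)
  x <- matrix(stats::rnorm(6 * 12), 6, 12,
              dimnames = list(paste0("g", 1:6), paste0("s", 1:12)))
  e_pos <- module_eigengene(x)$eigengene
  e_neg <- module_eigengene(-x)$eigengene
  z <- t(scale(t(x)))
  expect_gte(stats::cor(e_pos, colMeans(z)), 0)
  expect_gte(stats::cor(e_neg, colMeans(t(scale(t(-x))))), 0)
  # module of identical genes: eigengene is the standardized profile itself
  same <- matrix(rep(x[1, ], 4), 4, byrow = TRUE,
                 dimnames = list(paste0("g", 1:4), colnames(x)))
  eg <- module_eigengene(same)
  prof <- scale(x[1, ])[, 1]
  expect_equal(abs(stats::cor(eg$eigengene, prof)), 1, tolerance = 1e-10)
  expect_equal(eg$variance_explained, 1, tolerance = 1e-10)
  expect_error(module_eigengene(matrix(1, 3, 5,
                                       dimnames = list(letters[1:3],
                                                       LETTERS[1:5]))),
               "constant")
})

test_that("kME is the gene-eigengene correlation, with the eigengene itself at 1", {
  set.seed(46)
  x <- factor_matrix(c(10), 5, 20, loading = 0.9, noise_sd = 0.3)
  eg <- module_eigengene(x, rownames(x)[1:10])
  kme <- compute_kme(x, eg$eigengene)
  for (g in rownames(x))
    expect_equal(unname(kme[g]), stats::cor(x[g, ], eg$eigengene),
                 tolerance = 1e-12)
  withE <- rbind(x, E = eg$eigengene)
  expect_equal(unname(compute_kme(withE, eg$eigengene)["E"]), 1,
               tolerance = 1e-12)
  # noise-free module: member kME is 1 up to numerical tolerance
  y <- factor_matrix(c(10), 0, 20, loading = 1, noise_sd = 0)
  egy <- module_eigengene(y)
  expect_equal(unname(compute_kme(y, egy$eigengene)), rep(1, 10),
               tolerance = 1e-6)
})

test_that("kME pruning removes at the inclusive 0.3 boundary", {
  set.seed(47)
  x <- factor_matrix(c(12), 0, 20, loading = 0.9, noise_sd = 0.4)
  labels <- stats::setNames(rep(1L, 12), rownames(x))
  kme <- stats::setNames(c(0.3, 0.31, rep(0.9, 10)), rownames(x))
  pruned <- prune_low_kme(x, labels, kme_cut = 0.3, kme = kme)
  expect_identical(unname(pruned["g001"]), 0L)   # kME = 0.30: removed
  expect_identical(unname(pruned["g002"]), 1L)   # kME = 0.31: retained
})

test_that("pruning empties all-noise modules and keeps only strong members", {
  set.seed(48)
  x <- matrix(stats::rnorm(15 * 30), 15, 30,
              dimnames = list(paste0("g", 1:15), paste0("s", 1:30)))
  labels <- stats::setNames(rep(1L, 15), rownames(x))
  pruned <- prune_low_kme(x, labels, kme_cut = 0.95)
  expect_true(all(pruned == 0))
  # after default pruning every surviving member exceeds the cut
  y <- factor_matrix(c(20), 0, 30, loading = 0.7, noise_sd = 0.8, seed = 2)
  lab <- stats::setNames(rep(1L, 20), rownames(y))
  kept <- prune_low_kme(y, lab, kme_cut = 0.3)
  if (any(kept > 0)) {
    eg <- module_eigengene(y, names(kept)[kept > 0])
    kme <- compute_kme(y[names(kept)[kept > 0], , drop = FALSE],
                       eg$eigengene)
    expect_true(all(kme > 0.3))
  }
})

test_that("eigengene-based merging joins duplicated factors and spares orthogonal ones", {
  set.seed(49)
  n_s <- 24
  f1 <- stats::rnorm(n_s)
  f2 <- stats::rnorm(n_s)
  f2 <- stats::residuals(stats::lm(f2 ~ f1))   # exactly orthogonal
  x <- rbind(matrix(rep(f1, each = 10), 10, byrow = FALSE) +
               matrix(stats::rnorm(10 * n_s, 0, 0.05), 10),
             matrix(rep(f1, each = 10), 10) +
               matrix(stats::rnorm(10 * n_s, 0, 0.05), 10),
             matrix(rep(f2, each = 10), 10) +
               matrix(stats::rnorm(10 * n_s, 0, 0.05), 10))
  dimnames(x) <- list(paste0("g", 1:30), paste0("s", 1:n_s))
  labels <- stats::setNames(rep(c(1L, 2L, 3L), each = 10), rownames(x))
  merged <- merge_close_modules(x, labels, cut_height = 0.25)
  expect_identical(length(unique(merged[merged > 0])), 2L)
  # the two f1 blocks now share a label; the f2 block does not
  expect_identical(unname(merged["g1"]), unname(merged["g11"]))
  expect_false(merged["g1"] == merged["g21"])
  # cut height zero is the identity
  expect_identical(merge_close_modules(x, labels, cut_height = 0), labels)
  # merging is idempotent
  expect_identical(merge_close_modules(x, merged, cut_height = 0.25), merged)
})

test_that("k-means baseline honors k, the seed and the size floor", {
  set.seed(50)
  x <- factor_matrix(c(12, 12), 0, 25, loading = 1, noise_sd = 0.1)
  one <- kmeans_baseline(x, k = 1, seed = 3, min_module_size = 5)
  expect_true(all(one == 1))
  two <- kmeans_baseline(x, k = 2, seed = 3, min_module_size = 10)
  expect_identical(two, kmeans_baseline(x, k = 2, seed = 3,
                                        min_module_size = 10))
  truth1 <- rownames(x)[1:12]
  mods <- split(names(two)[two > 0], two[two > 0])
  expect_gte(max(vapply(mods, jaccard, 0, b = truth1)), 0.9)
  expect_error(kmeans_baseline(x, k = 100, seed = 1), "k must be")
})

test_that("fit_modules returns a full model object with working methods", {
  cfg <- sim_config(n_genes = 150, n_go_terms = 1, go_size_range = c(60, 60),
                    planted_modules = list(
                      planted_module(1, size = 20, loading = 0.9,
                                     case_shift = 1.5)),
                    noise_sd = 0.4, missing_rate = 0, seed = 51)
  sim <- simulate_cohorts(cfg)
  tm <- term_expression(sim$train, sim$truth$term_genes[[1]])
  fit <- fit_modules(tm, term_name = "demo")
  expect_s3_class(fit, "comod")
  expect_gte(length(fit$modules), 1)
  sm <- summary(fit)
  expect_true(all(c("module", "size", "trait_p") %in% names(sm)))
  km <- coef(fit)
  expect_identical(rownames(km), rownames(tm$values))
  # predicting on the training cohort reproduces each eigengene up to sign
  pr <- predict(fit)
  for (i in seq_along(fit$modules))
    expect_gt(abs(stats::cor(pr[, i], fit$modules[[i]]$eigengene)), 0.999)
  # projecting onto the test cohort tracks the planted factor there
  pr_test <- predict(fit, newdata = sim$test)
  f_test <- sim$truth$factors_test["PM01", ]
  expect_gt(abs(stats::cor(pr_test[, 1], f_test)), 0.8)
  # residuals remove the module component
  res <- residuals(fit)
  m1 <- fit$modules[[1]]
  expect_lt(max(abs(res[m1$genes, ] %*% m1$eigengene)), 1e-8)
  expect_output(print(fit), "comod fit")
})
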