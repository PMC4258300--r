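test_that("trait association reproduces the exact correlation t-test", {
  ph <- c(rep(1L, 5), rep(0L, 5))
  e <- scale(ph)[, 1]
  perfect <- trait_association(e, ph)
  expect_equal(perfect$r, 1, tolerance = 1e-12)
  expect_lt(perfect$p, 1e-12)
  # zero-mean within each phenotype class, hence exactly orthogonal
  orth <- rep(c(1, -1, 1, -1, 0), 2)
  flat <- trait_association(orth, ph)
  expect_equal(flat$r, 0, tolerance = 1e-12)
  expect_equal(flat$p, 1, tolerance = 1e-12)
  expect_error(trait_association(e, rep(1L, 10)), "single class")
  expect_error(trait_association(e[1:3], ph[1:3]), "at least 4")
})

test_that("trait p-value matches a numerically integrated t-tail oracle", {
  set.seed(70)
  ph <- c(rep(1L, 12), rep(0L, 8))
  e <- stats::rnorm(20) + 0.8 * ph
  ta <- trait_association(e, ph)
  n <- 20
  t_stat <- abs(ta$r) * sqrt((n - 2) / (1 - ta$r^2))
  oracle <- 2 * stats::integrate(function(u) stats::dt(u, df = n - 2),
                                 t_stat, Inf, rel.tol = 1e-12)$value
  expect_equal(ta$p, oracle, tolerance = 1e-8)
})

test_that("BH adjustment matches the hand-computed step-up reference", {
  expect_equal(bh_fdr(0.02), 0.02)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03),
               tolerance = 1e-12)
  # hand step-up: sorted p (0.005, 0.04, 0.04, 0.8); m/i * p_i =
  # (0.02, 0.08, 0.0533.., 0.8); cummin from the right: 0.02, 0.0533..,
  # 0.0533.., 0.8
  p <- c(0.04, 0.005, 0.8, 0.04)
  expect_equal(bh_fdr(p), c(0.16 / 3, 0.02, 0.8, 0.16 / 3),
               tolerance = 1e-12)
  set.seed(71)
  q <- stats::runif(25)
  adj <- bh_fdr(q)
  expect_true(all(adj >= q & adj <= 1))
  ord <- sample(25)
  expect_equal(bh_fdr(q[ord]), adj[ord], tolerance = 1e-15)
  expect_error(bh_fdr(c(0.2, 1.4)), "0, 1")
})

test_that("hypergeometric enrichment reproduces closed-form and enumeration values", {
  uni <- paste0("g", 1:20)
  # all five drawn genes in a five-gene evidence set: p = 1 / C(20,5)
  er <- hypergeometric_enrichment(uni[1:5], uni[1:5], uni)
  expect_equal(er$p, 1 / choose(20, 5), tolerance = 1e-12)
  expect_identical(er$k, 5L)
  # module = evidence = universe
  er2 <- hypergeometric_enrichment(uni, uni, uni)
  expect_equal(er2$p, 1)
  expect_identical(er2$k, er2$m)
  # enumeration oracle on a small universe
  for (case in list(c(10, 4, 5, 2), c(12, 6, 4, 3), c(9, 3, 3, 0))) {
    N <- case[1]; K <- case[2]; m <- case[3]; k <- case[4]
    er3 <- hypergeometric_enrichment(paste0("g", 1:m),
                                     paste0("g", c(seq_len(k),
                                                   (m + 1):(m + K - k))),
                                     paste0("g", 1:N))
    expect_identical(er3$k, as.integer(k))
    expect_equal(er3$p, hyper_upper_oracle(N, K, m, k), tolerance = 1e-12)
  }
  expect_error(hypergeometric_enrichment(character(), uni[1:3], uni),
               "empty")
  expect_error(hypergeometric_enrichment("zz", uni[1:3], uni),
               "universe")
})

test_that("module overlap Fisher test matches tail enumeration of the hypergeometric PMF", {
  # 2x2 table (3,2;1,4): universe 10, |A| = 5, |B| = 4, overlap 3
  uni <- paste0("g", 1:10)
  a <- uni[1:5]
  b <- uni[c(1:3, 6)]
  ft <- module_overlap_fisher(a, b, uni)
  expect_identical(ft$k, 3L)
  expect_equal(ft$p, fisher_two_sided_oracle(10, 5, 4, 3),
               tolerance = 1e-10)
  # identical nontrivial modules in a large universe: extreme table
  big <- paste0("g", 1:500)
  expect_lt(module_overlap_fisher(big[1:30], big[1:30], big)$p, 1e-20)
  expect_error(module_overlap_fisher(character(), b, uni), "empty")
})

test_that("disjoint random modules are usually non-significant", {
  big <- paste0("g", 1:400)
  ps <- sapply(1:10, function(s) {
    set.seed(700 + s)
    picks <- sample(big, 40)
    module_overlap_fisher(picks[1:20], picks[21:40], big)$p
  })
  expect_gte(mean(ps > 0.05), 0.8)
})

test_that("candidate calling requires two distinct evidence categories by default", {
  tab <- data.frame(
    module = c("m2", "m2", "m2", "m3", "m4", "m4"),
    category = c("cis_eqtl", "scna", "mutation", "trans_eqtl", "cis_eqtl",
                 "trans_eqtl"),
    fdr = c(8.93e-3, 0.040, 0.081, 0.003, 0.02, 0.04),
    stringsAsFactors = FALSE)
  calls <- call_candidates(tab)
  # the cis-eQTL + SCNA pattern qualifies; one category does not
  expect_true(calls$candidate[calls$module == "m2"])
  expect_false(calls$candidate[calls$module == "m3"])
  # cis- and trans-eQTL count as distinct categories
  expect_true(calls$candidate[calls$module == "m4"])
  # relaxing to one category yields a superset of the default calls
  loose <- call_candidates(tab, min_categories = 1)
  expect_true(all(calls$candidate <= loose$candidate))
  # the stricter eQTL-plus-other reading drops the eQTL-only module
  strict <- call_candidates(tab, rule = "eqtl_plus_other")
  expect_true(strict$candidate[strict$module == "m2"])
  expect_false(strict$candidate[strict$module == "m4"])
})

test_that("candidate merging links only significantly overlapping modules", {
  uni <- paste0("g", 1:600)
  mods <- list(red = uni[1:30], black = uni[3:32], blue = uni[101:130])
  res <- merge_overlapping_candidates(mods, uni, alpha = 0.01)
  expect_identical(length(res$merged), 2L)
  expect_true("black+red" %in% names(res$merged))
  expect_setequal(res$merged[["black+red"]], uni[1:32])
  expect_identical(res$components[["red"]], res$components[["black"]])
  # order independence
  res2 <- merge_overlapping_candidates(mods[c(3, 1, 2)], uni, alpha = 0.01)
  expect_setequal(names(res2$merged), names(res$merged))
  # nothing overlaps: modules pass through unmerged
  far <- list(a = uni[1:20], b = uni[301:320])
  out <- merge_overlapping_candidates(far, uni)$merged
  expect_identical(names(out), c("a", "b"))
  expect_setequal(out$a, far$a)
  expect_setequal(out$b, far$b)
})

test_that("regulator ranking enforces the minimum overlap and the top-n rule", {
  uni <- paste0("g", 1:500)
  module <- uni[1:25]
  sets <- list(
    strong = c(uni[1:20], uni[401:420]),     # covers 80% of the module
    weak = c(uni[1], uni[301:340]),          # single-gene overlap: excluded
    medium = c(uni[1:6], uni[201:240]))
  set.seed(72)
  for (d in 1:10) sets[[paste0("decoy", d)]] <- sample(uni[30:500], 40)
  tab <- regulator_enrichment(module, sets, uni, fdr_cut = 0.01,
                              min_overlap = 2, top_n = 5)
  expect_identical(tab$regulator[1], "strong")
  expect_false("weak" %in% tab$regulator)
  expect_lte(nrow(tab), 5)
  expect_true(all(diff(tab$fdr) >= 0))
  empty <- regulator_enrichment(module, sets, uni, top_n = 0)
  expect_identical(nrow(empty), 0L)
})

test_that("hypergeometric upper tail equals the one-sided Fisher test", {
  set.seed(73)
  for (i in 1:25) {
    N <- sample(20:80, 1)
    K <- sample(1:(N - 1), 1)
    m <- sample(1:(N - 1), 1)
    uni <- paste0("g", 1:N)
    ev <- uni[1:K]
    mod <- sample(uni, m)
    er <- hypergeometric_enrichment(mod, ev, uni)
    tab <- matrix(c(er$k, er$K - er$k, er$m - er$k,
                    er$N - er$K - er$m + er$k), 2, 2)
    expect_equal(er$p,
                 stats::fisher.test(tab, alternative = "greater")$p.value,
                 tolerance = 1e-10)
  }
})
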