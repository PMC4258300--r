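# shared fixtures and independent oracles used across test files

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# genes x samples matrix driven by latent factors: block i gets factor i
# times `loading`, plus iid noise; remaining rows pure noise
factor_matrix <- function(block_sizes, n_noise, n_samples, loading = 1,
                          noise_sd = 0, seed = 1) {
  set.seed(seed)
  n <- sum(block_sizes) + n_noise
  x <- matrix(stats::rnorm(n * n_samples, 0, max(noise_sd, 1e-9)),
              n, n_samples)
  at <- 1
  for (b in block_sizes) {
    f <- stats::rnorm(n_samples)
    x[at:(at + b - 1), ] <- rep(f, each = b) * loading +
      matrix(stats::rnorm(b * n_samples, 0, noise_sd), b, n_samples)
    at <- at + b
  }
  dimnames(x) <- list(sprintf("g%03d", seq_len(n)),
                      sprintf("s%03d", seq_len(n_samples)))
  x
}

small_cohort <- function(n_genes = 12, n_case = 4, n_ctrl = 4, seed = 1) {
  set.seed(seed)
  m <- matrix(stats::rnorm(n_genes * (n_case + n_ctrl)), n_genes,
              dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n_case + n_ctrl))))
  expr_cohort(m, c(rep(1L, n_case), rep(0L, n_ctrl)))
}

# O(n^3) reference implementation of the topological overlap matrix
tom_oracle <- function(a) {
  n <- nrow(a)
  out <- diag(n)
  k <- sapply(seq_len(n), function(i) sum(a[i, -i]))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
    out[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  out
}

random_adjacency <- function(n, seed) {
  set.seed(seed)
  a <- matrix(stats::runif(n * n), n)
  a <- (a + t(a)) / 2
  diag(a) <- 1
  dimnames(a) <- list(paste0("g", seq_len(n)), paste0("g", seq_len(n)))
  a
}

# exhaustive-enumeration oracles for the exact tests: enumerate every
# m-subset of an N-gene universe whose first K genes form the evidence set
overlap_distribution <- function(N, m) {
  stopifnot(N <= 15)
  utils::combn(N, m)
}

hyper_upper_oracle <- function(N, K, m, k) {
  subs <- overlap_distribution(N, m)
  ov <- if (K == 0) rep(0, ncol(subs)) else
    colSums(subs <= K)          # members drawn from the first K genes
  mean(ov >= k)
}

fisher_two_sided_oracle <- function(N, K, m, k) {
  subs <- overlap_distribution(N, m)
  ov <- if (K == 0) rep(0, ncol(subs)) else colSums(subs <= K)
  pmf <- table(factor(ov, levels = 0:min(m, K))) / ncol(subs)
  p_obs <- pmf[as.character(k)]
  sum(pmf[pmf <= p_obs * (1 + 1e-7)])
}
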