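# Independent oracles, deliberately written as naive loops so they share no
# code path with the package implementation.

# Brute-force median-of-ratios: geometric mean per all-positive gene, then
# per-sample median of count/geomean, rescaled to geometric mean 1.
oracle_size_factors <- function(counts) {
  ref <- c()
  for (i in seq_len(nrow(counts))) {
    if (all(counts[i, ] > 0)) ref <- c(ref, i)
  }
  stopifnot(length(ref) > 0)
  geo <- numeric(length(ref))
  for (k in seq_along(ref)) {
    geo[k] <- prod(counts[ref[k], ])^(1 / ncol(counts))
  }
  f <- numeric(ncol(counts))
  for (j in seq_len(ncol(counts))) {
    r <- numeric(length(ref))
    for (k in seq_along(ref)) r[k] <- counts[ref[k], j] / geo[k]
    f[j] <- stats::median(r)
  }
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  f
}

# Exhaustive two-sided exact Mann-Whitney p-value: enumerate every
# assignment of the pooled values into a group of size |a|, compute the U
# statistic for each, and apply the standard two-sided doubling rule.
oracle_wilcoxon_exact <- function(a, b) {
  pooled <- c(a, b)
  m <- length(a)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  sets <- utils::combn(length(pooled), m)
  u_all <- apply(sets, 2, function(ii) sum(r[ii]) - m * (m + 1) / 2)
  mn <- m * length(b)
  p <- if (u_obs > mn / 2) 2 * mean(u_all >= u_obs) else 2 * mean(u_all <= u_obs)
  min(1, p)
}

# Benjamini-Hochberg step-up by the textbook formula.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (k in seq_len(m)) {
    vals <- numeric(0)
    for (j in k:m) vals <- c(vals, min(1, p[o[j]] * m / j))
    q[o[k]] <- min(vals)
  }
  q
}

# Small random all-positive count matrix.
rand_positive_matrix <- function(n_genes, n_samples) {
  m <- matrix(sample(1:1000, n_genes * n_samples, replace = TRUE),
              n_genes, n_samples,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n_samples))))
  storage.mode(m) <- "integer"
  m
}

# Tiny hand-rolled two-group dataset for fast unit tests.
tiny_dataset <- function(seed = 101, n_genes = 300, n_per_group = 6) {
  simulate_dataset(simulation_config(
    n_genes = n_genes, n_per_group = c(n_per_group, n_per_group),
    n_stable = 5, frac_de = 0.1, seed = seed))
}
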