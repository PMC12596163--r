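make_meta <- function(n_per_group, labels = c("A", "B")) {
  data.frame(group = factor(rep(labels, each = n_per_group)),
             row.names = sprintf("s%03d", seq_len(2 * n_per_group)))
}

test_that("method-of-moments dispersion recovers simulation truth", {
  # constant gene: zero variance -> alpha_raw = 0
  m <- rbind(g1 = rep(7L, 8), g2 = c(1L, 9L, 3L, 2L, 8L, 1L, 4L, 6L))
  colnames(m) <- sprintf("s%03d", 1:8)
  disp <- estimate_dispersions(m, stats::setNames(rep(1, 8), colnames(m)),
                               make_meta(4), shrink = FALSE)
  expect_identical(disp$alpha_raw[disp$gene_id == "g1"], 0)
  expect_identical(disp$alpha, disp$alpha_raw)   # shrink disabled

  # Poisson genes (true alpha 0), n = 100/group: near-zero on average
  sim <- simulate_dataset(simulation_config(n_genes = 500, n_per_group = c(100, 100),
                                            mean_range = c(100, 100), dispersion = 0,
                                            frac_de = 0, n_stable = 0, seed = 21))
  sf <- estimate_size_factors(sim$counts)
  d0 <- estimate_dispersions(sim$counts, sf, sim$meta, shrink = FALSE)
  expect_lt(mean(d0$alpha_raw), 0.05)

  # NB genes with true alpha = 0.2, mu = 500, n = 50/group
  sim <- simulate_dataset(simulation_config(n_genes = 500, n_per_group = c(50, 50),
                                            mean_range = c(500, 500), dispersion = 0.2,
                                            frac_de = 0, n_stable = 0, seed = 22))
  sf <- estimate_size_factors(sim$counts)
  d2 <- estimate_dispersions(sim$counts, sf, sim$meta, shrink = FALSE)
  med <- stats::median(d2$alpha_raw)
  expect_gt(med, 0.15)
  expect_lt(med, 0.25)

  # shrinkage pulls estimates toward the trend, reducing spread
  d2s <- estimate_dispersions(sim$counts, sf, sim$meta, shrink = TRUE)
  expect_lt(stats::mad(d2s$alpha), stats::mad(d2$alpha_raw))
  expect_true(all(d2s$alpha >= 0 & is.finite(d2s$alpha)))

  expect_error(
    estimate_dispersions(m[, 1:3],
                         stats::setNames(rep(1, 3), colnames(m)[1:3]),
                         data.frame(group = factor(c("A", "A", "B")),
                                    row.names = colnames(m)[1:3])),
    class = "ecnorm_validation_error")
})

test_that("Wald test agrees with reference GLM fits on shared fixtures", {
  set.seed(23)
  n <- 30
  x <- rep(0:1, each = n / 2)
  s <- stats::setNames(exp(stats::runif(n, -0.3, 0.3)), sprintf("s%03d", 1:n))
  cnt <- rbind(g1 = stats::rpois(n, 40 * exp(0.7 * x) * s),
               g2 = stats::rpois(n, 15 * s))
  colnames(cnt) <- names(s)
  storage.mode(cnt) <- "integer"
  meta <- make_meta(n / 2)

  # alpha = 0 supplied: reduces to the Poisson GLM
  disp0 <- data.frame(gene_id = c("g1", "g2"), alpha = c(0, 0))
  r0 <- nb_wald_test(cnt, s, disp0, meta)
  for (g in 1:2) {
    fit <- stats::glm(cnt[g, ] ~ x + offset(log(s)), family = stats::poisson())
    expect_equal(r0$log2fc[g] * log(2), unname(stats::coef(fit)[2]), tolerance = 1e-8)
    expect_equal(r0$se[g] * log(2),
                 unname(sqrt(diag(stats::vcov(fit)))[2]), tolerance = 1e-6)
  }

  # fixed positive alpha: matches glm with MASS negative binomial family
  disp1 <- data.frame(gene_id = c("g1", "g2"), alpha = c(0.1, 0.25))
  r1 <- nb_wald_test(cnt, s, disp1, meta)
  for (g in 1:2) {
    fit <- stats::glm(cnt[g, ] ~ x + offset(log(s)),
                      family = MASS::negative.binomial(theta = 1 / disp1$alpha[g]))
    expect_equal(r1$log2fc[g] * log(2), unname(stats::coef(fit)[2]), tolerance = 1e-6)
  }
})

test_that("Wald test handles degenerate genes and label swaps", {
  sim <- tiny_dataset(seed = 24)
  cnt <- sim$counts
  cnt[1, ] <- 0L   # untestable gene
  sf <- estimate_size_factors(cnt)
  disp <- estimate_dispersions(cnt, sf, sim$meta)
  res <- nb_wald_test(cnt, sf, disp, sim$meta)

  expect_identical(res$status[1], "all_zero")
  expect_true(is.na(res$log2fc[1]) && is.na(res$pvalue[1]) && is.na(res$fdr[1]))
  expect_identical(is.na(res$pvalue), res$status != "ok")

  # swapping the reference level negates log2fc and keeps p-values
  res2 <- nb_wald_test(cnt, sf, disp, sim$meta, reference_level = levels(sim$meta$group)[2])
  ok <- res$status == "ok" & res2$status == "ok"
  expect_equal(res$log2fc[ok], -res2$log2fc[ok], tolerance = 1e-6)
  expect_equal(res$pvalue[ok], res2$pvalue[ok], tolerance = 1e-6)
  expect_error(nb_wald_test(cnt, sf, disp, sim$meta, reference_level = "zebra"),
               class = "ecnorm_validation_error")

  # fdr never below the raw p-value; ordering by p and by fdr agree
  expect_true(all(res$fdr[ok] >= res$pvalue[ok]))
  expect_identical(order(res$pvalue[ok]), order(res$fdr[ok], res$pvalue[ok]))
})

test_that("power grows with sample size at fixed effect", {
  power_at <- function(n, seed, lfc) {
    sim <- simulate_dataset(simulation_config(
      n_genes = 400, n_per_group = c(n, n), mean_range = c(200, 200),
      dispersion = 0.1, frac_de = 0.5, lfc = lfc, n_stable = 0, seed = seed))
    sf <- estimate_size_factors(sim$counts)
    disp <- estimate_dispersions(sim$counts, sf, sim$meta)
    res <- nb_wald_test(sim$counts, sf, disp, sim$meta)
    de <- sim$truth$is_de
    mean(res$pvalue[de] <= 0.05, na.rm = TRUE)
  }
  # |log2FC| = 1 at mu = 200 saturates both sizes near power 1
  expect_gte(power_at(50, 25, lfc = 1), power_at(10, 26, lfc = 1))
  # a weak effect separates the two sample sizes strictly
  expect_gt(power_at(50, 25, lfc = 0.4), power_at(10, 26, lfc = 0.4) + 0.2)
})

test_that("Benjamini-Hochberg adjustment matches the step-up formula", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_identical(bh_adjust(0.05), 0.05)
  expect_error(bh_adjust(c(0.5, 1.2)), class = "ecnorm_validation_error")
  expect_error(bh_adjust(-0.1), class = "ecnorm_validation_error")

  # NA passes through and m counts only non-NA entries
  p <- c(0.01, NA, 0.04, 0.3, NA)
  q <- bh_adjust(p)
  expect_identical(is.na(q), is.na(p))
  expect_equal(q[!is.na(q)], oracle_bh(p[!is.na(p)]))

  set.seed(27)
  for (i in 1:20) {
    p <- stats::runif(sample(1:30, 1))
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(q >= p & q <= 1))
  }
})
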