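ratio_fixture <- function() {
  m <- rbind(bm = c(10L, 20L, 6L, 8L), ec = c(5L, 4L, 0L, 2L),
             other = c(1L, 1L, 1L, 1L))
  colnames(m) <- paste0("s", 1:4)
  m
}

test_that("biomarker/control ratios follow the zero-count policy", {
  m <- ratio_fixture()
  rc <- normalization_ratio(m[, 1:2], "bm", "ec")
  expect_equal(rc$ratios, c(2, 5))
  expect_identical(rc$excluded_samples, character(0))

  rc2 <- normalization_ratio(m, "bm", "ec", zero_policy = "exclude")
  expect_identical(rc2$sample_ids, c("s1", "s2", "s4"))
  expect_identical(rc2$excluded_samples, "s3")
  expect_equal(rc2$ratios, c(2, 5, 4))

  rc3 <- normalization_ratio(m, "bm", "ec", zero_policy = "pseudocount")
  expect_length(rc3$ratios, 4L)
  expect_equal(rc3$ratios[3], 6.5 / 0.5)

  expect_error(normalization_ratio(m, "bm", "bm"), class = "ecnorm_validation_error")
  expect_error(normalization_ratio(m, "bm", "nope"), class = "ecnorm_key_error")
  z <- m; z["ec", ] <- 0L
  expect_error(normalization_ratio(z, "bm", "ec"), class = "ecnorm_validation_error",
               regexp = "every sample")
})

test_that("ratios cancel per-sample technical scale", {
  set.seed(41)
  for (i in 1:100) {
    m <- rand_positive_matrix(6, 5)
    j <- sample(5, 1)
    c_fac <- sample(2:9, 1)
    m2 <- m
    m2[, j] <- m2[, j] * c_fac
    r1 <- normalization_ratio(m, "g001", "g002")
    r2 <- normalization_ratio(m2, "g001", "g002")
    expect_equal(r1$ratios, r2$ratios, tolerance = 1e-12)
  }
})

test_that("exact Wilcoxon p matches exhaustive enumeration", {
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6), mode = "exact"), 0.1,
               tolerance = 1e-12)
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3), mode = "normal"), 1)
  expect_error(wilcoxon_rank_sum(numeric(0), 1), class = "ecnorm_validation_error")
  expect_warning(p <- wilcoxon_rank_sum(c(1, 1, 2), c(3, 4, 5), mode = "exact"),
                 regexp = "ties")
  expect_true(p >= 0 && p <= 1)

  # symmetry in the two groups
  set.seed(43)
  a <- stats::rnorm(7); b <- stats::rnorm(5)
  expect_equal(wilcoxon_rank_sum(a, b), wilcoxon_rank_sum(b, a), tolerance = 1e-12)

  # spot enumeration oracle (the full n <= 8 sweep runs in the acceptance suite)
  for (i in 1:10) {
    a <- sample(seq(0, 1, length.out = 50), sample(2:4, 1))
    b <- sample(setdiff(seq(0, 1, length.out = 50), a), sample(2:4, 1))
    expect_equal(wilcoxon_rank_sum(a, b, mode = "exact"),
                 oracle_wilcoxon_exact(a, b), tolerance = 1e-12)
  }
})

test_that("significance stars follow the conventional thresholds", {
  expect_identical(significance_stars(c(0.0005, 0.005, 0.03, 0.5)),
                   c("***", "**", "*", "ns"))
  expect_identical(significance_stars(c(0.001, 0.01, 0.05)), c("***", "**", "*"))
  expect_error(significance_stars(1.5), class = "ecnorm_validation_error")
  expect_error(significance_stars(-0.1), class = "ecnorm_validation_error")
})

test_that("direction flips are involutive and leave the test untouched", {
  m <- ratio_fixture()
  meta <- data.frame(group = factor(c("A", "A", "B", "B")), row.names = paste0("s", 1:4))
  rc <- test_ratio(normalization_ratio(m, "bm", "ec", zero_policy = "pseudocount"), meta)
  fl <- flip_direction(rc)
  expect_identical(fl$direction, -rc$direction)
  expect_identical(fl$wilcoxon_p, rc$wilcoxon_p)
  expect_identical(fl$ratios, rc$ratios)
  expect_identical(flip_direction(fl)$direction, rc$direction)
})

test_that("rescaling the control rescales ratios and keeps the p-value", {
  sim <- tiny_dataset(seed = 44)
  m <- sim$counts
  pos <- rowSums(m > 0) == ncol(m)
  bm <- rownames(m)[which(pos)[1]]
  ec <- rownames(m)[which(pos)[2]]
  r1 <- test_ratio(normalization_ratio(m, bm, ec), sim$meta)
  m2 <- m
  m2[ec, ] <- m2[ec, ] * 3L
  r2 <- test_ratio(normalization_ratio(m2, bm, ec), sim$meta)
  expect_equal(r2$ratios, r1$ratios / 3, tolerance = 1e-12)
  expect_equal(r2$wilcoxon_p, r1$wilcoxon_p, tolerance = 1e-12)
})

test_that("recapitulation flags concordant significant ratio shifts", {
  sim <- simulate_dataset(simulation_config(
    n_genes = 500, frac_de = 0.04, lfc = 2, n_stable = 3,
    confounded_ec = TRUE, confounded_lfc = 2, seed = 45))
  sf <- estimate_size_factors(sim$counts)
  disp <- estimate_dispersions(sim$counts, sf, sim$meta)
  res <- nb_wald_test(sim$counts, sf, disp, sim$meta)
  up_bm <- sim$truth$gene_id[sim$truth$is_de & sim$truth$true_lfc > 0 &
                               !sim$truth$is_confounded][1:3]

  tbl <- compare_ecs(sim$counts, sim$meta, up_bm,
                     c("stable_0001", "confounded_ec_1"), res = res)
  expect_identical(nrow(tbl), 6L)
  expect_identical(tbl$stars, significance_stars(tbl$wilcoxon_p))
  stable_rows <- tbl$ec == "stable_0001"
  expect_true(all(tbl$recapitulated[stable_rows]))
  # the confounded control shares the biomarkers' fold change: signal cancels
  expect_false(any(tbl$recapitulated[!stable_rows]))

  expect_error(compare_ecs(sim$counts, sim$meta, "stable_0001", "stable_0001"),
               class = "ecnorm_validation_error")
})
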