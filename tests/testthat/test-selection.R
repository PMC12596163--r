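# Small hand-built DE + dispersion tables for filter-logic tests.
worked_tables <- function() {
  res <- data.frame(
    gene_id  = c("rps11_like", "gapdh_like", "tbp_like", "mir186_like",
                 "deg_strong", "deg_lowexpr", "allzero"),
    base_mean = c(800, 1200, 900, 465, 500, 50, 0),
    log2fc   = c(0.012, 0.036, -0.11, -0.06, 1.5, 1.5, NA),
    se       = rep(0.1, 7),
    wald_stat = rep(0.1, 7),
    pvalue   = c(0.85, 0.65, 0.05, 0.76, 0.04, 0.04, NA),
    fdr      = c(0.9, 0.8, 0.3, 0.85, 0.2, 0.2, NA),
    status   = c(rep("ok", 6), "all_zero"),
    stringsAsFactors = FALSE)
  disp <- data.frame(gene_id = res$gene_id,
                     alpha = c(0.01, 0.05, 0.08, 0.02, 0.1, 0.1, 0))
  list(res = res, disp = disp)
}

test_that("stability filter reproduces the canonical worked examples", {
  tb <- worked_tables()
  ecs <- select_ecs(tb$res, tb$disp)
  # stable ribosomal-protein-like gene passes the default filter
  expect_identical(ecs$gene_id, "rps11_like")
  # GAPDH-like (p .65, lfc .036) and TBP-like (p .05, lfc -.11) fail defaults
  expect_false(any(c("gapdh_like", "tbp_like") %in% ecs$gene_id))
  # miR-186-like (p .76, lfc -.06) fails defaults but passes relaxed thresholds
  expect_false("mir186_like" %in% ecs$gene_id)
  relaxed <- selection_thresholds(ec_p_min = 0.6, ec_lfc_max = 0.1)
  ecs_rel <- select_ecs(tb$res, tb$disp, relaxed)
  expect_true("mir186_like" %in% ecs_rel$gene_id)
  expect_false("tbp_like" %in% ecs_rel$gene_id)   # |lfc| = .11 still too large
  # relaxing thresholds never drops a previous candidate
  expect_true(all(ecs$gene_id %in% ecs_rel$gene_id))
})

test_that("biomarker selection applies p, fold-change and expression floors", {
  tb <- worked_tables()
  degs <- select_degs(tb$res)
  expect_true("deg_strong" %in% degs$gene_id)
  expect_false("deg_lowexpr" %in% degs$gene_id)    # below the 100-count floor
  expect_false("allzero" %in% degs$gene_id)        # NA p never selected
  expect_false("rps11_like" %in% degs$gene_id)

  # ranking: p ascending, |log2fc| descending on ties, then gene id
  res <- data.frame(gene_id = c("b", "a", "c", "d"),
                    base_mean = rep(500, 4),
                    log2fc = c(2, -3, 3, 1),
                    pvalue = c(0.01, 0.01, 0.01, 0.001),
                    stringsAsFactors = FALSE)
  degs2 <- select_degs(res)
  expect_identical(degs2$gene_id, c("d", "a", "c", "b"))
  expect_identical(degs2$rank, 1:4)
})

test_that("selections are sound and mutually exclusive at defaults", {
  sim <- tiny_dataset(seed = 31)
  sf <- estimate_size_factors(sim$counts)
  disp <- estimate_dispersions(sim$counts, sf, sim$meta)
  res <- nb_wald_test(sim$counts, sf, disp, sim$meta)
  th <- selection_thresholds()
  degs <- select_degs(res, th)
  ecs <- suppressWarnings(select_ecs(res, disp, th))

  expect_true(all(degs$pvalue <= th$deg_p_max))
  expect_true(all(abs(degs$log2fc) >= th$deg_lfc_min))
  expect_true(all(degs$base_mean >= th$min_mean_norm))
  expect_true(all(ecs$pvalue_raw >= th$ec_p_min))
  expect_true(all(abs(ecs$log2fc) < th$ec_lfc_max))
  expect_true(all(ecs$base_mean >= th$min_mean_norm))
  expect_length(intersect(degs$gene_id, ecs$gene_id), 0)

  # threshold monotonicity
  ecs_rel <- suppressWarnings(
    select_ecs(res, disp, selection_thresholds(ec_p_min = 0.5, ec_lfc_max = 0.1)))
  expect_true(all(ecs$gene_id %in% ecs_rel$gene_id))
})

test_that("stability ranking is a gap-free permutation ordered by dispersion", {
  tb <- worked_tables()
  ecs <- select_ecs(tb$res, tb$disp, selection_thresholds(ec_p_min = 0.6, ec_lfc_max = 0.2))
  expect_identical(sort(ecs$stability_rank), seq_len(nrow(ecs)))
  expect_true(!is.unsorted(ecs$alpha))
  rep_tbl <- stability_report(ecs)
  expect_identical(rep_tbl$stability_rank, seq_len(nrow(ecs)))
  expect_identical(colnames(rep_tbl)[1:2], c("stability_rank", "gene_id"))

  # empty candidate list: warning plus header-only report
  strict <- selection_thresholds(ec_p_min = 0.99, ec_lfc_max = 1e-6)
  expect_warning(none <- select_ecs(tb$res, tb$disp, strict), regexp = "relaxing")
  expect_identical(nrow(none), 0L)
  expect_identical(nrow(stability_report(none)), 0L)
  f <- withr::local_tempfile(fileext = ".csv")
  write_results_csv(stability_report(none), f)
  expect_identical(length(readLines(f)), 1L)
})

test_that("threshold constructor rejects invalid values", {
  expect_error(selection_thresholds(deg_p_max = 0), class = "ecnorm_validation_error")
  expect_error(selection_thresholds(ec_p_min = 1), class = "ecnorm_validation_error")
  expect_error(selection_thresholds(ec_lfc_max = 0), class = "ecnorm_validation_error")
  expect_error(selection_thresholds(min_mean_norm = -5), class = "ecnorm_validation_error")
})
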