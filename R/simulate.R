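#' Simulation configuration
#'
#' Parameters of the negative binomial count simulator. The generative
#' model mirrors the assumptions of the analysis pipeline: counts are drawn
#' `NB(mean = s_j * q_i * 2^(x_j * lfc_i), dispersion = alpha_i)` on the
#' `Var = mu + alpha * mu^2` parameterization, where `s_j` is the sample's
#' true size factor, `q_i` the gene's baseline mean, and `x_j` the 0/1
#' group indicator. `alpha = 0` genes are Poisson.
#'
#' Defaults emulate a two-group serum small-RNA cohort: 2000 genes, 20
#' samples per group, true size factors log-uniform in `[0.5, 2]`, baseline
#' means log-uniform in `[50, 5000]`, dispersion 0.1, 5% of genes
#' differentially expressed at |log2FC| = 2 split evenly between up- and
#' down-regulation (so size-factor estimation stays unbiased), and 50
#' planted stable genes (log2FC = 0, dispersion 0.01, mean 500) playing the
#' role of true endogenous controls.
#'
#' @param n_genes Total number of genes.
#' @param n_per_group Integer pair: samples in the reference and the
#'   alternative group.
#' @param size_factor_range Positive pair `(low, high)`: true size factors
#'   are drawn log-uniformly from this interval.
#' @param mean_range Positive pair: baseline means `q_i` are drawn
#'   log-uniformly from this interval.
#' @param dispersion Constant NB dispersion for non-planted genes, or —
#'   when `dispersion_trend` is given — ignored in favour of the trend.
#' @param dispersion_trend Optional pair `c(a0, a1)` for a mean-dependent
#'   dispersion `alpha(mu) = a0 + a1 / mu`.
#' @param frac_de Fraction of genes that are differentially expressed,
#'   in `[0, 1)`.
#' @param lfc Absolute log2 fold change planted in DE genes (sign
#'   alternates gene by gene), or a vector of signed values recycled over
#'   the DE genes.
#' @param n_stable Number of planted stable genes (log2FC 0, low
#'   dispersion).
#' @param stable_alpha,stable_mean Dispersion and baseline mean of planted
#'   stable genes.
#' @param confounded_ec If `TRUE`, plant one additional gene labelled
#'   `confounded_ec_1`: moderately expressed and itself differentially
#'   expressed — the analogue of a canonical control (a miR-16-like gene)
#'   that is unstable in the studied condition.
#' @param confounded_lfc,confounded_mean Signed log2 fold change and
#'   baseline mean of the confounded control.
#' @param group_labels Two group labels, reference first (default
#'   `c("control", "disease")`).
#' @param seed Integer seed; fixes all randomness of
#'   [simulate_dataset()].
#' @return A list of class `"simulation_config"`.
#' @export
simulation_config <- function(n_genes = 2000L, n_per_group = c(20L, 20L),
                              size_factor_range = c(0.5, 2),
                              mean_range = c(50, 5000),
                              dispersion = 0.1, dispersion_trend = NULL,
                              frac_de = 0.05, lfc = 2,
                              n_stable = 50L, stable_alpha = 0.01, stable_mean = 500,
                              confounded_ec = FALSE, confounded_lfc = 2,
                              confounded_mean = 500,
                              group_labels = c("control", "disease"),
                              seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), n_per_group = as.integer(n_per_group),
              size_factor_range = size_factor_range, mean_range = mean_range,
              dispersion = dispersion, dispersion_trend = dispersion_trend,
              frac_de = frac_de, lfc = lfc,
              n_stable = as.integer(n_stable), stable_alpha = stable_alpha,
              stable_mean = stable_mean,
              confounded_ec = isTRUE(confounded_ec),
              confounded_lfc = confounded_lfc, confounded_mean = confounded_mean,
              group_labels = as.character(group_labels), seed = as.integer(seed))
  if (cfg$n_genes < 2L) abort_validation("n_genes must be >= 2")
  if (length(cfg$n_per_group) != 2L || any(cfg$n_per_group < 2L)) {
    abort_validation("n_per_group must be two integers >= 2")
  }
  if (any(size_factor_range <= 0) || size_factor_range[2L] < size_factor_range[1L]) {
    abort_validation("size_factor_range must be positive and increasing")
  }
  if (any(mean_range <= 0) || mean_range[2L] < mean_range[1L]) {
    abort_validation("mean_range must be positive and increasing")
  }
  if (cfg$dispersion < 0 || cfg$stable_alpha < 0) abort_validation("dispersions must be >= 0")
  if (frac_de < 0 || frac_de >= 1) abort_validation("frac_de must be in [0, 1)")
  n_planted <- cfg$n_stable + round(frac_de * cfg$n_genes) + as.integer(cfg$confounded_ec)
  if (n_planted > cfg$n_genes) abort_validation("planted genes exceed n_genes")
  if (length(cfg$group_labels) != 2L || anyDuplicated(cfg$group_labels)) {
    abort_validation("group_labels must be two distinct labels")
  }
  structure(cfg, class = "simulation_config")
}

#' Simulate a count matrix with known truth
#'
#' Draws a genes-x-samples NB count matrix under the configuration's
#' generative model, together with sample metadata and per-gene /
#' per-sample truth tables. All randomness is fixed by `cfg$seed` through
#' R's Mersenne-Twister generator, so identical configurations reproduce
#' identical matrices on any platform; the caller's RNG state is left
#' untouched.
#'
#' @param cfg A [simulation_config()].
#' @return A list: `counts` (integer matrix), `meta` (metadata
#'   `data.frame` with factor `group`), `truth` (per-gene `data.frame`:
#'   `gene_id`, `true_mean`, `true_alpha`, `true_lfc`, `is_de`,
#'   `is_stable`, `is_confounded`), and `sample_truth` (`sample_id`,
#'   `group`, `true_size_factor`).
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  with_seed(cfg$seed, simulate_dataset_impl(cfg))
}

simulate_dataset_impl <- function(cfg) {
  G <- cfg$n_genes
  n1 <- cfg$n_per_group[1L]; n2 <- cfg$n_per_group[2L]
  S <- n1 + n2
  n_de <- round(cfg$frac_de * G)
  n_conf <- as.integer(cfg$confounded_ec)
  n_null <- G - n_de - cfg$n_stable - n_conf

  gene_id <- c(sprintf("de_%04d", seq_len(n_de)),
               sprintf("stable_%04d", seq_len(cfg$n_stable)),
               if (n_conf) "confounded_ec_1",
               sprintf("null_%04d", seq_len(n_null)))
  is_de <- c(rep(TRUE, n_de), rep(FALSE, cfg$n_stable), rep(TRUE, n_conf), rep(FALSE, n_null))
  is_stable <- c(rep(FALSE, n_de), rep(TRUE, cfg$n_stable), rep(FALSE, n_conf + n_null))
  is_conf <- c(rep(FALSE, n_de + cfg$n_stable), rep(TRUE, n_conf), rep(FALSE, n_null))

  lo <- log(cfg$mean_range[1L]); hi <- log(cfg$mean_range[2L])
  q <- exp(stats::runif(G, lo, hi))
  q[is_stable] <- cfg$stable_mean
  q[is_conf] <- cfg$confounded_mean

  de_lfc <- if (length(cfg$lfc) == 1L) {
    rep_len(c(1, -1), n_de) * cfg$lfc
  } else rep_len(cfg$lfc, n_de)
  true_lfc <- numeric(G)
  true_lfc[seq_len(n_de)] <- de_lfc
  true_lfc[is_conf] <- cfg$confounded_lfc

  alpha <- if (is.null(cfg$dispersion_trend)) {
    rep(cfg$dispersion, G)
  } else cfg$dispersion_trend[1L] + cfg$dispersion_trend[2L] / q
  alpha[is_stable] <- cfg$stable_alpha

  sf <- exp(stats::runif(S, log(cfg$size_factor_range[1L]), log(cfg$size_factor_range[2L])))
  x <- rep(c(0, 1), c(n1, n2))
  sample_id <- sprintf("sample_%02d", seq_len(S))
  group <- factor(rep(cfg$group_labels, c(n1, n2)), levels = cfg$group_labels)

  mu <- (q * 2^(outer(true_lfc, x))) * rep(sf, each = G)
  mu_vec <- as.vector(mu)
  size_vec <- rep(ifelse(alpha > 0, 1 / alpha, Inf), times = S)
  cnt <- numeric(G * S)
  nb <- is.finite(size_vec)
  cnt[nb] <- stats::rnbinom(sum(nb), size = size_vec[nb], mu = mu_vec[nb])
  cnt[!nb] <- stats::rpois(sum(!nb), lambda = mu_vec[!nb])
  counts <- matrix(cnt, G, S, dimnames = list(gene_id, sample_id))
  if (max(counts) < .Machine$integer.max) storage.mode(counts) <- "integer"

  list(
    counts = counts,
    meta = data.frame(group = group, row.names = sample_id),
    truth = data.frame(gene_id = gene_id, true_mean = q, true_alpha = alpha,
                       true_lfc = true_lfc, is_de = is_de, is_stable = is_stable,
                       is_confounded = is_conf, stringsAsFactors = FALSE),
    sample_truth = data.frame(sample_id = sample_id, group = as.character(group),
                              true_size_factor = sf, stringsAsFactors = FALSE)
  )
}

#' Write a self-describing simulated fixture bundle
#'
#' Simulates a dataset and writes `counts.csv`, `metadata.csv`,
#' `truth.csv`, `sample_truth.csv` and `config.json` into a directory, in
#' exactly the formats [read_count_matrix()] and [read_metadata()] expect.
#'
#' @param cfg A [simulation_config()].
#' @param dir Output directory (created if missing).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_fixture_bundle <- function(cfg, dir) {
  stopifnot(inherits(cfg, "simulation_config"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sim <- simulate_dataset(cfg)
  paths <- c(counts = file.path(dir, "counts.csv"),
             metadata = file.path(dir, "metadata.csv"),
             truth = file.path(dir, "truth.csv"),
             sample_truth = file.path(dir, "sample_truth.csv"),
             config = file.path(dir, "config.json"))
  write_count_matrix(sim$counts, paths[["counts"]])
  write_results_csv(data.frame(sample_id = rownames(sim$meta),
                               group = as.character(sim$meta$group),
                               stringsAsFactors = FALSE),
                    paths[["metadata"]])
  write_results_csv(sim$truth, paths[["truth"]])
  write_results_csv(sim$sample_truth, paths[["sample_truth"]])
  jsonlite::write_json(unclass(cfg), paths[["config"]], auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(paths)
}

# Evaluate `code` under an explicit, portable RNG configuration seeded
# with `seed`, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  force(code)
}
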