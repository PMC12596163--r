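#' Per-gene negative binomial dispersion estimates
#'
#' Gene-wise dispersion on the NB parameterization `Var = mu + alpha * mu^2`
#' (used throughout the package; `alpha = 0` is Poisson). The raw estimate
#' is a pooled method-of-moments estimator on normalized counts: with
#' group-wise means `m_g` and variances `v_g` over the `n_g` samples of
#' group `g` (total `n`),
#'
#' `alpha_raw = max(0, sum_g w_g * (v_g - m_g) / m_g^2)`, `w_g = (n_g - 1) / (n - 2)`.
#'
#' With `shrink = TRUE` a parametric mean-dispersion trend
#' `alpha_trend(mu) = a0 + a1 / mu` is fitted by robust regression
#' ([MASS::rlm()]) over genes with positive raw dispersion, and each gene's
#' final dispersion is the geometric mean of its raw estimate and the trend
#' value at its mean:
#' `alpha = exp(0.5 * log(alpha_trend) + 0.5 * log(max(alpha_raw, 1e-8)))`.
#' Shrinkage damps the sampling noise of the gene-wise estimator at typical
#' cohort sizes, which matters both for Wald-test calibration and for
#' dispersion-based stability ranking.
#'
#' @inheritParams normalize_counts
#' @param meta Metadata `data.frame` with a two-level factor column `group`
#'   (see [read_metadata()]); rows are matched to `colnames(counts)`.
#' @param shrink Apply trend shrinkage (default `TRUE`).
#' @return A `data.frame` with one row per gene: `gene_id`, `base_mean`
#'   (mean normalized count), `alpha_raw`, `alpha_trend`, `alpha`.
#' @export
estimate_dispersions <- function(counts, sf, meta, shrink = TRUE) {
  validate_count_matrix(counts)
  meta <- align_metadata(counts, meta)
  grp <- check_group(meta)
  n_g <- table(grp)
  if (any(n_g < 2L)) abort_validation("dispersion estimation needs >= 2 samples per group")
  n <- length(grp)
  norm <- normalize_counts(counts, sf)

  alpha_raw <- rep(0, nrow(counts))
  for (g in levels(grp)) {
    cols <- which(grp == g)
    x <- norm[, cols, drop = FALSE]
    m <- rowMeans(x)
    v <- rowSums((x - m)^2) / (length(cols) - 1L)
    w <- (length(cols) - 1L) / (n - 2L)
    term <- ifelse(m > 0, w * (v - m) / m^2, 0)
    alpha_raw <- alpha_raw + term
  }
  alpha_raw <- pmax(0, alpha_raw)
  base_mean <- rowMeans(norm)

  alpha_trend <- rep(NA_real_, length(alpha_raw))
  alpha <- alpha_raw
  if (shrink) {
    fit_set <- alpha_raw > 0 & base_mean > 0
    if (sum(fit_set) >= 10L) {
      coefs <- fit_dispersion_trend(alpha_raw[fit_set], base_mean[fit_set])
    } else {
      # too few informative genes for a trend: flat robust location
      pos <- alpha_raw[alpha_raw > 0]
      coefs <- c(a0 = if (length(pos)) stats::median(pos) else 0, a1 = 0)
    }
    alpha_trend <- pmax(coefs[[1L]] + coefs[[2L]] / pmax(base_mean, 1e-8), 1e-8)
    alpha <- exp(0.5 * log(alpha_trend) + 0.5 * log(pmax(alpha_raw, 1e-8)))
    alpha[base_mean == 0] <- 0
  }

  data.frame(gene_id = rownames(counts), base_mean = base_mean,
             alpha_raw = alpha_raw, alpha_trend = alpha_trend, alpha = alpha,
             row.names = NULL, stringsAsFactors = FALSE)
}

# Robust fit of alpha ~ a0 + a1/mu. Huber M-estimation; falls back to an
# ordinary least-squares fit if rlm fails to converge on degenerate input.
fit_dispersion_trend <- function(alpha_raw, base_mean) {
  df <- data.frame(a = alpha_raw, im = 1 / base_mean)
  fit <- tryCatch(MASS::rlm(a ~ im, data = df, maxit = 50),
                  error = function(e) NULL, warning = function(w) NULL)
  if (is.null(fit)) fit <- stats::lm(a ~ im, data = df)
  co <- stats::coef(fit)
  c(a0 = unname(co[1L]), a1 = unname(co[2L]))
}

#' Two-group negative binomial Wald test
#'
#' Fits, per gene, the NB log-linear model
#' `mu_ij = s_j * exp(beta0 + beta1 * x_j)` with known dispersion and the
#' size factor as multiplicative offset, where `x_j` is 0 for the reference
#' group and 1 otherwise. Fitting is by iteratively reweighted least
#' squares (Fisher scoring, weights `mu / (1 + alpha * mu)`), run
#' vectorized across all genes; convergence is `max|delta beta| < 1e-8`
#' within 100 iterations. The log2 fold change is `beta1 / ln 2`, its
#' standard error comes from the inverse Fisher information, and the Wald
#' p-value is two-sided normal. Raw p-values are adjusted by
#' Benjamini-Hochberg into the `fdr` column.
#'
#' Genes with all-zero counts are untestable and get an `NA` row; genes
#' whose fit does not converge (e.g. one group entirely zero, so the fold
#' change diverges) are flagged in `status` with `NA` p-values.
#'
#' @inheritParams estimate_dispersions
#' @param disp Dispersion table from [estimate_dispersions()] (column
#'   `alpha` is used), aligned on gene identifiers.
#' @param reference_level Group level coding `x = 0`; default the first
#'   (lexicographically smallest) level. The sign of `log2fc` depends on it.
#' @param max_iter,tol IRLS iteration cap and convergence tolerance.
#' @return A `data.frame` with one row per gene: `gene_id`, `base_mean`,
#'   `log2fc`, `se` (of `log2fc`), `wald_stat`, `pvalue`, `fdr`, `status`
#'   (`"ok"`, `"all_zero"` or `"not_converged"`).
#' @export
nb_wald_test <- function(counts, sf, disp, meta, reference_level = NULL,
                         max_iter = 100L, tol = 1e-8) {
  validate_count_matrix(counts)
  meta <- align_metadata(counts, meta)
  grp <- check_group(meta)
  if (!is.null(reference_level)) {
    if (!reference_level %in% levels(grp)) {
      abort_validation(sprintf("reference level '%s' is not a group level (%s)",
                               reference_level, paste(levels(grp), collapse = ", ")))
    }
    grp <- stats::relevel(grp, ref = reference_level)
  }
  if (!setequal(disp$gene_id, rownames(counts))) {
    abort_validation("dispersion table and count matrix disagree on gene identifiers")
  }
  alpha <- disp$alpha[match(rownames(counts), disp$gene_id)]
  if (any(!is.finite(alpha)) || any(alpha < 0)) abort_validation("dispersions must be finite and >= 0")

  sf <- if (is.null(names(sf))) stats::setNames(sf, colnames(counts)) else sf[colnames(counts)]
  x <- as.numeric(grp == levels(grp)[2L])
  G <- nrow(counts); S <- ncol(counts)
  norm <- normalize_counts(counts, sf)
  base_mean <- rowMeans(norm)

  y <- counts
  storage.mode(y) <- "double"
  log_sf <- matrix(log(sf), G, S, byrow = TRUE)
  amat <- matrix(pmax(alpha, 0), G, S)

  b0 <- log(pmax(base_mean, 1e-8))
  b1 <- rep(0, G)
  active <- base_mean > 0                    # all-zero genes are untestable
  converged <- rep(FALSE, G)

  for (it in seq_len(max_iter)) {
    idx <- which(active & !converged)
    if (!length(idx)) break
    eta <- b0[idx] + outer(b1[idx], x)       # linear predictor sans offset
    mu <- exp(eta + log_sf[idx, , drop = FALSE])
    mu <- pmax(mu, 1e-300)
    w <- mu / (1 + amat[idx, , drop = FALSE] * mu)   # dispersion floor below
    z <- eta + (y[idx, , drop = FALSE] - mu) / mu
    S0 <- rowSums(w)
    S1 <- as.vector(w %*% x)                 # = S2 since x is 0/1
    T0 <- rowSums(w * z)
    T1 <- as.vector((w * z) %*% x)
    det <- S0 * S1 - S1 * S1
    ok <- is.finite(det) & det > 1e-12
    nb1 <- ifelse(ok, (S0 * T1 - S1 * T0) / det, b1[idx])
    nb0 <- ifelse(ok, (T0 - S1 * nb1) / S0, b0[idx])
    step <- pmax(abs(nb0 - b0[idx]), abs(nb1 - b1[idx]))
    b0[idx] <- nb0
    b1[idx] <- nb1
    converged[idx[ok & step < tol]] <- TRUE
    active[idx[!ok]] <- FALSE                # singular fit: flag, stop iterating
  }

  # standard errors from the Fisher information at the final fit
  se_b1 <- rep(NA_real_, G)
  idx <- which(converged)
  if (length(idx)) {
    eta <- b0[idx] + outer(b1[idx], x)
    mu <- exp(eta + log_sf[idx, , drop = FALSE])
    w <- mu / (1 + amat[idx, , drop = FALSE] * mu)
    S0 <- rowSums(w)
    S1 <- as.vector(w %*% x)
    det <- S0 * S1 - S1 * S1
    se_b1[idx] <- sqrt(S0 / det)
  }

  status <- ifelse(base_mean == 0, "all_zero",
                   ifelse(converged, "ok", "not_converged"))
  testable <- status == "ok"
  log2fc <- ifelse(testable, b1 / log(2), NA_real_)
  se <- ifelse(testable, se_b1 / log(2), NA_real_)
  wald <- ifelse(testable, b1 / se_b1, NA_real_)
  pval <- ifelse(testable, 2 * stats::pnorm(-abs(wald)), NA_real_)

  data.frame(gene_id = rownames(counts), base_mean = base_mean,
             log2fc = log2fc, se = se, wald_stat = wald,
             pvalue = pval, fdr = bh_adjust(pval), status = status,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment over the non-`NA` entries (`m` = number of
#' non-`NA` p-values); `NA` in gives `NA` out. Delegates to
#' [stats::p.adjust()] after the NA bookkeeping.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`, `NA` allowed.
#' @return Vector of the same length with adjusted values.
#' @export
bh_adjust <- function(pvalues) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1)) {
    abort_validation("p-values must lie in [0, 1]")
  }
  out <- pvalues
  out[ok] <- stats::p.adjust(pvalues[ok], method = "BH")
  out
}

# Validate and return the two-level group factor from metadata.
check_group <- function(meta) {
  if (!"group" %in% colnames(meta)) abort_validation("metadata has no 'group' column")
  grp <- meta$group
  if (!is.factor(grp)) grp <- factor(grp, levels = sort(unique(as.character(grp))))
  grp <- droplevels(grp)
  if (nlevels(grp) != 2L) {
    abort_validation(sprintf("group must have exactly 2 levels, found %d", nlevels(grp)))
  }
  grp
}
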