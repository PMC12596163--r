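#' Run the full endogenous-control discovery pipeline
#'
#' End-to-end workflow on a count matrix and metadata file: validate and
#' read inputs, estimate median-of-ratios size factors, normalize, estimate
#' dispersions, run the NB Wald test, select differentially expressed
#' biomarkers and endogenous control candidates, cross them in the
#' in-silico qPCR/ddPCR normalization, and write every table (plus plots
#' and a machine-readable run manifest) into `outdir`. All outputs are
#' deterministic for a given configuration.
#'
#' @param counts_file,metadata_file Input file paths (see
#'   [read_count_matrix()] and [read_metadata()]).
#' @param outdir Output directory, created if missing.
#' @param th [selection_thresholds()].
#' @param group_col Metadata column holding the two-level group factor.
#' @param reference_level Reference group level (log2 fold changes are
#'   "other vs reference"); default the lexicographically first level.
#' @param zero_policy Zero-control policy for in-silico ratios
#'   (`"exclude"` or `"pseudocount"`).
#' @param shrink Dispersion trend shrinkage flag, see
#'   [estimate_dispersions()].
#' @param strict Passed to [read_count_matrix()].
#' @param pseudo_reference Passed to [estimate_size_factors()].
#' @param top_degs,top_ecs How many top biomarkers and top-ranked controls
#'   enter the in-silico comparison grid (defaults 10 and 3).
#' @param make_plots Write heatmap/volcano/boxplot images (default `TRUE`).
#' @param seed Recorded in the manifest; the analysis itself is
#'   deterministic.
#' @return Invisibly, a list with the main result tables and the output
#'   paths.
#' @export
run_pipeline <- function(counts_file, metadata_file, outdir,
                         th = selection_thresholds(), group_col = "group",
                         reference_level = NULL, zero_policy = "exclude",
                         shrink = TRUE, strict = TRUE, pseudo_reference = FALSE,
                         top_degs = 10L, top_ecs = 3L,
                         make_plots = TRUE, seed = 1L) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  failed_marker <- file.path(outdir, "FAILED")
  if (file.exists(failed_marker)) unlink(failed_marker)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(sprintf("stage: %s\nerror: %s", name, conditionMessage(e)), failed_marker)
      ec_abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
               class(e)[1L])
    })
  }

  counts <- stage("read-counts", read_count_matrix(counts_file, strict = strict))
  meta <- stage("read-metadata",
                read_metadata(metadata_file, group_col = group_col, counts = counts))
  if (is.null(reference_level)) reference_level <- levels(meta$group)[1L]

  sf <- stage("size-factors", estimate_size_factors(counts, pseudo_reference = pseudo_reference))
  norm <- normalize_counts(counts, sf)
  disp <- stage("dispersions", estimate_dispersions(counts, sf, meta, shrink = shrink))
  res <- stage("wald-test",
               nb_wald_test(counts, sf, disp, meta, reference_level = reference_level))
  degs <- stage("select-deg", select_degs(res, th))
  ecs <- stage("select-ec", withCallingHandlers(
    select_ecs(res, disp, th),
    warning = function(w) { message("note: ", conditionMessage(w)); invokeRestart("muffleWarning") }))

  paths <- c(size_factors = "size_factors.csv", normalized = "normalized_counts.csv",
             de_table = "de_table.csv", deg_list = "deg_list.csv",
             ec_list = "ec_list.csv", insilico_summary = "insilico_summary.csv",
             insilico_ratios = "insilico_ratios.csv", manifest = "run_manifest.json")
  paths <- vapply(paths, function(p) file.path(outdir, p), character(1))

  stage("write-tables", {
    write_results_csv(data.frame(sample_id = names(sf), size_factor = unname(sf),
                                 stringsAsFactors = FALSE), paths[["size_factors"]])
    write_results_csv(data.frame(gene_id = rownames(norm), norm, check.names = FALSE,
                                 stringsAsFactors = FALSE), paths[["normalized"]])
    write_results_csv(res, paths[["de_table"]])
    write_results_csv(degs, paths[["deg_list"]])
    write_results_csv(stability_report(ecs), paths[["ec_list"]])
  })

  bm <- utils::head(degs$gene_id, top_degs)
  ec_ids <- utils::head(ecs$gene_id, top_ecs)
  summary_tbl <- empty_insilico_summary()
  ratio_long <- empty_insilico_ratios()
  if (length(bm) && length(ec_ids)) {
    summary_tbl <- stage("insilico",
                         compare_ecs(counts, meta, bm, ec_ids, res = res,
                                     zero_policy = zero_policy,
                                     reference_level = reference_level))
    ratio_long <- stage("insilico", insilico_ratio_table(counts, meta, bm, ec_ids, zero_policy))
  } else {
    message("note: in-silico comparison skipped (no biomarker or no endogenous control selected)")
  }
  write_results_csv(summary_tbl, paths[["insilico_summary"]])
  write_results_csv(ratio_long, paths[["insilico_ratios"]])

  plot_files <- character(0)
  if (make_plots) {
    plot_files <- stage("plots", {
      out <- character(0)
      if (nrow(degs) >= 2L) {
        f <- file.path(outdir, "heatmap_top_degs.png")
        plot_heatmap(norm, meta, utils::head(degs$gene_id, max(top_degs, 2L)), f)
        out <- c(out, f)
      }
      f <- file.path(outdir, "volcano.png")
      plot_volcano(res, f, p_max = th$deg_p_max, lfc_min = max(th$deg_lfc_min, 1))
      out <- c(out, f)
      if (length(bm) && length(ec_ids)) {
        f <- file.path(outdir, "ratio_boxplot_top_pair.png")
        rc <- normalization_ratio(counts, bm[1L], ec_ids[1L], zero_policy = zero_policy)
        plot_ratio_boxplot(rc, meta, f)
        out <- c(out, f)
      }
      out
    })
  }

  manifest <- list(
    package = "ecnorm",
    version = as.character(utils::packageVersion("ecnorm")),
    seed = seed,
    inputs = list(counts = counts_file, metadata = metadata_file, group_col = group_col),
    reference_level = reference_level,
    thresholds = unclass(th),
    options = list(zero_policy = zero_policy, shrink = shrink, strict = strict,
                   pseudo_reference = pseudo_reference,
                   top_degs = top_degs, top_ecs = top_ecs),
    dims = list(n_genes = nrow(counts), n_samples = ncol(counts)),
    n_degs = nrow(degs), n_ecs = nrow(ecs),
    recapitulation_rule = attr(summary_tbl, "recapitulation_rule"),
    outputs = basename(c(paths, plot_files))
  )
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)

  invisible(list(size_factors = sf, dispersions = disp, de_table = res,
                 degs = degs, ecs = ecs, insilico = summary_tbl,
                 paths = c(paths, plot_files)))
}

# Long-format per-sample ratio table for the biomarker x control grid.
insilico_ratio_table <- function(counts, meta, biomarkers, ecs, zero_policy) {
  rows <- list()
  for (bm in biomarkers) {
    for (ec in ecs) {
      rc <- normalization_ratio(counts, bm, ec, zero_policy = zero_policy)
      rows[[length(rows) + 1L]] <- data.frame(
        biomarker = bm, ec = ec, sample_id = rc$sample_ids,
        group = as.character(meta[rc$sample_ids, "group"]),
        ratio = rc$ratios, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

empty_insilico_summary <- function() {
  data.frame(biomarker = character(0), ec = character(0),
             n_ref = integer(0), n_alt = integer(0), n_excluded = integer(0),
             median_ratio_ref = numeric(0), median_ratio_alt = numeric(0),
             direction = numeric(0), wilcoxon_p = numeric(0), stars = character(0),
             de_log2fc = numeric(0), recapitulated = logical(0),
             stringsAsFactors = FALSE)
}

empty_insilico_ratios <- function() {
  data.frame(biomarker = character(0), ec = character(0), sample_id = character(0),
             group = character(0), ratio = numeric(0), stringsAsFactors = FALSE)
}

#' Dry-run validation of pipeline inputs
#'
#' Checks files, the design and the thresholds without running any
#' computation, returning a machine-readable problem report (empty when
#' everything is valid).
#'
#' @inheritParams run_pipeline
#' @return `data.frame` with columns `kind` (`file-not-found`,
#'   `bad-counts`, `bad-metadata`, `bad-design`, `sample-mismatch`,
#'   `bad-thresholds`) and `message`; zero rows when the inputs are valid.
#' @export
validate_inputs <- function(counts_file, metadata_file, group_col = "group",
                            th = selection_thresholds(), strict = TRUE) {
  problems <- list()
  add <- function(kind, msg) {
    problems[[length(problems) + 1L]] <<- data.frame(kind = kind, message = msg,
                                                     stringsAsFactors = FALSE)
  }

  if (!inherits(th, "selection_thresholds")) {
    ok <- tryCatch({ do.call(selection_thresholds, as.list(th)); TRUE },
                   error = function(e) { add("bad-thresholds", conditionMessage(e)); FALSE })
  }

  counts <- NULL
  if (!file.exists(counts_file)) {
    add("file-not-found", sprintf("count matrix file not found: '%s'", counts_file))
  } else {
    counts <- tryCatch(read_count_matrix(counts_file, strict = strict),
                       error = function(e) { add("bad-counts", conditionMessage(e)); NULL })
  }

  if (!file.exists(metadata_file)) {
    add("file-not-found", sprintf("metadata file not found: '%s'", metadata_file))
  } else {
    sep <- tryCatch(sniff_delimiter(metadata_file), error = function(e) ",")
    raw <- tryCatch(utils::read.table(metadata_file, header = TRUE, sep = sep,
                                      check.names = FALSE, stringsAsFactors = FALSE),
                    error = function(e) { add("bad-metadata", conditionMessage(e)); NULL })
    if (!is.null(raw)) {
      if (!group_col %in% colnames(raw)[-1L]) {
        add("bad-metadata", sprintf("metadata has no '%s' column", group_col))
      } else {
        grp <- as.character(raw[[group_col]])
        lev <- sort(unique(grp))
        if (length(lev) != 2L) {
          add("bad-design", sprintf("group must have exactly 2 levels, found %d (%s)",
                                    length(lev), paste(lev, collapse = ", ")))
        } else if (any(table(grp) < 2L)) {
          add("bad-design", "each group level needs at least 2 samples")
        }
        if (!is.null(counts)) {
          ids <- as.character(raw[[1L]])
          if (!setequal(ids, colnames(counts))) {
            add("sample-mismatch", sprintf(
              "in counts only [%s]; in metadata only [%s]",
              paste(setdiff(colnames(counts), ids), collapse = ", "),
              paste(setdiff(ids, colnames(counts)), collapse = ", ")))
          }
        }
      }
    }
  }

  if (length(problems)) do.call(rbind, problems) else {
    data.frame(kind = character(0), message = character(0), stringsAsFactors = FALSE)
  }
}
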