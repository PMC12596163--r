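#' Read a count matrix from CSV/TSV
#'
#' Reads a genes-x-samples table of raw read counts. The first column must
#' hold gene (or miRNA) identifiers and the header row sample identifiers,
#' the layout emitted by standard quantifiers (RSEM, HTSeq, miRge3) after
#' conversion to a plain delimited matrix.
#'
#' @param path Path to a delimited text file.
#' @param delimiter `"auto"` (default), `"comma"` or `"tab"`. Under `"auto"`
#'   the delimiter is taken from the file extension (`.csv` vs `.tsv`/`.tab`)
#'   and otherwise sniffed from the first line.
#' @param strict If `TRUE` (default) non-integral cells are an error. If
#'   `FALSE`, fractional values (e.g. RSEM expected counts) are rounded to
#'   the nearest integer with a warning.
#' @return An integer matrix with gene identifiers as `rownames` and sample
#'   identifiers as `colnames`.
#' @seealso [write_count_matrix()], [read_metadata()]
#' @export
read_count_matrix <- function(path, delimiter = "auto", strict = TRUE) {
  if (!file.exists(path)) abort_io(sprintf("count matrix file not found: '%s'", path))
  sep <- sniff_delimiter(path, delimiter)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, comment.char = "", quote = "\"")
  if (nrow(df) < 1L || ncol(df) < 2L) {
    abort_validation("count matrix is empty: need at least one gene row and one sample column")
  }
  gene_ids <- as.character(df[[1L]])
  sample_ids <- colnames(df)[-1L]
  if (anyDuplicated(gene_ids)) {
    abort_validation(sprintf("duplicate gene identifiers: %s",
                             paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", ")))
  }
  if (anyDuplicated(sample_ids)) {
    abort_validation(sprintf("duplicate sample identifiers: %s",
                             paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", ")))
  }

  m <- matrix(NA_real_, nrow = nrow(df), ncol = length(sample_ids),
              dimnames = list(gene_ids, sample_ids))
  for (j in seq_along(sample_ids)) {
    col <- df[[j + 1L]]
    if (!is.numeric(col)) {
      num <- suppressWarnings(as.numeric(col))
      bad <- which(is.na(num) & !is.na(col) & !col %in% c("NA", ""))
      if (length(bad)) {
        abort_validation(sprintf(
          "non-numeric count '%s' at gene '%s', sample '%s'",
          col[bad[1L]], gene_ids[bad[1L]], sample_ids[j]))
      }
      col <- num
    }
    m[, j] <- col
  }

  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1L, ]
    abort_validation(sprintf("missing count at gene '%s', sample '%s'",
                             gene_ids[bad[1L]], sample_ids[bad[2L]]))
  }
  if (any(m < 0)) {
    bad <- which(m < 0, arr.ind = TRUE)[1L, ]
    abort_validation(sprintf("negative count %s at gene '%s', sample '%s'",
                             format(m[bad[1L], bad[2L]]), gene_ids[bad[1L]], sample_ids[bad[2L]]))
  }
  nonint <- abs(m - round(m)) > 1e-8
  if (any(nonint)) {
    bad <- which(nonint, arr.ind = TRUE)[1L, ]
    if (strict) {
      abort_validation(sprintf(
        "non-integer count %s at gene '%s', sample '%s' (use strict = FALSE to round)",
        format(m[bad[1L], bad[2L]]), gene_ids[bad[1L]], sample_ids[bad[2L]]))
    }
    warning(sprintf("rounded %d non-integer count(s) to the nearest integer (first: gene '%s', sample '%s')",
                    sum(nonint), gene_ids[bad[1L]], sample_ids[bad[2L]]), call. = FALSE)
    m <- round(m)
  }
  if (max(m) < .Machine$integer.max) storage.mode(m) <- "integer"
  validate_count_matrix(m)
  m
}

#' Write a count matrix as CSV
#'
#' Inverse of [read_count_matrix()]: first column `gene_id`, one column per
#' sample. Writing then re-reading reproduces the matrix exactly.
#'
#' @param counts Integer matrix with gene rownames and sample colnames.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(counts, path) {
  validate_count_matrix(counts)
  df <- data.frame(gene_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_results_csv(df, path)
}

#' Read sample metadata from CSV/TSV
#'
#' Reads a samples-x-variables table. The first column must hold sample
#' identifiers; the designated group column must contain exactly two levels
#' with at least two samples each (a two-group design, e.g. disease vs
#' control). All other columns are carried along untouched.
#'
#' @param path Path to a delimited text file.
#' @param group_col Name of the column holding the two-level group factor
#'   (default `"group"`).
#' @param counts Optional count matrix; when supplied, the metadata sample
#'   set must equal the matrix sample set, and rows are reordered to match
#'   the matrix column order.
#' @inheritParams read_count_matrix
#' @return A `data.frame` with sample identifiers as rownames and a factor
#'   column `group` (levels sorted lexicographically; the first level is the
#'   default reference for log2 fold changes).
#' @export
read_metadata <- function(path, group_col = "group", counts = NULL, delimiter = "auto") {
  if (!file.exists(path)) abort_io(sprintf("metadata file not found: '%s'", path))
  sep <- sniff_delimiter(path, delimiter)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, comment.char = "", quote = "\"")
  if (nrow(df) < 1L || ncol(df) < 2L) {
    abort_validation("metadata is empty: need sample identifiers plus at least one variable column")
  }
  sample_ids <- as.character(df[[1L]])
  if (anyDuplicated(sample_ids)) {
    abort_validation(sprintf("duplicate sample identifiers in metadata: %s",
                             paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", ")))
  }
  if (!group_col %in% colnames(df)[-1L]) {
    abort_validation(sprintf("metadata has no '%s' column (columns: %s)",
                             group_col, paste(colnames(df)[-1L], collapse = ", ")))
  }
  meta <- df[, -1L, drop = FALSE]
  rownames(meta) <- sample_ids
  grp <- as.character(meta[[group_col]])
  lev <- sort(unique(grp))
  if (length(lev) != 2L) {
    abort_validation(sprintf("group must have exactly 2 levels, found %d (%s)",
                             length(lev), paste(lev, collapse = ", ")))
  }
  if (any(table(grp) < 2L)) {
    abort_validation("each group level needs at least 2 samples")
  }
  meta[[group_col]] <- NULL
  meta <- cbind(group = factor(grp, levels = lev), meta)
  if (!is.null(counts)) meta <- align_metadata(counts, meta)
  meta
}

#' Write a result table as CSV
#'
#' RFC-4180-style CSV with a header row; numeric columns keep full double
#' precision (well beyond 6 significant digits). Zero-row tables produce a
#' header-only file.
#'
#' @param table A `data.frame` with at least one column.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_results_csv <- function(table, path) {
  if (!is.data.frame(table)) table <- as.data.frame(table)
  if (ncol(table) < 1L) abort_validation("result table has no columns")
  ok <- tryCatch({
    utils::write.csv(table, path, row.names = FALSE, quote = TRUE, na = "NA")
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) abort_io(sprintf("cannot write '%s': %s", path, conditionMessage(ok)))
  invisible(path)
}

#' Validate a count matrix
#'
#' Asserts the count-matrix contract: a numeric matrix of finite,
#' non-negative, integral values with unique gene rownames and sample
#' colnames, at least 2 x 2.
#'
#' @param counts Matrix to validate.
#' @return `counts`, invisibly.
#' @export
validate_count_matrix <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    abort_validation("counts must be a numeric matrix")
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort_validation("counts must have gene rownames and sample colnames")
  }
  if (nrow(counts) < 2L || ncol(counts) < 2L) {
    abort_validation("count matrix needs at least 2 genes and 2 samples")
  }
  if (anyDuplicated(rownames(counts))) abort_validation("duplicate gene identifiers")
  if (anyDuplicated(colnames(counts))) abort_validation("duplicate sample identifiers")
  if (anyNA(counts) || any(!is.finite(counts))) abort_validation("counts must be finite")
  if (any(counts < 0)) abort_validation("counts must be non-negative")
  if (any(abs(counts - round(counts)) > 1e-8)) abort_validation("counts must be integral")
  invisible(counts)
}

# Reorder metadata rows to the count matrix column order; error with the
# symmetric difference if the sample sets disagree.
align_metadata <- function(counts, meta) {
  cm <- colnames(counts)
  mm <- rownames(meta)
  if (!setequal(cm, mm)) {
    only_counts <- setdiff(cm, mm)
    only_meta <- setdiff(mm, cm)
    abort_validation(sprintf(
      "sample sets differ: in counts only [%s]; in metadata only [%s]",
      paste(only_counts, collapse = ", "), paste(only_meta, collapse = ", ")))
  }
  meta[cm, , drop = FALSE]
}

sniff_delimiter <- function(path, delimiter = "auto") {
  if (delimiter %in% c("comma", ",")) return(",")
  if (delimiter %in% c("tab", "\t")) return("\t")
  if (!identical(delimiter, "auto")) {
    abort_validation(sprintf("delimiter must be 'auto', 'comma' or 'tab', got '%s'", delimiter))
  }
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") return(",")
  if (ext %in% c("tsv", "tab")) return("\t")
  first <- readLines(path, n = 1L)
  n_tab <- nchar(first) - nchar(gsub("\t", "", first, fixed = TRUE))
  n_com <- nchar(first) - nchar(gsub(",", "", first, fixed = TRUE))
  if (n_tab > n_com) "\t" else ","
}
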