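#' Read an expression matrix and sample sheet
#'
#' Reads a tab-separated log2-scale expression matrix (first column `gene_id`,
#' one column per sample) together with a sample sheet binding samples to
#' cohorts and drug-response conditions. All downstream stages consume the
#' tidy tibble this returns: `gene_id` plus one numeric column per sample.
#'
#' @param matrix_path Path to the expression TSV. First column must be named
#'   `gene_id`; remaining columns are sample ids. Cells must be decimal
#'   numbers (no thousands separators); missing values are rejected.
#' @param sheet_path Path to the sample-sheet TSV with columns
#'   `sample_id`, `cohort_id`, `condition` (`sensitive` or `resistant`).
#'   Optional; when `NULL` only the matrix is read.
#' @param collapse Collapse duplicated gene ids by keeping the
#'   maximum-variance row (see [collapse_duplicates()])? If `FALSE`
#'   (default) duplicated gene ids are an error.
#' @param from_linear If `TRUE` values are treated as linear-scale counts and
#'   log2(x + 1)-transformed at load. Default `FALSE` (input already log2).
#'
#' @return A list with elements `expression` (tibble, `gene_id` + sample
#'   columns) and `samples` (tibble, the sheet; `NULL` when no sheet given).
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("gene_id\ts1\ts2", "TP53\t8.1\t8.3", "MYC\t10\t11"), tf)
#' read_expression(tf)$expression
#' @export
read_expression <- function(matrix_path, sheet_path = NULL, collapse = FALSE,
                            from_linear = FALSE) {
  raw <- readr::read_tsv(matrix_path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (ncol(raw) < 2L) abort("expression TSV needs a gene_id column plus >=1 sample column")
  names(raw)[1] <- "gene_id"
  vals <- purrr::map(raw[-1], function(col) {
    suppressWarnings(as.numeric(col))
  })
  for (s in names(vals)) {
    bad <- which(is.na(vals[[s]]))
    if (length(bad)) {
      abort(sprintf(
        "non-numeric or missing value in sample '%s' at gene '%s' (row %d)",
        s, raw$gene_id[bad[1]], bad[1]
      ))
    }
  }
  expr <- dplyr::bind_cols(tibble(gene_id = raw$gene_id), as_tibble(vals))
  if (from_linear) {
    expr <- dplyr::mutate(expr, dplyr::across(-"gene_id", ~ log2(.x + 1)))
  }
  if (anyDuplicated(expr$gene_id)) {
    if (collapse) {
      expr <- collapse_duplicates(expr)
    } else {
      dup <- unique(expr$gene_id[duplicated(expr$gene_id)])
      abort(sprintf(
        "duplicate gene ids (%s); pass collapse = TRUE to keep max-variance rows",
        paste(head(dup, 5), collapse = ", ")
      ))
    }
  }
  assert_expression(expr)

  samples <- NULL
  if (!is.null(sheet_path)) {
    samples <- readr::read_tsv(sheet_path,
                               col_types = readr::cols(.default = "c"),
                               progress = FALSE)
    assert_sample_sheet(samples)
    missing <- setdiff(samples$sample_id, names(expr)[-1])
    if (length(missing)) {
      abort(sprintf("sample sheet sample(s) absent from matrix columns: %s",
                    paste(missing, collapse = ", ")))
    }
  }
  list(expression = expr, samples = samples)
}

#' Write an expression matrix to TSV
#'
#' Inverse of [read_expression()]: `gene_id` first column, one column per
#' sample, full double precision (round-trips bitwise through
#' [read_expression()]).
#'
#' @param expression Expression tibble (`gene_id` + numeric sample columns).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expression, path) {
  assert_expression(expression)
  readr::write_tsv(expression, path, progress = FALSE)
  invisible(path)
}

#' Write a sample sheet to TSV
#'
#' @param samples Sample-sheet tibble (`sample_id`, `cohort_id`, `condition`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(samples, path) {
  assert_sample_sheet(samples)
  readr::write_tsv(samples[c("sample_id", "cohort_id", "condition")], path,
                   progress = FALSE)
  invisible(path)
}

#' Collapse duplicated gene ids to their maximum-variance row
#'
#' Array platforms report several probes per gene symbol; this keeps, for each
#' duplicated `gene_id`, the row with maximal variance across samples (the
#' common probe-collapse convention). Ties keep the first occurrence. Row
#' order of first occurrences is preserved.
#'
#' @param expression Expression tibble, possibly with repeated `gene_id`s.
#' @return Expression tibble with unique `gene_id`s.
#' @export
collapse_duplicates <- function(expression) {
  stopifnot(is_expression_tbl(expression))
  m <- expr_matrix(expression)
  rv <- apply(m, 1L, var)
  keep <- expression |>
    dplyr::mutate(.row = dplyr::row_number(), .var = rv) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::slice_max(.data$.var, n = 1L, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$.row) |>
    dplyr::select(-".row", -".var")
  keep
}

#' Quantile-normalize an expression matrix
#'
#' Forces every sample (column) onto the common reference distribution: after
#' normalization each sample's sorted value vector equals the mean of all
#' samples' sorted vectors, with ties within a sample receiving the mean of
#' the reference values they span. This is the deterministic
#' between-array standardization applied to each cohort-pair dataset before
#' differential expression; it is never applied across datasets. Delegates to
#' \code{limma::normalizeBetweenArrays(method = "quantile")}.
#'
#' @param expression Expression tibble with at least 2 sample columns
#'   (a single sample is returned unchanged with a warning).
#' @return Quantile-normalized expression tibble, same genes and samples.
#' @examples
#' x <- tibble::tibble(gene_id = c("A", "B", "C"),
#'                     s1 = c(1, 3, 5), s2 = c(2, 4, 6))
#' quantile_normalize(x)
#' @export
quantile_normalize <- function(expression) {
  assert_expression(expression)
  m <- expr_matrix(expression)
  if (ncol(m) < 2L) {
    warn("quantile_normalize: single sample, returning input unchanged")
    return(expression)
  }
  norm <- limma::normalizeBetweenArrays(m, method = "quantile")
  dimnames(norm) <- dimnames(m)
  expr_tbl(norm)
}

#' Derive sensitive/resistant cohort pairs from a sample sheet
#'
#' @param samples Sample-sheet tibble.
#' @return Tibble with one row per cohort: `cohort_id`, list-columns
#'   `sensitive` and `resistant` of sample ids, and counts `n_sensitive`,
#'   `n_resistant`.
#' @export
cohort_pairs <- function(samples) {
  assert_sample_sheet(samples)
  out <- samples |>
    dplyr::group_by(.data$cohort_id) |>
    dplyr::summarise(
      sensitive = list(.data$sample_id[.data$condition == "sensitive"]),
      resistant = list(.data$sample_id[.data$condition == "resistant"]),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      n_sensitive = lengths(.data$sensitive),
      n_resistant = lengths(.data$resistant)
    ) |>
    dplyr::arrange(.data$cohort_id)
  bad <- out$cohort_id[out$n_sensitive == 0L | out$n_resistant == 0L]
  if (length(bad)) {
    abort(sprintf("cohort(s) missing a sensitive or resistant arm: %s",
                  paste(bad, collapse = ", ")))
  }
  out
}
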