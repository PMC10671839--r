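# shared internal helpers: symbol normalization, expression-table accessors,
# seed handling

# gene symbols are matched as uppercased, whitespace-stripped tokens at every
# set boundary; no alias resolution is attempted
normalize_symbols <- function(x) toupper(trimws(as.character(x)))

is_expression_tbl <- function(x) {
  is.data.frame(x) && ncol(x) >= 2L && names(x)[1] == "gene_id"
}

# genes-by-samples numeric matrix view of an expression tibble
expr_matrix <- function(x) {
  stopifnot(is_expression_tbl(x))
  m <- as.matrix(x[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- x$gene_id
  m
}

# rebuild the tidy container from a genes-by-samples matrix
expr_tbl <- function(m) {
  out <- as_tibble(m, .name_repair = "minimal")
  dplyr::bind_cols(tibble(gene_id = rownames(m)), out)
}

assert_expression <- function(x, arg = "expression") {
  if (!is_expression_tbl(x)) {
    abort(sprintf(
      "`%s` must be a data frame whose first column is `gene_id` followed by numeric sample columns.",
      arg
    ))
  }
  m <- expr_matrix(x)
  if (!all(is.finite(m))) {
    bad <- which(!is.finite(m), arr.ind = TRUE)[1, ]
    abort(sprintf(
      "`%s` contains a non-finite value at gene '%s', sample '%s'.",
      arg, rownames(m)[bad[1]], colnames(m)[bad[2]]
    ))
  }
  invisible(x)
}

assert_sample_sheet <- function(sheet, arg = "samples") {
  req <- c("sample_id", "cohort_id", "condition")
  if (!is.data.frame(sheet) || !all(req %in% names(sheet))) {
    abort(sprintf("`%s` must have columns sample_id, cohort_id, condition.", arg))
  }
  if (anyDuplicated(sheet$sample_id)) {
    abort(sprintf(
      "duplicate sample_id in `%s`: %s", arg,
      paste(unique(sheet$sample_id[duplicated(sheet$sample_id)]), collapse = ", ")
    ))
  }
  bad <- setdiff(unique(sheet$condition), c("sensitive", "resistant"))
  if (length(bad)) {
    abort(sprintf("`%s` condition must be 'sensitive' or 'resistant'; found: %s",
                  arg, paste(bad, collapse = ", ")))
  }
  invisible(sheet)
}

# run `code` under a fixed RNG state without disturbing the caller's stream
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed) %% .Machine$integer.max, code)
}

# derive a distinct reproducible child seed from a master seed
child_seed <- function(seed, offset) {
  (as.integer(seed) + 1013L * as.integer(offset)) %% .Machine$integer.max
}
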