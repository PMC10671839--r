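#' Read a GMT gene-set collection
#'
#' Standard tab-separated GMT: set name, description, then member genes.
#' Symbols are uppercased and whitespace-stripped; set names must be unique.
#'
#' @param path GMT file path.
#' @return Named list of character vectors (one per set).
#' @export
read_gmt <- function(path) {
  sets <- fgsea::gmtPathways(path)
  if (anyDuplicated(names(sets))) abort("duplicate set names in GMT")
  lapply(sets, function(g) unique(normalize_symbols(g)))
}

#' Write a GMT gene-set collection
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional character vector of set descriptions
#'   (defaults to the set names).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  descriptions <- descriptions %||% names(sets)
  lines <- purrr::map2_chr(names(sets), seq_along(sets), function(nm, i) {
    paste(c(nm, descriptions[i], sets[[i]]), collapse = "\t")
  })
  writeLines(lines, path)
  invisible(path)
}

#' The packaged literature list of lipid-metabolism resistance genes
#'
#' Nine lipid-metabolism enzymes repeatedly implicated in cancer drug
#' resistance (acetyl-CoA/fatty-acid synthesis and carnitine shuttle genes),
#' shipped as a GMT resource that users may replace with their own curation.
#'
#' @return Character vector of gene symbols.
#' @export
literature_genes <- function() {
  path <- system.file("extdata", "literature_lipid_resistance.gmt",
                      package = "paxscreen")
  read_gmt(path)[["lipid_resistance_literature"]]
}

#' Read a scored interaction-edge table
#'
#' Tab-separated `gene_a  gene_b  score` undirected edges. Scores on the
#' 0-1000 integer convention are auto-detected (any score > 1) and divided
#' by 1000. Self-loops are dropped; duplicate undirected edges collapse to
#' their maximum score.
#'
#' @param path Edge TSV path.
#' @return Tibble: `gene_a`, `gene_b` (uppercased, `gene_a < gene_b`),
#'   `score` in \[0, 1\].
#' @export
read_interactions <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    gene_a = "c", gene_b = "c", score = "d"), progress = FALSE)
  as_interaction_table(x)
}

#' Canonicalize an interaction-edge table
#'
#' @param edges Data frame with `gene_a`, `gene_b`, `score`.
#' @return Deduplicated undirected edge tibble with scores in \[0, 1\].
#' @export
as_interaction_table <- function(edges) {
  stopifnot(all(c("gene_a", "gene_b", "score") %in% names(edges)))
  a <- normalize_symbols(edges$gene_a)
  b <- normalize_symbols(edges$gene_b)
  score <- edges$score
  if (any(score < 0)) abort("negative interaction scores")
  if (any(score > 1)) score <- score / 1000  # STRING 0-1000 convention
  if (any(score > 1)) abort("interaction scores exceed 1 even after rescaling")
  keep <- a != b
  out <- tibble(gene_a = pmin(a, b)[keep], gene_b = pmax(a, b)[keep],
                score = score[keep])
  if (!nrow(out)) return(out)
  out |>
    dplyr::group_by(.data$gene_a, .data$gene_b) |>
    dplyr::summarise(score = max(.data$score), .groups = "drop")
}

#' Genes co-upregulated with an anchor gene in patients
#'
#' Splits patients at the median expression of the anchor gene
#' ([median_split()]), runs the moderated-t two-group comparison of high
#' versus low for every gene, and returns genes passing
#' `log2fc >= synergy_lfc` and `p <= synergy_p` (inclusive).
#'
#' @param expression Patient expression tibble (log2; `gene_id` + patients).
#' @param anchor Anchor gene symbol (must be present).
#' @param config [screen_config()].
#' @return Tibble of passing genes: `gene`, `log2fc`, `p`, sorted by gene;
#'   the anchor symbol is stored in the `anchor` attribute and the full DE
#'   table in the `de` attribute.
#' @export
co_upregulated_genes <- function(expression, anchor, config = screen_config()) {
  assert_expression(expression)
  anchor <- normalize_symbols(anchor)
  genes <- normalize_symbols(expression$gene_id)
  idx <- which(genes == anchor)
  if (!length(idx)) abort(sprintf("anchor gene '%s' absent from expression matrix", anchor))
  m <- expr_matrix(expression)
  rownames(m) <- genes
  grp <- median_split(m[idx[1], ])
  mh <- m[, grp == "high", drop = FALSE]
  ml <- m[, grp == "low", drop = FALSE]
  st <- pooled_stats_matrix(mh, ml)
  prior <- fit_variance_prior(st$s_sq, st$df[1])
  mo <- moderate_stats(st$log2fc, st$s_sq, st$df[1], st$v, prior)
  de <- tibble(gene = st$gene, log2fc = st$log2fc, t = mo$t, df = mo$df, p = mo$p)
  out <- de |>
    dplyr::filter(.data$log2fc >= config$synergy_lfc,
                  .data$p <= config$synergy_p) |>
    dplyr::select("gene", "log2fc", "p") |>
    dplyr::arrange(.data$gene)
  attr(out, "anchor") <- anchor
  attr(out, "de") <- de
  out
}

# accept a character set or a tibble with a `gene` column
as_gene_set <- function(x) {
  g <- if (is.data.frame(x)) x$gene else x
  unique(normalize_symbols(g))
}

#' Three-way gene-set intersection
#'
#' Intersects the co-upregulated gene set with two named gene sets
#' (by default the lipid-metabolism and oncological sets) to obtain the
#' synergy gene set. All symbols are case-normalized before intersecting.
#'
#' @param co_up Character vector or tibble with a `gene` column.
#' @param gene_sets Named list of gene sets (e.g. from [read_gmt()]).
#' @param set_names The two set names to intersect with.
#' @return Sorted character vector.
#' @export
triple_intersection <- function(co_up, gene_sets,
                                set_names = c("lipid_metabolism", "oncological")) {
  missing <- setdiff(set_names, names(gene_sets))
  if (length(missing)) {
    abort(sprintf("gene set(s) missing from collection: %s",
                  paste(missing, collapse = ", ")))
  }
  out <- as_gene_set(co_up)
  for (nm in set_names) out <- intersect(out, normalize_symbols(gene_sets[[nm]]))
  sort(out)
}

#' High-confidence interaction core around an anchor gene
#'
#' Keeps the synergy genes with a direct interaction edge to the anchor whose
#' score is strictly greater than `ppi_score`, plus the anchor itself
#' (multi-hop connectivity does not count).
#'
#' @param synergy Synergy gene set (character or tibble with `gene`).
#' @param anchor Anchor gene symbol.
#' @param edges Interaction tibble from [read_interactions()] /
#'   [as_interaction_table()].
#' @param config [screen_config()].
#' @return Sorted character vector including the anchor.
#' @export
ppi_core_filter <- function(synergy, anchor, edges, config = screen_config()) {
  anchor <- normalize_symbols(anchor)
  syn <- as_gene_set(synergy)
  edges <- as_interaction_table(edges)
  touching <- edges[(edges$gene_a == anchor | edges$gene_b == anchor) &
                      edges$score > config$ppi_score, ]
  partners <- setdiff(unique(c(touching$gene_a, touching$gene_b)), anchor)
  sort(unique(c(anchor, intersect(syn, partners))))
}

#' Select lipid-metabolism resistance genes (LRGs)
#'
#' Intersects the interaction core with a literature-curated list of
#' lipid-metabolism drug-resistance genes and removes the anchor, yielding
#' the genes proposed to act synergistically with the anchor.
#'
#' @param core Core gene set from [ppi_core_filter()].
#' @param anchor Anchor gene symbol (removed from the result).
#' @param literature Literature gene list (default the packaged
#'   [literature_genes()]).
#' @return Sorted character vector.
#' @export
lrg_select <- function(core, anchor, literature = literature_genes()) {
  if (!length(literature)) abort("literature list is empty")
  anchor <- normalize_symbols(anchor)
  sort(setdiff(intersect(as_gene_set(core), normalize_symbols(literature)),
               anchor))
}

#' Full synergy analysis around an anchor gene
#'
#' Chains [co_upregulated_genes()], [triple_intersection()],
#' [ppi_core_filter()] and [lrg_select()].
#'
#' @inheritParams co_upregulated_genes
#' @inheritParams ppi_core_filter
#' @inheritParams lrg_select
#' @param gene_sets Named list with `lipid_metabolism` and `oncological` sets.
#' @return Object of class `paxs_synergy`: list with `anchor`, `co_up`
#'   (tibble), `synergy`, `core`, `lrgs` (character vectors).
#' @export
synergy_analysis <- function(expression, anchor, gene_sets, edges,
                             literature = literature_genes(),
                             config = screen_config()) {
  co_up <- co_upregulated_genes(expression, anchor, config)
  synergy <- triple_intersection(co_up, gene_sets)
  core <- ppi_core_filter(synergy, anchor, edges, config)
  lrgs <- lrg_select(core, anchor, literature)
  structure(list(anchor = normalize_symbols(anchor), co_up = co_up,
                 synergy = synergy, core = core, lrgs = lrgs),
            class = "paxs_synergy")
}

#' @export
print.paxs_synergy <- function(x, ...) {
  cat(sprintf("Synergy analysis around %s\n", x$anchor))
  cat(sprintf("  co-upregulated genes: %d\n", nrow(x$co_up)))
  cat(sprintf("  synergy set (triple intersection): %d\n", length(x$synergy)))
  cat(sprintf("  interaction core: %d node(s)\n", length(x$core)))
  cat(sprintf("  LRGs: %s\n",
              if (length(x$lrgs)) paste(x$lrgs, collapse = ", ") else "(none)"))
  invisible(x)
}
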