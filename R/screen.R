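#' Screening thresholds
#'
#' Bundles every threshold used by the consensus screen and the downstream
#' synergy analysis. Defaults are the screen's operating point: a cohort
#' votes "up" when `log2fc >= up_lfc` (1.0) and `p <= up_p` (0.05); a
#' candidate must collect `min_support` (3) votes and never fall below
#' `floor_lfc` (-0.2) in the non-voting cohorts; resistance genes (PRGs) are
#' candidates with support strictly above `min_support`. Synergy co-up
#' screening uses `synergy_lfc` (0.6) and `synergy_p` (0.05); interaction
#' core filtering keeps edges with score strictly above `ppi_score` (0.7).
#'
#' @param up_lfc,up_p Up-regulation vote thresholds (inclusive).
#' @param floor_lfc No-downregulation floor for non-voting cohorts (inclusive).
#' @param min_support Minimum number of voting cohorts for candidacy.
#' @param synergy_lfc,synergy_p Co-upregulation thresholds (inclusive).
#' @param ppi_score Interaction-score cutoff (strict).
#' @return List of class `paxs_config`.
#' @export
screen_config <- function(up_lfc = 1, up_p = 0.05, floor_lfc = -0.2,
                          min_support = 3L, synergy_lfc = 0.6,
                          synergy_p = 0.05, ppi_score = 0.7) {
  cfg <- list(up_lfc = up_lfc, up_p = up_p, floor_lfc = floor_lfc,
              min_support = as.integer(min_support),
              synergy_lfc = synergy_lfc, synergy_p = synergy_p,
              ppi_score = ppi_score)
  if (!(cfg$up_lfc > 0 && cfg$floor_lfc < 0)) {
    abort("need up_lfc > 0 > floor_lfc")
  }
  for (p in c(cfg$up_p, cfg$synergy_p)) {
    if (!(p > 0 && p < 1)) abort("p thresholds must lie in (0, 1)")
  }
  if (cfg$min_support < 1L) abort("min_support must be >= 1")
  if (cfg$ppi_score < 0 || cfg$ppi_score > 1) abort("ppi_score must lie in [0, 1]")
  structure(cfg, class = "paxs_config")
}

#' @export
print.paxs_config <- function(x, ...) {
  cat("Screen thresholds:\n")
  cat(sprintf("  vote:    log2fc >= %g & p <= %g, support >= %d (floor %g)\n",
              x$up_lfc, x$up_p, x$min_support, x$floor_lfc))
  cat(sprintf("  synergy: log2fc >= %g & p <= %g; interaction score > %g\n",
              x$synergy_lfc, x$synergy_p, x$ppi_score))
  invisible(x)
}

#' Per-cohort up-regulation votes
#'
#' Marks, for every gene-by-cohort pair of a differential-expression table,
#' whether the gene is significantly up-regulated in that resistant cohort
#' (`log2fc >= up_lfc` and `p <= up_p`, both inclusive). Gene/cohort pairs
#' missing from the table (gene not on that platform) carry `up = NA`,
#' distinct from a failed vote.
#'
#' @param de Differential-expression tibble from [moderated_t_table()]
#'   (columns `gene`, `cohort`, `log2fc`, `p`).
#' @param config [screen_config()].
#' @return Tibble `gene` x `cohort` with columns `log2fc`, `p`, `up`
#'   (logical, `NA` when unmeasured), complete over all gene/cohort pairs.
#' @export
cohort_up_flags <- function(de, config = screen_config()) {
  stopifnot(all(c("gene", "cohort", "log2fc", "p") %in% names(de)))
  de |>
    dplyr::select("gene", "cohort", "log2fc", "p") |>
    tidyr::complete(gene = unique(de$gene), cohort = unique(de$cohort)) |>
    dplyr::mutate(
      up = !is.na(.data$log2fc) & !is.na(.data$p) &
        .data$log2fc >= config$up_lfc & .data$p <= config$up_p,
      up = dplyr::if_else(is.na(.data$log2fc), NA, .data$up)
    )
}

#' Consensus candidate screen across resistant cohorts
#'
#' The core selection rule: a gene is a candidate resistance gene when it is
#' significantly up-regulated in at least `min_support` resistant cohorts
#' (the "votes") and meets the `log2fc >= floor_lfc` floor in every measured
#' cohort where it did not vote — i.e. it is never materially down-regulated
#' elsewhere. Genes measured in fewer than half the cohorts (`< ceiling(n/2)`)
#' are excluded from candidacy with a warning.
#'
#' @inheritParams cohort_up_flags
#' @return Tibble of class `paxs_candidates`, one row per gene: `gene`,
#'   `support`, `n_measured`, `floor_ok`, `is_candidate`, `flags` (one
#'   character per cohort in sorted order: `1` vote, `0` no vote, `.`
#'   unmeasured). Cohort order is recorded in the `cohorts` attribute.
#' @export
candidate_screen <- function(de, config = screen_config()) {
  flags <- cohort_up_flags(de, config)
  cohorts <- sort(unique(flags$cohort))
  n_cohorts <- length(cohorts)
  min_measured <- ceiling(n_cohorts / 2)
  out <- flags |>
    dplyr::arrange(.data$gene, .data$cohort) |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(
      support = sum(.data$up, na.rm = TRUE),
      n_measured = sum(!is.na(.data$up)),
      floor_ok = all(.data$log2fc[!is.na(.data$up) & !.data$up] >= config$floor_lfc),
      flags = paste(dplyr::case_when(is.na(.data$up) ~ ".",
                                     .data$up ~ "1",
                                     TRUE ~ "0"), collapse = ""),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      is_candidate = .data$support >= config$min_support & .data$floor_ok &
        .data$n_measured >= min_measured
    )
  n_excluded <- sum(out$n_measured < min_measured)
  if (n_excluded > 0L) {
    warn(sprintf(
      "%d gene(s) measured in fewer than %d of %d cohorts were excluded from candidacy",
      n_excluded, min_measured, n_cohorts
    ))
  }
  out <- dplyr::relocate(out, "gene", "support", "n_measured", "floor_ok",
                         "is_candidate", "flags")
  attr(out, "cohorts") <- cohorts
  class(out) <- c("paxs_candidates", class(out))
  out
}

#' Rank candidates by vote frequency and select resistance genes
#'
#' Candidates are ranked by their support (number of cohorts voting "up"),
#' descending, ties broken lexicographically by gene id; ranks run 1..n over
#' candidates. The highest-ranking candidates — those with support strictly
#' greater than `min_support` — are selected as paclitaxel resistance-related
#' genes (PRGs).
#'
#' @param candidates Output of [candidate_screen()].
#' @param config [screen_config()].
#' @return The candidate tibble with `rank` (NA for non-candidates) and
#'   `is_prg` columns, candidates first in rank order.
#' @export
rank_and_select_prgs <- function(candidates, config = screen_config()) {
  stopifnot(all(c("gene", "support", "is_candidate") %in% names(candidates)))
  if (!any(candidates$is_candidate)) {
    warn("no candidate genes; empty PRG set")
  }
  at <- attr(candidates, "cohorts")
  out <- candidates |>
    dplyr::arrange(dplyr::desc(.data$is_candidate),
                   dplyr::desc(.data$support), .data$gene) |>
    dplyr::mutate(
      rank = dplyr::if_else(.data$is_candidate,
                            cumsum(.data$is_candidate), NA_integer_),
      is_prg = .data$is_candidate & .data$support > config$min_support
    )
  if (any(out$is_candidate) && !any(out$is_prg)) {
    warn("no candidate exceeds min_support; PRG set is empty")
  }
  attr(out, "cohorts") <- at
  class(out) <- unique(c("paxs_candidates", class(out)))
  out
}

#' Write a candidate table to TSV
#'
#' @param candidates Output of [candidate_screen()] / [rank_and_select_prgs()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_candidates <- function(candidates, path) {
  cols <- intersect(c("gene", "support", "is_candidate", "is_prg", "rank", "flags"),
                    names(candidates))
  readr::write_tsv(candidates[cols], path, progress = FALSE)
  invisible(path)
}
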