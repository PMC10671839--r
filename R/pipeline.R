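# configuration-driven orchestration: screen / synergy / assay stages with
# manifests and machine-readable reports

config_known_keys <- c(
  "version", "seed", "out", "anchor", "thresholds",
  "screen", "synergy", "assay", "stages"
)

#' Read and validate a run configuration
#'
#' YAML with a versioned schema. Top-level keys: `seed`, `out`, `anchor`,
#' `thresholds` (any [screen_config()] field), and per-stage input blocks
#' `screen` (`expression`, `samples`), `synergy` (`expression`, `survival`,
#' `gene_sets`, `interactions`, optional `literature`), `assay`
#' (`dose_response`: named condition -> CSV path; optional `ri_pairs`:
#' list of `resistant`/`sensitive` condition names). Unknown keys are
#' rejected; referenced files must exist.
#'
#' @param path YAML file path, or a list already in the schema's shape.
#' @return Validated config list of class `paxs_run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), config_known_keys)
  if (length(unknown)) {
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  cfg$version <- cfg$version %||% 1L
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$thresholds <- do.call(screen_config, cfg$thresholds %||% list())
  for (stage in c("screen", "synergy", "assay")) {
    blk <- cfg[[stage]]
    if (is.null(blk)) next
    paths <- unlist(blk[names(blk) %in%
                          c("expression", "samples", "survival", "gene_sets",
                            "interactions", "literature")], use.names = FALSE)
    paths <- c(paths, unlist(blk$dose_response, use.names = FALSE))
    missing <- paths[!file.exists(paths)]
    if (length(missing)) {
      abort(sprintf("[%s] input file(s) not found: %s", stage,
                    paste(missing, collapse = ", ")))
    }
  }
  structure(cfg, class = c("paxs_run_config", "list"))
}

stage_log <- function(stage, level, msg) {
  message(sprintf("[%s] %s: %s", stage, level, msg))
}

write_manifest <- function(out_dir, stage, cfg, inputs, outputs) {
  cfg_plain <- unclass(cfg)
  cfg_plain$thresholds <- unclass(cfg_plain$thresholds)
  cfg_plain$out <- NULL  # hash the analysis config, not the output location
  cfg_json <- jsonlite::toJSON(cfg_plain, auto_unbox = TRUE, digits = NA)
  tf <- tempfile(); writeLines(cfg_json, tf)
  checksum <- function(paths) {
    as.list(setNames(vapply(paths, function(p) unname(tools::md5sum(p)),
                            character(1)), basename(paths)))
  }
  manifest <- list(
    stage = stage,
    package_version = as.character(utils::packageVersion("paxscreen")),
    seed = cfg$seed,
    config_md5 = unname(tools::md5sum(tf)),
    inputs = checksum(inputs),
    outputs = checksum(outputs)
  )
  unlink(tf)
  path <- file.path(out_dir, sprintf("manifest_%s.json", stage))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE)
  invisible(path)
}

#' Run the consensus-screen stage
#'
#' Loads the cell-line expression matrix and sample sheet, quantile-
#' normalizes each cohort-pair dataset, computes per-cohort moderated-t
#' differential expression, applies the consensus candidate screen, and
#' ranks/selects resistance genes. Writes `candidates.tsv`,
#' `screen_summary.json` and a stage manifest when `out` is configured.
#'
#' @param config Path to a YAML run config, or a config list
#'   (see [read_run_config()]).
#' @return List (invisible): `candidates` tibble, `de` table, `summary`.
#' @export
run_screen <- function(config) {
  cfg <- read_run_config(config)
  if (is.null(cfg$screen)) abort("[screen] config block missing")
  stage_log("screen", "info", "loading expression and sample sheet")
  inp <- read_expression(cfg$screen$expression, cfg$screen$samples)
  pairs <- cohort_pairs(inp$samples)
  stage_log("screen", "info",
            sprintf("normalizing and testing %d cohort(s)", nrow(pairs)))
  de <- purrr::map(pairs$cohort_id, function(co) {
    ids <- inp$samples$sample_id[inp$samples$cohort_id == co]
    sub <- inp$expression[c("gene_id", ids)]
    norm <- quantile_normalize(sub)
    moderated_t_table(norm, inp$samples, cohorts = co)
  }) |> purrr::list_rbind()
  cand <- candidate_screen(de, cfg$thresholds) |>
    rank_and_select_prgs(cfg$thresholds)
  summary <- list(
    n_genes = dplyr::n_distinct(de$gene),
    n_cohorts = dplyr::n_distinct(de$cohort),
    n_candidates = sum(cand$is_candidate),
    prgs = cand$gene[cand$is_prg],
    thresholds = unclass(cfg$thresholds)
  )
  if (summary$n_candidates == 0L) stage_log("screen", "warn", "zero candidates")
  stage_log("screen", "info", sprintf("%d candidates, %d PRGs",
                                      summary$n_candidates, length(summary$prgs)))
  if (!is.null(cfg$out)) {
    dir.create(cfg$out, recursive = TRUE, showWarnings = FALSE)
    out_tsv <- file.path(cfg$out, "candidates.tsv")
    out_json <- file.path(cfg$out, "screen_summary.json")
    write_candidates(cand, out_tsv)
    jsonlite::write_json(summary, out_json, auto_unbox = TRUE, digits = NA)
    write_manifest(cfg$out, "screen", cfg,
                   c(cfg$screen$expression, cfg$screen$samples),
                   c(out_tsv, out_json))
  }
  invisible(list(candidates = cand, de = de, summary = summary))
}

#' Run the synergy-discovery stage
#'
#' Loads the patient expression matrix, survival table, gene sets and
#' interaction edges; splits patients at the anchor's median expression;
#' screens co-upregulated genes; intersects with the lipid-metabolism and
#' oncological sets; filters the high-confidence interaction core; selects
#' LRGs; and computes Kaplan-Meier curves with a log-rank test for the
#' anchor and each LRG. Writes `synergy.json`, per-gene KM TSVs and a
#' manifest when `out` is configured.
#'
#' @inheritParams run_screen
#' @return List (invisible): `synergy` (`paxs_synergy`), `survival_tests`
#'   tibble, `km` curves list.
#' @export
run_synergy <- function(config) {
  cfg <- read_run_config(config)
  if (is.null(cfg$synergy)) abort("[synergy] config block missing")
  if (is.null(cfg$anchor)) abort("[synergy] anchor gene not configured")
  stage_log("synergy", "info", "loading patient data")
  expr <- read_expression(cfg$synergy$expression)$expression
  surv <- read_survival(cfg$synergy$survival)
  sets <- read_gmt(cfg$synergy$gene_sets)
  edges <- read_interactions(cfg$synergy$interactions)
  literature <- if (!is.null(cfg$synergy$literature)) {
    lit <- read_gmt(cfg$synergy$literature)
    lit[[1]]
  } else {
    literature_genes()
  }
  syn <- synergy_analysis(expr, cfg$anchor, sets, edges, literature,
                          cfg$thresholds)
  stage_log("synergy", "info",
            sprintf("synergy %d, core %d, LRGs: %s", length(syn$synergy),
                    length(syn$core), paste(syn$lrgs, collapse = ", ")))

  m <- expr_matrix(expr)
  rownames(m) <- normalize_symbols(rownames(m))
  surv_genes <- intersect(c(syn$anchor, syn$lrgs), rownames(m))
  km_list <- list()
  tests <- purrr::map(surv_genes, function(g) {
    vals <- m[g, surv$patient_id[surv$patient_id %in% colnames(m)]]
    recs <- dplyr::semi_join(surv, tibble(patient_id = names(vals)),
                             by = "patient_id")
    recs$group <- median_split(vals[recs$patient_id])
    km_list[[g]] <<- km_estimate(recs)
    lr <- log_rank_test(recs)
    tibble(gene = g, chi_sq = lr$chi_sq, p = lr$p)
  }) |> purrr::list_rbind()

  if (!is.null(cfg$out)) {
    dir.create(cfg$out, recursive = TRUE, showWarnings = FALSE)
    outs <- character(0)
    for (g in names(km_list)) {
      p <- file.path(cfg$out, sprintf("km_%s.tsv", g))
      readr::write_tsv(as_tibble(km_list[[g]]), p, progress = FALSE)
      outs <- c(outs, p)
    }
    out_json <- file.path(cfg$out, "synergy.json")
    jsonlite::write_json(
      list(anchor = syn$anchor, n_co_up = nrow(syn$co_up),
           n_synergy = length(syn$synergy), core = syn$core,
           lrgs = syn$lrgs,
           survival = purrr::transpose(as.list(tests))),
      out_json, auto_unbox = TRUE, digits = NA)
    write_manifest(cfg$out, "synergy", cfg,
                   unlist(cfg$synergy[c("expression", "survival", "gene_sets",
                                        "interactions")], use.names = FALSE),
                   c(outs, out_json))
  }
  invisible(list(synergy = syn, survival_tests = tests, km = km_list))
}

#' Run the assay-analytics stage
#'
#' Fits a 4PL dose-response curve per configured condition, tabulates
#' IC50s, and computes resistance indices for configured
#' resistant/sensitive condition pairs. Individual fit failures are
#' reported and skipped; the run continues. Writes `assay.json` and a
#' manifest when `out` is configured.
#'
#' @inheritParams run_screen
#' @return List (invisible): `fits` (named list of `paxs_4pl`), `ic50`
#'   tibble, `ri` tibble.
#' @export
run_assay <- function(config) {
  cfg <- read_run_config(config)
  if (is.null(cfg$assay) || is.null(cfg$assay$dose_response)) {
    abort("[assay] dose_response inputs missing")
  }
  fits <- list()
  for (cond in names(cfg$assay$dose_response)) {
    dat <- read_dose_response(cfg$assay$dose_response[[cond]])
    fit <- tryCatch(fit_4pl(dat), error = function(e) e)
    if (inherits(fit, "error")) {
      stage_log("assay", "warn",
                sprintf("fit failed for '%s': %s", cond, conditionMessage(fit)))
    } else {
      fits[[cond]] <- fit
      stage_log("assay", "info",
                sprintf("%s: IC50 = %.4g nM", cond, fit$ic50))
    }
  }
  ic50 <- purrr::imap(fits, function(f, nm) {
    dplyr::mutate(glance(f), condition = nm, .before = 1)
  }) |> purrr::list_rbind()
  ri <- tibble()
  for (pair in cfg$assay$ri_pairs %||% list()) {
    if (all(c(pair$resistant, pair$sensitive) %in% names(fits))) {
      ri <- dplyr::bind_rows(ri, dplyr::mutate(
        resistance_index(fits[[pair$resistant]], fits[[pair$sensitive]]),
        resistant = pair$resistant, sensitive = pair$sensitive))
    }
  }
  if (!is.null(cfg$out)) {
    dir.create(cfg$out, recursive = TRUE, showWarnings = FALSE)
    out_json <- file.path(cfg$out, "assay.json")
    jsonlite::write_json(list(ic50 = ic50, resistance_index = ri),
                         out_json, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
    write_manifest(cfg$out, "assay", cfg,
                   unlist(cfg$assay$dose_response, use.names = FALSE),
                   out_json)
  }
  invisible(list(fits = fits, ic50 = ic50, ri = ri))
}

#' Simulate a full input bundle to disk
#'
#' Convenience wrapper: builds the deterministic demonstration fixture with
#' the given seed and writes every pipeline input ([write_bundle()]).
#'
#' @param dir Target directory.
#' @param seed RNG seed.
#' @return Named vector of written paths, invisibly.
#' @export
simulate_bundle <- function(dir, seed = 1903L) {
  fx <- build_paper_fixture(seed = seed)
  write_bundle(dir, fx)
}

#' Run every configured stage
#'
#' @inheritParams run_screen
#' @return List with the per-stage results (stages without a config block
#'   are skipped).
#' @export
run_all <- function(config) {
  cfg <- read_run_config(config)
  out <- list()
  if (!is.null(cfg$screen)) out$screen <- run_screen(cfg)
  if (!is.null(cfg$synergy)) out$synergy <- run_synergy(cfg)
  if (!is.null(cfg$assay)) out$assay <- run_assay(cfg)
  invisible(out)
}
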