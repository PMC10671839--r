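#' Specification for a synthetic sensitive/resistant cell-line panel
#'
#' Describes the statistical structure the screen assumes: a shared gene
#' universe measured in several cohorts, each a paired set of sensitive and
#' resistant samples with a cohort-specific batch shift, plus resistance
#' genes planted as up-regulation in the resistant arms of chosen cohort
#' subsets.
#'
#' @param n_genes Number of genes.
#' @param n_cohorts Number of cohort pairs (default 7, the screening design).
#' @param reps_per_arm Replicates per arm per cohort (default 3).
#' @param planted Tibble with columns `gene` (index or id), `lfc`
#'   (log2 effect added to resistant arms) and `cohorts` (list-column of
#'   cohort indices). `NULL` for a null panel.
#' @param batch_scale_sd SD of per-cohort additive batch shifts (log2 units).
#' @param noise_sd Per-measurement Gaussian noise SD (log2 units).
#' @param seed RNG seed; generation is a pure function of the spec.
#' @return List of class `paxs_panel_spec`.
#' @export
panel_spec <- function(n_genes = 1000L, n_cohorts = 7L, reps_per_arm = 3L,
                       planted = NULL, batch_scale_sd = 0.5, noise_sd = 0.3,
                       seed = 1L) {
  if (reps_per_arm < 1L) abort("reps_per_arm must be >= 1")
  if (!is.null(planted)) {
    stopifnot(all(c("gene", "lfc", "cohorts") %in% names(planted)))
    bad <- unlist(planted$cohorts)
    if (any(bad < 1L | bad > n_cohorts)) abort("planted cohort index out of range")
  }
  structure(list(n_genes = as.integer(n_genes), n_cohorts = as.integer(n_cohorts),
                 reps_per_arm = as.integer(reps_per_arm), planted = planted,
                 batch_scale_sd = batch_scale_sd, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "paxs_panel_spec")
}

#' Generate a synthetic multi-cohort cell-line panel
#'
#' Baseline gene means are Normal(8, 2) on the log2 scale; each cohort adds
#' a batch shift Normal(0, `batch_scale_sd`) to all of its samples; planted
#' effects are added to the resistant arms of their listed cohorts; every
#' measurement receives Normal(0, `noise_sd`) noise. Output is byte-stable
#' given the spec (seed included).
#'
#' @param spec [panel_spec()].
#' @return List: `expression` (tibble), `samples` (sheet tibble),
#'   `pairs` ([cohort_pairs()] tibble).
#' @export
gen_cellline_panel <- function(spec) {
  stopifnot(inherits(spec, "paxs_panel_spec"))
  with_seed(spec$seed, {
    genes <- sprintf("G%05d", seq_len(spec$n_genes))
    base <- rnorm(spec$n_genes, mean = 8, sd = 2)
    cohorts <- sprintf("cohort%02d", seq_len(spec$n_cohorts))
    batch <- rnorm(spec$n_cohorts, 0, spec$batch_scale_sd)
    sheets <- purrr::map(seq_len(spec$n_cohorts), function(ci) {
      tibble(
        sample_id = c(sprintf("%s_S%d", cohorts[ci], seq_len(spec$reps_per_arm)),
                      sprintf("%s_R%d", cohorts[ci], seq_len(spec$reps_per_arm))),
        cohort_id = cohorts[ci],
        condition = rep(c("sensitive", "resistant"), each = spec$reps_per_arm)
      )
    })
    samples <- purrr::list_rbind(sheets)
    m <- matrix(base, nrow = spec$n_genes, ncol = nrow(samples),
                dimnames = list(genes, samples$sample_id))
    m <- m + rep(batch[match(samples$cohort_id, cohorts)],
                 each = spec$n_genes)
    if (!is.null(spec$planted)) {
      for (k in seq_len(nrow(spec$planted))) {
        g <- spec$planted$gene[k]
        gi <- if (is.numeric(g)) as.integer(g) else match(g, genes)
        for (ci in spec$planted$cohorts[[k]]) {
          cols <- samples$sample_id[samples$cohort_id == cohorts[ci] &
                                      samples$condition == "resistant"]
          m[gi, cols] <- m[gi, cols] + spec$planted$lfc[k]
        }
      }
    }
    if (spec$noise_sd > 0) {
      m <- m + matrix(rnorm(length(m), 0, spec$noise_sd), nrow = nrow(m))
    }
    list(expression = expr_tbl(m), samples = samples,
         pairs = cohort_pairs(samples))
  })
}

#' Specification for a synthetic patient cohort
#'
#' @param n_patients Number of patients (default 368, an ovarian-cancer
#'   cohort scale).
#' @param anchor Anchor gene symbol.
#' @param synergy_genes Tibble with `gene` and `r` (target correlation with
#'   the anchor); `NULL` for none.
#' @param n_null_genes Independent background genes.
#' @param hazard_beta Named numeric: per-SD log-hazard-ratio of driver genes
#'   (positive = worse survival). Empty for a null cohort.
#' @param censoring_rate Target fraction of censored patients (default 0.4).
#' @param baseline_hazard Baseline exponential hazard per day (default
#'   log(2)/1000: 1000-day median survival).
#' @param seed RNG seed.
#' @return List of class `paxs_patient_spec`.
#' @export
patient_spec <- function(n_patients = 368L, anchor = "CPT1A",
                         synergy_genes = NULL, n_null_genes = 100L,
                         hazard_beta = c(CPT1A = 0.7),
                         censoring_rate = 0.4,
                         baseline_hazard = log(2) / 1000, seed = 1L) {
  if (!is.null(synergy_genes)) {
    stopifnot(all(c("gene", "r") %in% names(synergy_genes)))
    if (any(abs(synergy_genes$r) >= 1)) abort("correlations must lie in (-1, 1)")
  }
  if (censoring_rate < 0 || censoring_rate >= 1) {
    abort("censoring_rate must lie in [0, 1)")
  }
  structure(list(n_patients = as.integer(n_patients),
                 anchor = normalize_symbols(anchor),
                 synergy_genes = synergy_genes,
                 n_null_genes = as.integer(n_null_genes),
                 hazard_beta = hazard_beta, censoring_rate = censoring_rate,
                 baseline_hazard = baseline_hazard, seed = as.integer(seed)),
            class = "paxs_patient_spec")
}

#' Generate a synthetic patient cohort with expression-linked survival
#'
#' The anchor gene is standard normal (z-score) around a log2 mean of 8;
#' each synergy gene is built as `r * z_anchor + sqrt(1 - r^2) * noise`, so
#' its population correlation with the anchor is exactly `r`. Survival times
#' are exponential with patient hazard
#' `h0 * exp(sum(beta_g * z_g))` over the driver genes; censoring times are
#' independent exponential with rate calibrated (numerically) so the
#' expected censored fraction matches `censoring_rate`.
#'
#' @param spec [patient_spec()].
#' @return List: `expression` (tibble, log2 scale), `survival` (tibble:
#'   `patient_id`, `time`, `event`).
#' @export
gen_patient_cohort <- function(spec) {
  stopifnot(inherits(spec, "paxs_patient_spec"))
  with_seed(spec$seed, {
    n <- spec$n_patients
    ids <- sprintf("PT%04d", seq_len(n))
    z_anchor <- rnorm(n)
    z <- list()
    z[[spec$anchor]] <- z_anchor
    if (!is.null(spec$synergy_genes)) {
      for (k in seq_len(nrow(spec$synergy_genes))) {
        g <- normalize_symbols(spec$synergy_genes$gene[k])
        r <- spec$synergy_genes$r[k]
        z[[g]] <- r * z_anchor + sqrt(1 - r^2) * rnorm(n)
      }
    }
    if (spec$n_null_genes > 0L) {
      for (g in sprintf("NULL%04d", seq_len(spec$n_null_genes))) {
        z[[g]] <- rnorm(n)
      }
    }
    m <- do.call(rbind, z) + 8
    rownames(m) <- names(z)
    colnames(m) <- ids

    lp <- rep(0, n)
    for (g in names(spec$hazard_beta)) {
      gg <- normalize_symbols(g)
      if (!gg %in% names(z)) abort(sprintf("hazard driver '%s' not generated", gg))
      lp <- lp + spec$hazard_beta[[g]] * z[[gg]]
    }
    hazard <- spec$baseline_hazard * exp(lp)
    death <- rexp(n, rate = hazard)
    if (spec$censoring_rate > 0) {
      # solve mean_i hc/(hc + h_i) = censoring_rate for the censoring rate hc
      target <- spec$censoring_rate
      f <- function(hc) mean(hc / (hc + hazard)) - target
      hc <- uniroot(f, lower = 1e-12, upper = 1e6 * max(hazard))$root
      cens <- rexp(n, rate = hc)
    } else {
      cens <- rep(Inf, n)
    }
    time <- pmin(death, cens)
    event <- as.integer(death <= cens)
    list(expression = expr_tbl(m),
         survival = tibble(patient_id = ids, time = time, event = event))
  })
}

#' Generate a synthetic scored interaction table
#'
#' Anchor-to-partner edges get high confidence scores Uniform(0.75, 0.99);
#' decoy edges between random non-partner pairs get Uniform(0.10, 0.69).
#' No self-loops; duplicate undirected edges keep the maximum score.
#'
#' @param nodes All node symbols.
#' @param anchor Anchor gene.
#' @param partners True high-confidence partners of the anchor (subset of
#'   `nodes`).
#' @param decoy_density Expected fraction of the remaining node pairs to
#'   connect with a sub-threshold edge (default 0.05).
#' @param seed RNG seed.
#' @return Interaction tibble (`gene_a`, `gene_b`, `score`).
#' @export
gen_interaction_table <- function(nodes, anchor, partners,
                                  decoy_density = 0.05, seed = 1L) {
  nodes <- unique(normalize_symbols(nodes))
  anchor <- normalize_symbols(anchor)
  partners <- unique(normalize_symbols(partners))
  if (!all(partners %in% nodes)) abort("partners must be a subset of nodes")
  with_seed(seed, {
    edges <- tibble(gene_a = anchor, gene_b = partners,
                    score = runif(length(partners), 0.75, 0.99))
    others <- setdiff(nodes, anchor)
    if (decoy_density > 0 && length(others) >= 2L) {
      pairs <- utils::combn(others, 2L)
      keep <- runif(ncol(pairs)) < decoy_density
      if (any(keep)) {
        edges <- dplyr::bind_rows(edges, tibble(
          gene_a = pairs[1, keep], gene_b = pairs[2, keep],
          score = runif(sum(keep), 0.10, 0.69)
        ))
      }
    }
    as_interaction_table(edges)
  })
}

#' Generate synthetic dose-response plate data
#'
#' Draws replicate viability readings from a 4PL curve with Gaussian noise.
#'
#' @param bottom,top,hill,ic50 True curve parameters (ic50 in nM).
#' @param doses Concentrations in nM (include 0 for untreated wells).
#' @param reps Replicates per dose.
#' @param noise_sd Gaussian noise SD on the response scale.
#' @param seed RNG seed.
#' @return Tibble: `concentration`, `replicate`, `response`.
#' @export
gen_dose_response <- function(bottom = 5, top = 100, hill = 1.2, ic50 = 800,
                              doses = c(0, 30, 100, 300, 1000, 3000, 10000),
                              reps = 3L, noise_sd = 3, seed = 1L) {
  with_seed(seed, {
    grid <- tidyr::expand_grid(concentration = sort(doses),
                               replicate = sprintf("rep%d", seq_len(reps)))
    mu <- ifelse(grid$concentration == 0, top,
                 fourpl(grid$concentration, bottom, top, hill, ic50))
    dplyr::mutate(grid, response = mu + rnorm(nrow(grid), 0, noise_sd))
  })
}

#' Write a simulated input bundle to disk
#'
#' Writes every file the pipeline consumes (expression TSVs and sample
#' sheet, patient expression and survival TSVs, gene-set GMT, interaction
#' TSV, dose-response CSVs) plus a manifest JSON recording the seed.
#'
#' @param dir Target directory (created if needed).
#' @param bundle A fixture bundle, e.g. from [build_paper_fixture()].
#' @return Named character vector of written paths, invisibly.
#' @export
write_bundle <- function(dir, bundle) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    expression = file.path(dir, "cellline_expression.tsv"),
    samples = file.path(dir, "cellline_samples.tsv"),
    patient_expression = file.path(dir, "patient_expression.tsv"),
    survival = file.path(dir, "patient_survival.tsv"),
    gene_sets = file.path(dir, "gene_sets.gmt"),
    interactions = file.path(dir, "interactions.tsv"),
    manifest = file.path(dir, "manifest.json")
  )
  write_expression(bundle$cellline$expression, paths[["expression"]])
  write_sample_sheet(bundle$cellline$samples, paths[["samples"]])
  write_expression(bundle$patient$expression, paths[["patient_expression"]])
  write_survival(bundle$patient$survival, paths[["survival"]])
  write_gmt(bundle$gene_sets, paths[["gene_sets"]])
  readr::write_tsv(bundle$interactions, paths[["interactions"]], progress = FALSE)
  for (cond in names(bundle$dose_response)) {
    p <- file.path(dir, sprintf("dose_response_%s.csv", cond))
    wide <- bundle$dose_response[[cond]] |>
      tidyr::pivot_wider(names_from = "replicate", values_from = "response") |>
      dplyr::rename(concentration_nM = "concentration")
    readr::write_csv(wide, p, progress = FALSE)
    paths[[paste0("dose_response_", cond)]] <- p
  }
  jsonlite::write_json(list(seed = bundle$seed, anchor = bundle$anchor,
                            created = "paxscreen simulate"),
                       paths[["manifest"]], auto_unbox = TRUE)
  invisible(paths)
}
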