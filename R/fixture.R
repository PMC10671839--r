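# The deterministic demonstration fixture: a complete synthetic input bundle
# whose screen/synergy outputs are known by construction (19 candidates, PRG
# supports 7/4/4, a 19-node interaction core, 4 LRGs).

fixture_candidates_16 <- c(
  "ACSS1", "AK5", "ALCAM", "CHRD", "CLDN1", "CLDN16", "GALNT10", "HERC5",
  "LAMB1", "NFE2L3", "OSTF1", "PGM2", "PODXL", "PRKD3", "SLC4A8", "THBS1"
)

fixture_partners_18 <- c(
  "ACACA", "ACADM", "ACADVL", "ACSL1", "ACSL3", "CHKB", "RORA", "EP300",
  "SCD", "HADHB", "SREBF2", "PPARG", "FASN", "HADHA", "SREBF1", "PPARA",
  "SLC25A20", "CPT2"
)

#' Build the deterministic demonstration fixture
#'
#' Produces a complete synthetic input bundle whose analysis outputs are
#' known by construction, for end-to-end validation of the pipeline:
#'
#' * a 7-cohort cell-line panel (3 replicates per arm, within-arm jitter SD
#'   0.05 so planted effects are significant essentially deterministically)
#'   in which one resistance gene (`ABCB1`) is up-regulated (log2FC 3) in
#'   all 7 cohorts, two (`CPT1A`, `ATP1B1`) in 4 cohorts, and 16 further
#'   genes (log2FC 2) in 3 cohorts each — 19 candidate genes in total, of
#'   which the three highest-ranked are resistance genes (supports 7, 4, 4);
#'   decoy genes exercise the floor rule (up in 3 cohorts but log2FC -0.5
#'   in a fourth), the effect-size threshold (log2FC 0.5), and the support
#'   threshold (up in only 2 cohorts). Every planted effect is paired with a
#'   mirrored "balancer" gene occupying the vacated expression slot, so each
#'   cohort's per-sample value distribution is balanced and per-cohort
#'   quantile normalization leaves planted fold changes intact;
#' * a 368-patient cohort in which 18 partner genes correlate with the
#'   anchor `CPT1A` (r = 0.8), `ATP1B1` correlates weakly (r = 0.32), and
#'   survival hazard increases with `CPT1A`/`FASN`/`SCD` and decreases with
#'   `ATP1B1` expression (40% censoring);
#' * lipid-metabolism and oncological gene sets, the 9-gene literature list,
#'   and an interaction table wiring the anchor to its 18 partners at score
#'   0.9 plus sub-threshold and off-target decoy edges (including one at
#'   exactly 0.7, which the strict cutoff excludes) — so the interaction
#'   core has exactly 19 nodes and the LRG selection returns
#'   ACACA, FASN, CPT2, SCD;
#' * paired sensitive/resistant dose-response plates (true IC50s 299.7 and
#'   1574 nM) and a small qPCR Ct table.
#'
#' @param seed RNG seed for the (tiny) jitter and patient sampling; the
#'   discrete outputs above are invariant to it by construction.
#' @return List with elements `seed`, `anchor`, `cellline`
#'   (`expression`, `samples`, `pairs`), `patient` (`expression`,
#'   `survival`), `gene_sets`, `literature`, `interactions`,
#'   `dose_response` (named list of tibbles), `qpcr`, and `planted`
#'   (the ground-truth gene lists).
#' @export
build_paper_fixture <- function(seed = 1903L) {
  anchor <- "CPT1A"
  n_cohorts <- 7L
  reps <- 3L

  # planted design: gene, baseline-relative lfc, voting cohorts
  plan <- dplyr::bind_rows(
    tibble(gene = "ABCB1", lfc = 3, cohorts = list(1:7)),
    tibble(gene = "CPT1A", lfc = 3, cohorts = list(1:4)),
    tibble(gene = "ATP1B1", lfc = 3, cohorts = list(c(2L, 3L, 5L, 7L))),
    purrr::map2(fixture_candidates_16, seq_along(fixture_candidates_16),
                function(g, i) {
                  tibble(gene = g, lfc = 2,
                         cohorts = list(sort(unique((c(i, i + 2, i + 4) - 1) %% 7 + 1))))
                }) |> purrr::list_rbind(),
    tibble(gene = "DECOY_FLOOR", lfc = 2, cohorts = list(1:3)),
    tibble(gene = "DECOY_FLOOR", lfc = -0.5, cohorts = list(4L)),
    tibble(gene = "DECOY_WEAK", lfc = 0.5, cohorts = list(1:3)),
    tibble(gene = "DECOY_TWO", lfc = 2, cohorts = list(1:2))
  )

  n_null <- 60L
  null_genes <- sprintf("NULLC%03d", seq_len(n_null))
  genes0 <- c(unique(plan$gene), null_genes)
  # deterministic well-separated baselines on a 0.5-log2 grid
  base0 <- 4 + ((seq_along(genes0) * 7L) %% 17L) * 0.5
  names(base0) <- genes0

  # balancers: for every planted effect, a mirror gene whose baseline is the
  # planted gene's shifted level and whose resistant arms move back down, so
  # each cohort's value distribution is unchanged by the planting
  balancers <- purrr::map(seq_len(nrow(plan)), function(k) {
    tibble(gene = sprintf("BAL%03d", k),
           base = base0[[plan$gene[k]]] + plan$lfc[k],
           lfc = -plan$lfc[k], cohorts = plan$cohorts[k])
  }) |> purrr::list_rbind()

  baselines <- c(base0, setNames(balancers$base, balancers$gene))
  effects <- dplyr::bind_rows(plan, balancers[c("gene", "lfc", "cohorts")])

  cellline <- with_seed(seed, {
    cohorts <- sprintf("cohort%02d", seq_len(n_cohorts))
    samples <- purrr::map(cohorts, function(co) {
      tibble(sample_id = c(sprintf("%s_S%d", co, seq_len(reps)),
                           sprintf("%s_R%d", co, seq_len(reps))),
             cohort_id = co,
             condition = rep(c("sensitive", "resistant"), each = reps))
    }) |> purrr::list_rbind()
    batch <- rnorm(n_cohorts, 0, 0.4)
    m <- matrix(baselines, nrow = length(baselines), ncol = nrow(samples),
                dimnames = list(names(baselines), samples$sample_id))
    m <- m + rep(batch[match(samples$cohort_id, cohorts)], each = nrow(m))
    for (k in seq_len(nrow(effects))) {
      for (ci in effects$cohorts[[k]]) {
        cols <- samples$sample_id[samples$cohort_id == cohorts[ci] &
                                    samples$condition == "resistant"]
        m[effects$gene[k], cols] <- m[effects$gene[k], cols] + effects$lfc[k]
      }
    }
    m <- m + matrix(rnorm(length(m), 0, 0.05), nrow = nrow(m))
    list(expression = expr_tbl(m), samples = samples,
         pairs = cohort_pairs(samples))
  })

  # patient cohort: anchor-correlated partners + survival drivers
  synergy_genes <- dplyr::bind_rows(
    tibble(gene = fixture_partners_18, r = 0.8),
    tibble(gene = c("LIPODECOY1", "LIPODECOY2", "LIPODECOY3"), r = 0.8),
    tibble(gene = c("COUPONLY1", "COUPONLY2"), r = 0.8),
    tibble(gene = "ATP1B1", r = 0.32)
  )
  pspec <- patient_spec(
    n_patients = 368L, anchor = anchor, synergy_genes = synergy_genes,
    n_null_genes = 100L,
    hazard_beta = c(CPT1A = 0.7, FASN = 0.5, SCD = 0.5, ATP1B1 = -0.5),
    censoring_rate = 0.4, seed = child_seed(seed, 2L)
  )
  patient <- gen_patient_cohort(pspec)

  gene_sets <- list(
    lipid_metabolism = sort(c(anchor, fixture_partners_18,
                              c("LIPODECOY1", "LIPODECOY2", "LIPODECOY3"),
                              c("LIPIDONLY1", "LIPIDONLY2"))),
    oncological = sort(c(anchor, fixture_partners_18,
                         c("LIPODECOY1", "LIPODECOY2", "LIPODECOY3"),
                         "ONCOONLY1"))
  )
  literature <- c("ACLY", "ACACA", "ACACB", "FASN", "CPT1A", "CPT1B",
                  "CPT1C", "CPT2", "SCD")

  interactions <- as_interaction_table(dplyr::bind_rows(
    tibble(gene_a = anchor, gene_b = fixture_partners_18, score = 0.9),
    tibble(gene_a = anchor, gene_b = "LIPODECOY1", score = 0.5),
    tibble(gene_a = anchor, gene_b = "LIPODECOY2", score = 0.7),  # boundary
    tibble(gene_a = anchor, gene_b = "NULL0001", score = 0.95),   # not synergy
    tibble(gene_a = "FASN", gene_b = "SCD", score = 0.9)          # not anchor
  ))

  dose_response <- list(
    sensitive = gen_dose_response(bottom = 5, top = 100, hill = 1.3,
                                  ic50 = 299.7,
                                  doses = c(0, 30, 100, 300, 1000, 3000,
                                            10000, 30000),
                                  reps = 3L, noise_sd = 2,
                                  seed = child_seed(seed, 3L)),
    resistant = gen_dose_response(bottom = 5, top = 100, hill = 1.3,
                                  ic50 = 1574,
                                  doses = c(0, 30, 100, 300, 1000, 3000,
                                            10000, 30000),
                                  reps = 3L, noise_sd = 2,
                                  seed = child_seed(seed, 4L))
  )

  qpcr <- tibble(
    sample = rep(c("resistant", "sensitive"), each = 4),
    gene = rep(c("CPT1A", "SCD", "FASN", "GAPDH"), times = 2),
    ct = c(22.0, 23.5, 23.0, 18.0,   # resistant
           24.0, 24.8, 24.6, 18.0)   # sensitive
  )

  list(
    seed = as.integer(seed), anchor = anchor,
    cellline = cellline, patient = patient,
    gene_sets = gene_sets, literature = literature,
    interactions = interactions, dose_response = dose_response, qpcr = qpcr,
    planted = list(
      candidates = sort(c("ABCB1", "CPT1A", "ATP1B1", fixture_candidates_16)),
      prgs = c("ABCB1", "CPT1A", "ATP1B1"),
      partners = sort(fixture_partners_18),
      lrgs = c("ACACA", "CPT2", "FASN", "SCD")
    )
  )
}
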