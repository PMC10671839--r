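test_that("generators are pure functions of their spec", {
  spec <- panel_spec(n_genes = 50, n_cohorts = 3, seed = 7)
  a <- gen_cellline_panel(spec)
  b <- gen_cellline_panel(spec)
  expect_identical(a, b)
  c2 <- gen_cellline_panel(panel_spec(n_genes = 50, n_cohorts = 3, seed = 8))
  expect_false(identical(a$expression, c2$expression))

  p1 <- gen_patient_cohort(patient_spec(n_patients = 60, seed = 5))
  p2 <- gen_patient_cohort(patient_spec(n_patients = 60, seed = 5))
  expect_identical(p1, p2)
})

test_that("noiseless planted panels show exact per-cohort fold changes", {
  planted <- tibble::tibble(gene = 1L, lfc = 2, cohorts = list(1:3))
  spec <- panel_spec(n_genes = 10, n_cohorts = 5, reps_per_arm = 2,
                     planted = planted, batch_scale_sd = 0.5, noise_sd = 0,
                     seed = 11)
  panel <- gen_cellline_panel(spec)
  for (co in panel$pairs$cohort_id) {
    st <- gene_pooled_stats(panel$expression, panel$samples, co)
    expected <- if (co %in% sprintf("cohort%02d", 1:3)) 2 else 0
    expect_equal(st$log2fc[1], expected, tolerance = 1e-12)
    expect_equal(st$log2fc[-1], rep(0, 9), tolerance = 1e-12)
  }
  # generated output passes load-time validation silently
  expect_silent(paxscreen:::assert_expression(panel$expression))
  expect_silent(paxscreen:::assert_sample_sheet(panel$samples))
})

test_that("patient generator hits its target correlation and censoring", {
  spec <- patient_spec(
    n_patients = 368,
    synergy_genes = tibble::tibble(gene = "TWIN", r = 0.99),
    n_null_genes = 0, hazard_beta = c(CPT1A = 0.7),
    censoring_rate = 0.4, seed = 31
  )
  cohort <- gen_patient_cohort(spec)
  m <- as.matrix(cohort$expression[-1])
  rownames(m) <- cohort$expression$gene_id
  expect_gt(cor(m["CPT1A", ], m["TWIN", ]), 0.95)
  expect_lt(abs(mean(cohort$survival$event == 0) - 0.4), 0.05)
  expect_true(all(cohort$survival$time > 0))
})

test_that("null survival cohorts give uniform log-rank p-values", {
  set.seed(1)
  ps <- vapply(1:200, function(s) {
    cohort <- gen_patient_cohort(patient_spec(
      n_patients = 80, synergy_genes = NULL, n_null_genes = 0,
      hazard_beta = c(CPT1A = 0), censoring_rate = 0.3, seed = 1000 + s
    ))
    x <- as.numeric(cohort$expression[1, -1])
    recs <- cohort$survival
    recs$group <- median_split(x)
    log_rank_test(recs)$p
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("interaction generator wires true partners above the cutoff", {
  nodes <- c("ANCH", sprintf("P%02d", 1:10), sprintf("D%02d", 1:20))
  partners <- sprintf("P%02d", 1:10)
  tab <- gen_interaction_table(nodes, "ANCH", partners,
                               decoy_density = 0.2, seed = 12)
  core <- ppi_core_filter(c(partners, sprintf("D%02d", 1:20)), "ANCH", tab)
  expect_setequal(core, c("ANCH", partners))

  none <- gen_interaction_table(nodes, "ANCH", partners,
                                decoy_density = 0, seed = 12)
  expect_equal(nrow(none), 10L)
  expect_true(all(none$score > 0.7))

  # duplicate undirected edges collapse to the max score
  dup <- tibble::tibble(gene_a = c("A", "B", "B"), gene_b = c("B", "A", "A"),
                        score = c(0.2, 0.9, 0.5))
  expect_equal(as_interaction_table(dup)$score, 0.9)
})

test_that("the demonstration fixture reproduces its designed gene lists", {
  fx <- build_paper_fixture(seed = 20240101)
  de <- purrr::map(fx$cellline$pairs$cohort_id, function(co) {
    ids <- fx$cellline$samples$sample_id[fx$cellline$samples$cohort_id == co]
    norm <- quantile_normalize(fx$cellline$expression[c("gene_id", ids)])
    moderated_t_table(norm, fx$cellline$samples, cohorts = co)
  }) |> purrr::list_rbind()
  cand <- rank_and_select_prgs(candidate_screen(de))
  expect_equal(sum(cand$is_candidate), 19L)
  expect_setequal(cand$gene[cand$is_candidate], fx$planted$candidates)
  expect_equal(sort(cand$support[cand$is_prg], decreasing = TRUE), c(7L, 4L, 4L))
  expect_setequal(cand$gene[cand$is_prg], fx$planted$prgs)

  syn <- synergy_analysis(fx$patient$expression, fx$anchor, fx$gene_sets,
                          fx$interactions, fx$literature)
  expect_length(syn$core, 19L)
  expect_setequal(syn$core, c("CPT1A", fx$planted$partners))
  expect_equal(syn$lrgs, c("ACACA", "CPT2", "FASN", "SCD"))

  # discrete outputs are invariant to the jitter seed
  fx2 <- build_paper_fixture(seed = 77)
  de2 <- purrr::map(fx2$cellline$pairs$cohort_id, function(co) {
    ids <- fx2$cellline$samples$sample_id[fx2$cellline$samples$cohort_id == co]
    norm <- quantile_normalize(fx2$cellline$expression[c("gene_id", ids)])
    moderated_t_table(norm, fx2$cellline$samples, cohorts = co)
  }) |> purrr::list_rbind()
  cand2 <- candidate_screen(de2)
  expect_setequal(cand2$gene[cand2$is_candidate], fx$planted$candidates)
})
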