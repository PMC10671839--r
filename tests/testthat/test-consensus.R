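de_row <- function(gene, cohort, lfc, p) {
  tibble::tibble(gene = gene, cohort = cohort, log2fc = lfc, p = p)
}

random_de <- function(n_genes, n_cohorts, seed) {
  set.seed(seed)
  tidyr::expand_grid(gene = sprintf("g%03d", seq_len(n_genes)),
                     cohort = sprintf("c%d", seq_len(n_cohorts))) |>
    dplyr::mutate(log2fc = rnorm(dplyr::n(), 0, 1.2),
                  p = runif(dplyr::n()))
}

test_that("up-regulation vote thresholds are inclusive", {
  de <- dplyr::bind_rows(
    de_row("A", "c1", 1.0, 0.05),   # exactly at both thresholds: vote
    de_row("B", "c1", 2.0, 0.2),    # insignificant: no vote
    de_row("C", "c1", 0.99, 0.001)  # under the fold-change bar: no vote
  )
  flags <- cohort_up_flags(de)
  expect_equal(flags$up[match(c("A", "B", "C"), flags$gene)],
               c(TRUE, FALSE, FALSE))
})

test_that("vote flags equal a brute-force row scan on random tables", {
  de <- random_de(60, 7, seed = 101)
  flags <- cohort_up_flags(de)
  ref <- de$log2fc >= 1 & de$p <= 0.05
  got <- flags$up[match(paste(de$gene, de$cohort),
                        paste(flags$gene, flags$cohort))]
  expect_equal(got, ref)
})

test_that("candidacy needs enough votes and an intact floor", {
  cfg <- screen_config()
  # up everywhere: candidate with support 7
  de_all <- purrr::map(1:7, ~ de_row("A", paste0("c", .x), 3, 1e-5)) |>
    purrr::list_rbind()
  # up in 3, but -0.5 in a fourth cohort: floor violated
  de_floor <- dplyr::bind_rows(
    purrr::map(1:3, ~ de_row("B", paste0("c", .x), 2, 1e-4)) |> purrr::list_rbind(),
    de_row("B", "c4", -0.5, 0.4),
    purrr::map(5:7, ~ de_row("B", paste0("c", .x), 0, 0.9)) |> purrr::list_rbind()
  )
  de <- dplyr::bind_rows(de_all, tidyr::complete(de_floor, gene = "B",
                                                 cohort = paste0("c", 1:7)))
  de <- dplyr::bind_rows(de, de_row("A", "c1", 3, 1e-5)[0, ])
  cand <- candidate_screen(tidyr::complete(de, gene = c("A", "B"),
                                           cohort = paste0("c", 1:7)), cfg)
  a <- cand[cand$gene == "A", ]; b <- cand[cand$gene == "B", ]
  expect_true(a$is_candidate); expect_equal(a$support, 7L)
  expect_false(b$is_candidate); expect_equal(b$support, 3L)
  expect_false(b$floor_ok)
})

test_that("screen equals the brute-force oracle and ignores row order", {
  cfg <- screen_config()
  de <- random_de(80, 7, seed = 7)
  cand <- candidate_screen(de, cfg)
  ref <- oracle_screen(de, cfg$up_lfc, cfg$up_p, cfg$floor_lfc, cfg$min_support)
  ord <- match(ref$gene, cand$gene)
  expect_equal(cand$support[ord], ref$support)
  expect_equal(cand$is_candidate[ord], ref$is_candidate)

  shuffled <- de[sample(nrow(de)), ]
  cand2 <- candidate_screen(shuffled, cfg)
  expect_equal(dplyr::arrange(cand2, gene), dplyr::arrange(cand, gene),
               ignore_attr = TRUE)
})

test_that("tightening thresholds never enlarges the screen output", {
  de <- random_de(100, 7, seed = 31)
  base_cfg <- screen_config()
  base <- candidate_screen(de, base_cfg)
  for (cfg in list(screen_config(up_lfc = 1.5), screen_config(up_p = 0.01))) {
    tight <- candidate_screen(de, cfg)
    expect_true(all(tight$support <= base$support[match(tight$gene, base$gene)]))
  }
  higher_floor <- candidate_screen(de, screen_config(floor_lfc = -0.05))
  expect_true(all(higher_floor$is_candidate <=
                    base$is_candidate[match(higher_floor$gene, base$gene)]))
})

test_that("PRG selection keeps candidates strictly above min_support", {
  mk <- function(supports) {
    tibble::tibble(gene = sprintf("g%02d", seq_along(supports)),
                   support = as.integer(supports),
                   n_measured = 7L, floor_ok = TRUE,
                   is_candidate = supports >= 3, flags = "")
  }
  ranked <- rank_and_select_prgs(mk(c(7, 4, 4, rep(3, 16))), screen_config())
  expect_equal(sum(ranked$is_prg), 3L)
  expect_equal(ranked$rank[ranked$is_candidate], 1:19)
  expect_equal(ranked$support[1:3], c(7L, 4L, 4L))

  expect_warning(none <- rank_and_select_prgs(mk(rep(3, 5)), screen_config()),
                 "min_support")
  expect_equal(sum(none$is_prg), 0L)

  set.seed(12)
  sup <- sample(0:7, 40, replace = TRUE)
  got <- rank_and_select_prgs(mk(sup), screen_config())
  expect_setequal(got$gene[got$is_prg],
                  sprintf("g%02d", which(sup >= 3 & sup > 3)))
  # ties broken lexicographically
  expect_equal(got$gene[got$is_candidate],
               got[got$is_candidate, ] |>
                 dplyr::arrange(dplyr::desc(support), gene) |>
                 dplyr::pull(gene))
})

test_that("genes missing from most cohorts are excluded with a warning", {
  de <- dplyr::bind_rows(
    random_de(5, 7, seed = 2),
    de_row("rare", "c1", 3, 1e-6) |>
      dplyr::bind_rows(de_row("rare", "c2", 3, 1e-6),
                       de_row("rare", "c3", 3, 1e-6))
  )
  expect_warning(cand <- candidate_screen(de), "excluded")
  rare <- cand[cand$gene == "rare", ]
  expect_equal(rare$n_measured, 3L)
  expect_false(rare$is_candidate)
  expect_equal(rare$support, 3L)  # support still counted over measured cohorts
})

test_that("screen_config validates its invariants", {
  expect_error(screen_config(up_lfc = -1), "up_lfc")
  expect_error(screen_config(up_p = 1.5), "p thresholds")
  expect_error(screen_config(min_support = 0), "min_support")
  expect_error(screen_config(ppi_score = 2), "ppi_score")
})
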