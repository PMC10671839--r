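test_that("pooled per-gene statistics follow the two-sample arithmetic", {
  d1 <- cohort_data(matrix(c(2, 2), nrow = 1), matrix(c(4, 4), nrow = 1))
  st1 <- gene_pooled_stats(d1$expression, d1$samples, "c1")
  expect_equal(st1$log2fc, 2)
  expect_equal(st1$s_sq, 0)

  d2 <- cohort_data(matrix(c(1, 3), nrow = 1), matrix(c(5, 7), nrow = 1))
  st2 <- gene_pooled_stats(d2$expression, d2$samples, "c1")
  expect_equal(st2$log2fc, 4)
  expect_equal(st2$s_sq, 2)
  expect_equal(st2$df, 2)
  expect_equal(st2$v, 1)

  # permuting sample columns changes nothing
  perm <- d2$expression[c("gene_id", rev(names(d2$expression)[-1]))]
  expect_equal(gene_pooled_stats(perm, d2$samples, "c1"), st2)
})

test_that("variance prior fit clamps and recovers", {
  # all variances equal: infinite shrinkage onto that value
  pr <- fit_variance_prior(rep(1.7, 50), d_g = 4)
  expect_true(is.infinite(pr$d0))
  expect_equal(pr$s0_sq, 1.7)

  # under-dispersed log-variances also clamp to d0 = Inf
  set.seed(3)
  s2 <- exp(rnorm(100, 0, 0.05))  # var(log s2) << trigamma(2)
  pr2 <- fit_variance_prior(s2, d_g = 4)
  expect_true(is.infinite(pr2$d0))

  # parameter recovery from a scaled chi-square hierarchy
  set.seed(99)
  d0 <- 4; s0 <- 2; d_g <- 4; n <- 5000
  sigma2 <- d0 * s0 / rchisq(n, df = d0)
  s_sq <- sigma2 * rchisq(n, df = d_g) / d_g
  pr3 <- fit_variance_prior(s_sq, d_g)
  expect_lt(abs(pr3$d0 - d0) / d0, 0.25)
  expect_lt(abs(pr3$s0_sq - s0) / s0, 0.10)
})

test_that("moderated t reduces to its analytic limits", {
  set.seed(21)
  d <- cohort_data(matrix(rnorm(30, 8), nrow = 10),
                   matrix(rnorm(30, 8.5), nrow = 10))
  # d0 = 0: ordinary pooled two-sample t
  pr0 <- structure(list(d0 = 0, s0_sq = 1, n_genes = 10), class = "paxs_prior")
  de0 <- moderated_t_table(d$expression, d$samples, prior = pr0)
  m <- as.matrix(d$expression[-1])
  for (i in 1:10) {
    ref <- oracle_pooled_t(m[i, 4:6], m[i, 1:3])
    expect_equal(de0$t[i], unname(ref["t"]), tolerance = 1e-12)
    expect_equal(de0$p[i], unname(ref["p"]), tolerance = 1e-12)
  }
  # d0 = Inf: shared variance s0, normal tail
  prI <- structure(list(d0 = Inf, s0_sq = 0.8, n_genes = 10), class = "paxs_prior")
  deI <- moderated_t_table(d$expression, d$samples, prior = prI)
  expect_equal(deI$t, deI$log2fc / sqrt(0.8 * (2 / 3)), tolerance = 1e-12)
  expect_equal(deI$p, 2 * pnorm(-abs(deI$t)), tolerance = 1e-12)
})

test_that("moderated t matches an independent formula oracle and limma", {
  set.seed(77)
  n_genes <- 200
  sigma2 <- 4 * 0.5 / rchisq(n_genes, df = 4)
  mr <- matrix(rnorm(n_genes * 3, 8, sqrt(sigma2)), nrow = n_genes)
  ms <- matrix(rnorm(n_genes * 3, 8, sqrt(sigma2)), nrow = n_genes)
  mr[1:20, ] <- mr[1:20, ] + 1.5
  d <- cohort_data(ms, mr)
  de <- moderated_t_table(d$expression, d$samples)

  st <- gene_pooled_stats(d$expression, d$samples, "c1")
  pr <- fit_variance_prior(st$s_sq, st$df[1])
  for (i in c(1, 5, 50, 123, 200)) {
    ref <- oracle_moderated_t(mr[i, ], ms[i, ], pr$d0, pr$s0_sq)
    expect_equal(de$t[i], unname(ref["t"]), tolerance = 1e-10)
    expect_equal(de$p[i], unname(ref["p"]), tolerance = 1e-10)
  }

  # independent route: limma's eBayes on the same design
  skip_if_not_installed("limma")
  m <- cbind(ms, mr)
  design <- cbind(1, rep(c(0, 1), each = 3))
  fit <- limma::eBayes(limma::lmFit(m, design))
  expect_equal(unname(fit$df.prior), pr$d0, tolerance = 1e-6)
  expect_equal(unname(fit$s2.prior), pr$s0_sq, tolerance = 1e-6)
  expect_equal(de$t, unname(fit$t[, 2]), tolerance = 1e-8)
  expect_equal(de$p, unname(fit$p.value[, 2]), tolerance = 1e-8)
})

test_that("exchanging arms negates log2fc and t exactly", {
  set.seed(5)
  d <- cohort_data(matrix(rnorm(48, 8), nrow = 12), matrix(rnorm(48, 9), nrow = 12))
  de <- moderated_t_table(d$expression, d$samples)
  swapped <- d$samples
  swapped$condition <- ifelse(swapped$condition == "sensitive",
                              "resistant", "sensitive")
  de2 <- moderated_t_table(d$expression, swapped)
  expect_equal(de2$log2fc, -de$log2fc)
  expect_equal(de2$t, -de$t)
  expect_equal(de2$p, de$p)
})

test_that("singleton-arm cohorts use the global variance fallback", {
  set.seed(13)
  d <- cohort_data(matrix(rnorm(200, 8), ncol = 1), matrix(rnorm(200, 8), ncol = 1))
  de <- moderated_t_table(d$expression, d$samples)
  expect_true(all(is.finite(de$t)))
  expect_true(all(is.infinite(de$df)))
  # under the null with the fallback, t is roughly standard normal
  expect_lt(abs(sd(de$t) - 1), 0.25)
})

test_that("paired t-test handles regular and degenerate pairings", {
  x <- c(5, 7, 6, 8)
  expect_equal(paired_t_test(x, x)$p, 1)
  expect_equal(paired_t_test(x, x)$t, 0)

  res <- paired_t_test(c(1, 2, 3), c(2, 3, 4))  # constant nonzero differences
  expect_true(res$degenerate)
  expect_equal(res$p, 0)
  expect_equal(res$t, -Inf)

  set.seed(8)
  a <- rnorm(7, 10); b <- rnorm(7, 9)
  got <- paired_t_test(a, b)
  dif <- a - b
  t_ref <- mean(dif) / (sd(dif) / sqrt(7))
  expect_equal(got$t, t_ref, tolerance = 1e-12)
  expect_equal(got$df, 6)
  expect_equal(got$p, 2 * pt(-abs(t_ref), 6), tolerance = 1e-12)
})
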