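test_that("median split sends median-valued patients to the low group", {
  g1 <- median_split(c(1, 2, 3, 4))
  expect_equal(as.character(g1), c("low", "low", "high", "high"))

  g2 <- median_split(c(1, 2, 2, 3))
  expect_equal(as.character(g2), c("low", "low", "low", "high"))

  set.seed(4)
  x <- sample(rnorm(20), 50, replace = TRUE)
  got <- median_split(x)
  expect_equal(as.character(got), ifelse(x > median(x), "high", "low"))

  expect_error(median_split(rep(2, 10)), "identical")
  expect_error(median_split(c(1, 2, 3)), ">= 4")
})

test_that("product-limit estimate matches hand arithmetic and its limits", {
  # n = 3: death at 1, censor at 2, death at 3
  recs <- tibble::tibble(time = c(1, 2, 3), event = c(1, 0, 1))
  km <- km_estimate(recs)
  expect_equal(km_survival_at(km, c(1, 3)), c(2 / 3, 0))

  # no deaths: survival identically 1
  km0 <- km_estimate(tibble::tibble(time = 1:5, event = 0))
  expect_true(all(km0$survival == 1))

  # no censoring: empirical survival fraction, exactly
  set.seed(9)
  t_all <- rexp(40, 0.01)
  km1 <- km_estimate(tibble::tibble(time = t_all, event = 1))
  probe <- unname(quantile(t_all, c(0.2, 0.5, 0.9)))
  expect_equal(km_survival_at(km1, probe),
               sapply(probe, function(q) mean(t_all > q)))

  # product-limit structure: every step is previous * (1 - d/n)
  set.seed(10)
  recs2 <- tibble::tibble(time = round(rexp(60, 0.01)) + 1,
                          event = rbinom(60, 1, 0.6))
  km2 <- km_estimate(recs2)
  step <- cumprod(1 - km2$n_event / km2$n_risk)
  expect_equal(km2$survival, step)
  expect_true(all(diff(km2$survival) <= 1e-12))
})

test_that("product-limit estimate agrees with the survival package", {
  skip_if_not_installed("survival")
  set.seed(22)
  recs <- tibble::tibble(time = rexp(120, 0.002), event = rbinom(120, 1, 0.6))
  km <- km_estimate(recs)
  sf <- survival::survfit(survival::Surv(time, event) ~ 1, data = recs)
  ev <- km[km$n_event > 0, ]
  ref <- summary(sf, times = ev$time)
  expect_equal(ev$survival, ref$surv, tolerance = 1e-12)
  expect_equal(ev$n_risk, ref$n.risk)
})

test_that("log-rank test matches independent accumulations", {
  # identical groups record-for-record: chi = 0, p = 1
  a <- tibble::tibble(time = c(3, 5, 8), event = c(1, 1, 0))
  same <- log_rank_test(a, b = a)
  expect_equal(same$chi_sq, 0)
  expect_equal(same$p, 1)

  # 6-patient worked example against the formula oracle
  recs <- tibble::tibble(time = c(2, 4, 6, 3, 5, 7),
                         event = c(1, 1, 0, 1, 0, 1),
                         group = rep(c("a", "b"), each = 3))
  lr <- log_rank_test(recs)
  ref <- oracle_logrank(recs$time, recs$event, recs$group)
  expect_equal(lr$chi_sq, unname(ref["chi_sq"]), tolerance = 1e-12)
  expect_equal(lr$p, unname(ref["p"]), tolerance = 1e-12)
  expect_equal(sum(lr$observed), sum(lr$expected), tolerance = 1e-9)

  # label symmetry
  flip <- recs; flip$group <- ifelse(recs$group == "a", "b", "a")
  expect_equal(log_rank_test(flip)$chi_sq, lr$chi_sq, tolerance = 1e-12)

  # cross-check against survival::survdiff on a larger cohort
  skip_if_not_installed("survival")
  set.seed(30)
  big <- tibble::tibble(time = rexp(150, 0.002 * c(1, 1.8)[1 + (1:150 > 75)]),
                        event = rbinom(150, 1, 0.7),
                        group = rep(c("a", "b"), each = 75))
  mine <- log_rank_test(big)
  sd_ref <- survival::survdiff(survival::Surv(time, event) ~ group, data = big)
  expect_equal(mine$chi_sq, unname(sd_ref$chisq), tolerance = 1e-9)
  expect_equal(mine$observed, setNames(sd_ref$obs, c("a", "b")),
               ignore_attr = TRUE)
  expect_equal(mine$expected, setNames(sd_ref$exp, c("a", "b")),
               ignore_attr = TRUE, tolerance = 1e-9)
})

test_that("log-rank with no deaths is flagged degenerate with p = 1", {
  recs <- tibble::tibble(time = 1:8, event = 0, group = rep(c("a", "b"), 4))
  lr <- log_rank_test(recs)
  expect_true(lr$degenerate)
  expect_equal(lr$p, 1)
})

test_that("Pearson correlation follows the textbook formula", {
  x <- 1:10
  expect_equal(pearson_correlation(x, 2 * x + 1)$r, 1)

  set.seed(44)
  a <- rnorm(50); b <- 0.4 * a + rnorm(50)
  got <- pearson_correlation(a, b)
  r_ref <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  t_ref <- r_ref * sqrt(48 / (1 - r_ref^2))
  expect_equal(got$r, r_ref, tolerance = 1e-12)
  expect_equal(got$p, 2 * pt(-abs(t_ref), 48), tolerance = 1e-12)
  expect_equal(got$r_sq, got$r^2, tolerance = 1e-15)

  expect_error(pearson_correlation(rep(1, 5), rnorm(5)), "variance")
})

test_that("univariate OLS matches the normal equations and the r/p identity", {
  x <- c(1, 2, 3, 4, 5)
  fit0 <- ols_univariate(x, 2 * x)
  expect_equal(fit0$slope, 2)
  expect_equal(fit0$intercept, 0)
  expect_equal(fit0$r_sq, 1)

  set.seed(55)
  xs <- rnorm(30); ys <- 1.5 * xs + rnorm(30)
  fit <- ols_univariate(xs, ys)
  slope_ref <- sum((xs - mean(xs)) * (ys - mean(ys))) / sum((xs - mean(xs))^2)
  expect_equal(fit$slope, slope_ref, tolerance = 1e-10)
  expect_equal(fit$intercept, mean(ys) - slope_ref * mean(xs), tolerance = 1e-10)
  ct <- pearson_correlation(xs, ys)
  expect_equal(fit$p, ct$p, tolerance = 1e-15)
  expect_equal(fit$r_sq, fit$r^2, tolerance = 1e-15)
  expect_equal(glance(fit)$r_sq, fit$r_sq)
  expect_equal(tidy(fit)$estimate, c(fit$intercept, fit$slope))
})

test_that("survival IO round-trips", {
  recs <- tibble::tibble(patient_id = sprintf("p%d", 1:6),
                         time = c(10, 20, 30, 40, 50, 60),
                         event = c(1L, 0L, 1L, 1L, 0L, 1L))
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_survival(recs, tf)
  expect_equal(read_survival(tf), recs)
})
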