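#' Split patients at the median expression of a gene
#'
#' Patients strictly above the median go to `high`; patients at or below the
#' median go to `low` (ties at the median are assigned to `low`; the
#' convention is recorded in the `tie_rule` attribute).
#'
#' @param expression Numeric vector of per-patient expression for one gene
#'   (length >= 4).
#' @return Factor with levels `low`, `high`, same length as input.
#' @examples
#' median_split(c(1, 2, 2, 3))
#' @export
median_split <- function(expression) {
  if (length(expression) < 4L) abort("median_split needs >= 4 patients")
  if (!all(is.finite(expression))) abort("expression must be finite")
  if (diff(range(expression)) == 0) {
    abort("all expression values identical; median split impossible")
  }
  med <- median(expression)
  out <- factor(ifelse(expression > med, "high", "low"),
                levels = c("low", "high"))
  attr(out, "median") <- med
  attr(out, "tie_rule") <- "median values assigned to low"
  out
}

# validate a survival record frame: time > 0 finite, event in {0,1}
assert_survival <- function(records, arg = "records") {
  req <- c("time", "event")
  if (!is.data.frame(records) || !all(req %in% names(records))) {
    abort(sprintf("`%s` must have columns `time` and `event`", arg))
  }
  if (!all(is.finite(records$time)) || any(records$time <= 0)) {
    abort(sprintf("`%s`: times must be finite and > 0", arg))
  }
  if (!all(records$event %in% c(0, 1))) {
    abort(sprintf("`%s`: event must be 0 (censored) or 1 (death)", arg))
  }
  invisible(records)
}

#' Kaplan-Meier product-limit survival estimate
#'
#' Computes the product-limit estimator from first principles: at each
#' distinct death time `t_j` with `d_j` deaths among `n_j` patients at risk,
#' the survival curve steps down by the factor `(1 - d_j / n_j)`. Ties are
#' resolved by the standard convention that deaths precede censorings at
#' equal times (patients censored at `t_j` are still at risk there).
#'
#' @param records Data frame with columns `time` (days, > 0) and `event`
#'   (1 = death, 0 = censored); optionally a `group` column, in which case
#'   one curve per group is returned.
#' @return Tibble of class `paxs_km` with one row per distinct event time
#'   (plus censoring-only times for completeness of `n_risk` bookkeeping):
#'   `time`, `n_risk`, `n_event`, `n_censor`, `survival` (and `group` when
#'   grouped).
#' @export
km_estimate <- function(records) {
  assert_survival(records)
  if ("group" %in% names(records)) {
    out <- records |>
      dplyr::group_by(.data$group) |>
      dplyr::group_modify(~ km_one(.x)) |>
      dplyr::ungroup()
  } else {
    out <- km_one(records)
  }
  class(out) <- c("paxs_km", class(out))
  out
}

km_one <- function(records) {
  tab <- tibble(time = records$time, event = records$event) |>
    dplyr::group_by(.data$time) |>
    dplyr::summarise(n_event = sum(.data$event == 1),
                     n_censor = sum(.data$event == 0), .groups = "drop") |>
    dplyr::arrange(.data$time)
  n <- nrow(records)
  n_risk <- n - c(0, cumsum(tab$n_event + tab$n_censor))[seq_len(nrow(tab))]
  surv <- cumprod(1 - tab$n_event / n_risk)
  tibble(time = tab$time, n_risk = as.integer(n_risk),
         n_event = tab$n_event, n_censor = tab$n_censor, survival = surv)
}

#' Evaluate a Kaplan-Meier curve at arbitrary times
#'
#' @param curve Single-group `paxs_km` tibble.
#' @param times Times at which to read off S(t).
#' @return Numeric vector of survival probabilities (1 before the first
#'   event time).
#' @export
km_survival_at <- function(curve, times) {
  ev <- curve[curve$n_event > 0, ]
  vapply(times, function(tt) {
    past <- ev$time <= tt
    if (!any(past)) 1 else ev$survival[max(which(past))]
  }, numeric(1))
}

# fast numeric core of the log-rank statistic; group is logical (TRUE = b)
logrank_core <- function(time, event, in_b) {
  dt <- sort(unique(time[event == 1]))
  o_b <- e_b <- v <- 0
  for (tj in dt) {
    at_risk <- time >= tj
    n <- sum(at_risk)
    n_b <- sum(at_risk & in_b)
    d <- sum(event == 1 & time == tj)
    d_b <- sum(event == 1 & time == tj & in_b)
    o_b <- o_b + d_b
    e_b <- e_b + d * n_b / n
    if (n > 1) v <- v + d * (n_b / n) * (1 - n_b / n) * (n - d) / (n - 1)
  }
  d_tot <- sum(event == 1)
  list(observed = c(d_tot - o_b, o_b),
       expected = c(d_tot - e_b, e_b),
       variance = v)
}

#' Two-group log-rank test
#'
#' Compares survival between two groups by summing, over distinct death
#' times, the observed minus expected deaths in one group under the
#' hypergeometric model, with variance
#' `d (n_b/n)(1 - n_b/n)(n - d)/(n - 1)` at each death time. The statistic
#' `(O - E)^2 / V` is referred to a chi-square distribution with 1 degree of
#' freedom. Zero total variance (e.g. no deaths) yields `p = 1` with
#' `degenerate = TRUE`.
#'
#' @param records Data frame with columns `time`, `event`, and `group`
#'   (exactly two levels). Alternatively pass two record frames via `b`.
#' @param b Optional second group's records; then `records` is the first
#'   group and no `group` column is needed.
#' @return Object of class `paxs_logrank`: list with `chi_sq`, `df`, `p`,
#'   named `observed` and `expected` vectors, `variance`, and `degenerate`.
#' @export
log_rank_test <- function(records, b = NULL) {
  if (!is.null(b)) {
    assert_survival(records, "records"); assert_survival(b, "b")
    records <- dplyr::bind_rows(
      dplyr::mutate(records[c("time", "event")], group = "a"),
      dplyr::mutate(b[c("time", "event")], group = "b")
    )
  }
  assert_survival(records)
  if (!"group" %in% names(records)) abort("log_rank_test needs a `group` column (or `b=`)")
  lv <- if (is.factor(records$group)) levels(droplevels(factor(records$group))) else
    sort(unique(as.character(records$group)))
  if (length(lv) != 2L) abort("log_rank_test needs exactly two groups")
  core <- logrank_core(records$time, records$event,
                       as.character(records$group) == lv[2])
  degenerate <- core$variance <= 0
  chi <- if (degenerate) 0 else (core$observed[2] - core$expected[2])^2 / core$variance
  p <- if (degenerate) 1 else pchisq(chi, df = 1, lower.tail = FALSE)
  structure(list(chi_sq = chi, df = 1L, p = p,
                 observed = setNames(core$observed, lv),
                 expected = setNames(core$expected, lv),
                 variance = core$variance, degenerate = degenerate),
            class = "paxs_logrank")
}

#' @export
print.paxs_logrank <- function(x, ...) {
  cat(sprintf("Log-rank test: chi-square = %.4g (1 df), p = %.4g\n", x$chi_sq, x$p))
  cat(sprintf("  observed: %s | expected: %s\n",
              paste(sprintf("%s=%g", names(x$observed), x$observed), collapse = ", "),
              paste(sprintf("%s=%.3g", names(x$expected), x$expected), collapse = ", ")))
  if (x$degenerate) cat("  (degenerate: zero variance)\n")
  invisible(x)
}

#' @export
glance.paxs_logrank <- function(x, ...) {
  tibble(chi_sq = x$chi_sq, df = x$df, p = x$p,
         observed_a = x$observed[1], observed_b = x$observed[2],
         expected_a = x$expected[1], expected_b = x$expected[2],
         degenerate = x$degenerate)
}

#' Pearson product-moment correlation
#'
#' @param x,y Numeric vectors, length n >= 3, non-zero variance.
#' @return One-row tibble: `r`, `r_sq` (= r^2), `p` (two-sided, via the
#'   t-transform with n - 2 df), `n`.
#' @examples
#' pearson_correlation(1:10, (1:10) + rnorm(10))
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  n <- length(x)
  if (n < 3L) abort("need n >= 3")
  if (sd(x) == 0 || sd(y) == 0) abort("zero variance input")
  ct <- cor.test(x, y, method = "pearson")
  r <- unname(ct$estimate)
  tibble(r = r, r_sq = r^2, p = ct$p.value, n = n)
}

#' Univariate least-squares regression
#'
#' Ordinary least squares of `y` on a single predictor `x`. In the
#' univariate case the model R-squared equals the squared Pearson
#' correlation and the slope p-value equals the correlation p-value; both
#' identities hold exactly here by construction.
#'
#' @param x Predictor (non-zero variance, length n >= 3).
#' @param y Response.
#' @return Object of class `paxs_ols`: list with `slope`, `intercept`, `r`,
#'   `r_sq`, `p`, `n`, and the underlying `lm` fit.
#' @export
ols_univariate <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  n <- length(x)
  if (n < 3L) abort("need n >= 3")
  if (sd(x) == 0) abort("zero variance in predictor")
  fit <- lm(y ~ x, data = data.frame(x = x, y = y))
  ct <- pearson_correlation(x, y)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r = ct$r, r_sq = ct$r^2, p = ct$p, n = n, fit = fit),
            class = "paxs_ols")
}

#' @export
print.paxs_ols <- function(x, ...) {
  cat(sprintf("y = %.5f * x + %.5f   (R^2 = %.3f, r = %.4f, p = %.4g, n = %d)\n",
              x$slope, x$intercept, x$r_sq, x$r, x$p, x$n))
  invisible(x)
}

#' @export
tidy.paxs_ols <- function(x, ...) {
  tibble(term = c("(Intercept)", "x"),
         estimate = c(x$intercept, x$slope))
}

#' @export
glance.paxs_ols <- function(x, ...) {
  tibble(r = x$r, r_sq = x$r_sq, p = x$p, n = x$n)
}

#' Read a survival table
#'
#' @param path TSV with columns `patient_id`, `time_days`, `event`.
#' @return Tibble: `patient_id`, `time`, `event`.
#' @export
read_survival <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    patient_id = "c", time_days = "d", event = "i"), progress = FALSE)
  out <- tibble(patient_id = x$patient_id, time = x$time_days, event = x$event)
  assert_survival(out, path)
  out
}

#' Write a survival table
#'
#' @param records Tibble with `patient_id`, `time`, `event`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_survival <- function(records, path) {
  assert_survival(records)
  readr::write_tsv(tibble(patient_id = records$patient_id,
                          time_days = records$time, event = records$event),
                   path, progress = FALSE)
  invisible(path)
}
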