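#' Per-gene pooled two-group statistics for one cohort
#'
#' For each gene, computes the resistant-minus-sensitive log2 fold change, the
#' pooled (equal-variance) within-group variance `s_sq` on
#' `df = n1 + n2 - 2` degrees of freedom, and the design factor
#' `v = 1/n1 + 1/n2`. These are the sufficient statistics the moderated
#' t-statistic shrinks. With singleton arms on both sides `s_sq` and `df`
#' are `NA`/0 and the gene is handled by the global variance fallback in
#' [moderated_t_table()].
#'
#' @param expression Expression tibble (`gene_id` + sample columns, log2).
#' @param samples Sample sheet restricted to (or containing) the cohort.
#' @param cohort Cohort id to analyse.
#' @return Tibble: `gene`, `log2fc`, `s_sq`, `df`, `v`.
#' @export
gene_pooled_stats <- function(expression, samples, cohort) {
  assert_expression(expression)
  assert_sample_sheet(samples)
  sheet <- dplyr::filter(samples, .data$cohort_id == cohort)
  if (!nrow(sheet)) abort(sprintf("cohort '%s' not present in sample sheet", cohort))
  sens <- sheet$sample_id[sheet$condition == "sensitive"]
  res  <- sheet$sample_id[sheet$condition == "resistant"]
  if (!length(sens) || !length(res)) {
    abort(sprintf("cohort '%s' needs >=1 sample in each arm", cohort))
  }
  m <- expr_matrix(expression)
  missing <- setdiff(c(sens, res), colnames(m))
  if (length(missing)) {
    abort(sprintf("samples absent from matrix: %s", paste(missing, collapse = ", ")))
  }
  pooled_stats_matrix(m[, res, drop = FALSE], m[, sens, drop = FALSE])
}

# matrix fast path shared by gene_pooled_stats and the synergy DE
pooled_stats_matrix <- function(mr, ms) {
  n1 <- ncol(mr); n2 <- ncol(ms)
  lfc <- rowMeans(mr) - rowMeans(ms)
  d <- n1 + n2 - 2L
  if (d >= 1L) {
    ssr <- rowSums((mr - rowMeans(mr))^2)
    sss <- rowSums((ms - rowMeans(ms))^2)
    s_sq <- (ssr + sss) / d
  } else {
    s_sq <- rep(NA_real_, nrow(mr))
  }
  tibble(
    gene = rownames(mr),
    log2fc = unname(lfc),
    s_sq = unname(s_sq),
    df = rep(as.numeric(d), nrow(mr)),
    v = rep(1 / n1 + 1 / n2, nrow(mr))
  )
}

#' Fit the empirical-Bayes variance prior across genes
#'
#' Moment-matches the distribution of gene-wise log sample variances to the
#' scaled-F model underlying the moderated t-statistic: given residual
#' degrees of freedom `d_g`, the prior degrees of freedom `d0` solve
#' `trigamma(d0/2) = max(0, var(log s^2) - trigamma(d_g/2))` and the prior
#' variance `s0^2` comes from the matching mean equation. A non-positive
#' right-hand side means the observed variances are no more dispersed than
#' sampling noise alone: `d0` is infinite and `s0^2` is the mean sample
#' variance (all gene-wise variances are then treated as equal).
#'
#' @param s_sq Positive gene-wise pooled variances (non-finite and
#'   non-positive entries are dropped from the fit).
#' @param d_g Residual degrees of freedom shared by all genes (equal design).
#' @return Object of class `paxs_prior`: list with `d0` (possibly `Inf`),
#'   `s0_sq`, and `n_genes` used.
#' @export
fit_variance_prior <- function(s_sq, d_g) {
  if (length(d_g) != 1L || !is.finite(d_g) || d_g < 1) {
    abort("`d_g` must be a single value >= 1")
  }
  ok <- is.finite(s_sq) & s_sq > 0
  x <- s_sq[ok]
  if (length(x) < 2L) abort("need >=2 positive finite s_sq values to fit the prior")
  if (length(x) < 10L) {
    warn("fit_variance_prior: fewer than 10 genes; prior estimate is unstable")
  }
  z <- log(x)
  evar <- var(z) - trigamma(d_g / 2)
  if (evar <= 0) {
    prior <- list(d0 = Inf, s0_sq = mean(x), n_genes = length(x))
  } else {
    d0 <- 2 * limma::trigammaInverse(evar)
    s0_sq <- exp(mean(z) - digamma(d_g / 2) + log(d_g / 2) +
                   digamma(d0 / 2) - log(d0 / 2))
    prior <- list(d0 = unname(d0), s0_sq = unname(s0_sq), n_genes = length(x))
  }
  structure(prior, class = "paxs_prior")
}

#' @export
print.paxs_prior <- function(x, ...) {
  cat(sprintf("Variance prior: d0 = %s, s0^2 = %.6g (fit on %d genes)\n",
              if (is.infinite(x$d0)) "Inf" else format(x$d0, digits = 5),
              x$s0_sq, x$n_genes))
  invisible(x)
}

# moderated t given pooled stats and a prior; returns t, total df, p
moderate_stats <- function(log2fc, s_sq, d_g, v, prior) {
  d0 <- prior$d0; s0 <- prior$s0_sq
  if (is.infinite(d0)) {
    s_tilde <- rep(s0, length(log2fc))
    df_tot <- rep(Inf, length(log2fc))
  } else {
    s_obs <- ifelse(is.finite(s_sq), s_sq, 0)
    d_obs <- ifelse(is.finite(s_sq), d_g, 0)
    s_tilde <- (d0 * s0 + d_obs * s_obs) / (d0 + d_obs)
    df_tot <- d0 + d_obs
  }
  t_stat <- log2fc / sqrt(s_tilde * v)
  p <- 2 * pt(-abs(t_stat), df = df_tot)
  # 0/0 genes (no shrinkage, zero variance, zero effect) are flat: t = 0
  t_stat[!is.finite(t_stat) & log2fc == 0] <- 0
  p[is.na(p) & log2fc == 0] <- 1
  list(t = t_stat, df = df_tot, p = p)
}

#' Moderated-t differential expression table
#'
#' Runs the two-group empirical-Bayes moderated t-test, per cohort, for every
#' gene: the gene-wise pooled variance is shrunk toward the prior,
#' `s_tilde^2 = (d0 s0^2 + d_g s^2) / (d0 + d_g)`, the statistic is
#' `t = log2fc / (s_tilde * sqrt(1/n1 + 1/n2))`, and the two-sided p-value
#' uses `d0 + d_g` degrees of freedom (normal when `d0` is infinite). The
#' prior is fitted per cohort dataset with [fit_variance_prior()]. Cohorts in
#' which both arms are singletons (no within-group replication anywhere) fall
#' back to a global variance estimated from the cross-gene spread of log2
#' fold changes, with normal p-values.
#'
#' @param expression Expression tibble (already normalized per cohort).
#' @param samples Sample sheet; every cohort in `cohorts` must have both arms.
#' @param cohorts Cohort ids to analyse (default: all in `samples`).
#' @param prior Optional pre-fitted `paxs_prior` applied to every cohort;
#'   default fits one per cohort.
#' @return Tibble (class `paxs_de`): `gene`, `cohort`, `log2fc`, `t`, `df`,
#'   `p`; one row per gene per cohort.
#' @export
moderated_t_table <- function(expression, samples, cohorts = NULL, prior = NULL) {
  assert_expression(expression)
  assert_sample_sheet(samples)
  cohorts <- cohorts %||% sort(unique(samples$cohort_id))
  out <- purrr::map(cohorts, function(co) {
    st <- gene_pooled_stats(expression, samples, co)
    d_g <- st$df[1]
    if (is.null(prior)) {
      if (d_g >= 1) {
        pr <- fit_variance_prior(st$s_sq, d_g)
      } else {
        # singleton arms everywhere: null-majority global fallback
        pr <- structure(list(d0 = Inf, s0_sq = var(st$log2fc) / st$v[1],
                             n_genes = nrow(st)),
                        class = "paxs_prior")
      }
    } else {
      pr <- prior
    }
    mo <- moderate_stats(st$log2fc, st$s_sq, d_g, st$v, pr)
    tibble(gene = st$gene, cohort = co, log2fc = st$log2fc,
           t = mo$t, df = mo$df, p = mo$p)
  }) |>
    purrr::list_rbind()
  class(out) <- c("paxs_de", class(out))
  out
}

#' Paired-samples t-test with degenerate-case handling
#'
#' The cross-cohort confirmation test: values are paired by index (e.g. one
#' resistant and one sensitive expression value per cohort) and the ordinary
#' paired t-test is applied to the differences. Degenerate inputs are
#' flagged rather than erroring: all-zero differences give `t = 0, p = 1`;
#' zero-variance nonzero differences give the `p = 0` limit.
#'
#' @param values_a,values_b Equal-length numeric vectors, `n >= 2`.
#' @return One-row tibble: `t`, `df`, `p`, `mean_diff`, `n`, `degenerate`.
#' @examples
#' paired_t_test(c(5, 7, 6, 8), c(4, 5, 5, 6))
#' @export
paired_t_test <- function(values_a, values_b) {
  if (length(values_a) != length(values_b)) abort("paired vectors must have equal length")
  n <- length(values_a)
  if (n < 2L) abort("paired t-test needs n >= 2 pairs")
  d <- values_a - values_b
  if (all(d == 0)) {
    return(tibble(t = 0, df = n - 1, p = 1, mean_diff = 0, n = n,
                  degenerate = TRUE))
  }
  if (sd(d) == 0) {
    return(tibble(t = sign(mean(d)) * Inf, df = n - 1, p = 0,
                  mean_diff = mean(d), n = n, degenerate = TRUE))
  }
  tt <- stats::t.test(values_a, values_b, paired = TRUE)
  tibble(t = unname(tt$statistic), df = unname(tt$parameter),
         p = tt$p.value, mean_diff = unname(tt$estimate), n = n,
         degenerate = FALSE)
}
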