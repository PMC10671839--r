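#' Percent viability from plate-reader optical densities
#'
#' Standard blank-corrected normalization:
#' `100 * (treated - blank) / (mean(control) - blank)`.
#'
#' @param treated_od Treated-well OD450 readings.
#' @param control_od Untreated control-well readings.
#' @param blank_od Single blank (medium-only) reading.
#' @return Numeric vector of percent viabilities.
#' @examples
#' viability_percent(c(0.6, 0.5), c(1.0, 1.1, 0.9), 0.1)
#' @export
viability_percent <- function(treated_od, control_od, blank_od) {
  if (length(blank_od) != 1L) abort("blank_od must be a single value")
  denom <- mean(control_od) - blank_od
  if (denom <= 0) abort("mean control OD must exceed the blank")
  100 * (treated_od - blank_od) / denom
}

# 4PL mean function; decreasing in x for hill > 0
fourpl <- function(x, bottom, top, hill, ic50) {
  bottom + (top - bottom) / (1 + (x / ic50)^hill)
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of the decreasing 4PL model
#' `y = bottom + (top - bottom) / (1 + (x / ic50)^hill)` (hill > 0), the
#' standard CCK-8 viability curve. The IC50 is the concentration at the
#' midpoint of the fitted asymptotes (relative IC50). Zero-dose wells anchor
#' the top asymptote: they are included at `x = zero_eps * min(nonzero dose)`
#' so they sit far left on the log-concentration axis. Fitting multi-starts
#' from log-spaced IC50 seeds and keeps the best residual sum of squares;
#' bounds `bottom >= 0` and `top <= 1.2 * max(response)` stabilize the fit.
#'
#' @param data Data frame with columns `concentration` (nM, >= 0, at least 5
#'   distinct values) and `response` (viability percent or OD), one row per
#'   replicate well. Alternatively supply `concentration` and `response`
#'   vectors directly.
#' @param concentration,response Used when `data` is `NULL`.
#' @param zero_eps Placement factor for zero-dose wells (default `1e-3`).
#' @param n_starts Number of log-spaced IC50 starting values (default 7).
#' @return Object of class `paxs_4pl`: list with `bottom`, `top`, `hill`,
#'   `ic50` (nM), `rss`, `n`, `data`, and the kept `nls` fit.
#' @export
fit_4pl <- function(data = NULL, concentration = NULL, response = NULL,
                    zero_eps = 1e-3, n_starts = 7L) {
  if (!is.null(data)) {
    stopifnot(all(c("concentration", "response") %in% names(data)))
    concentration <- data$concentration
    response <- data$response
  }
  ok <- is.finite(concentration) & is.finite(response)
  x <- concentration[ok]; y <- response[ok]
  if (any(x < 0)) abort("concentrations must be >= 0")
  if (length(unique(x)) < 5L) abort("need >= 5 distinct concentrations")
  xmin <- min(x[x > 0])
  xfit <- ifelse(x == 0, zero_eps * xmin, x)

  # sanity: responses must decline with dose
  mean_by_dose <- tapply(y, xfit, mean)
  dose_levels <- as.numeric(names(mean_by_dose))
  if (isTRUE(stats::cor(log(dose_levels), as.numeric(mean_by_dose),
                        method = "spearman") > 0)) {
    abort("responses increase with dose; not a decreasing viability curve")
  }

  lower <- c(bottom = 0, top = -Inf, hill = 0.1, log_ic50 = log(xmin / 10))
  upper <- c(bottom = Inf, top = 1.2 * max(y), hill = 10,
             log_ic50 = log(max(x) * 10))
  starts_ic50 <- exp(seq(log(xmin), log(max(x)), length.out = n_starts))
  best <- NULL
  diags <- character(0)
  for (s in starts_ic50) {
    st <- list(bottom = max(min(y), 0), top = min(max(y), 1.2 * max(y)),
               hill = 1, log_ic50 = log(s))
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ bottom + (top - bottom) / (1 + (xfit / exp(log_ic50))^hill),
        start = st, lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) e
    )
    if (inherits(fit, "error")) {
      diags <- c(diags, conditionMessage(fit))
    } else {
      rss <- sum(residuals(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) {
    abort(paste0("4PL fit failed from every start:\n  ",
                 paste(unique(diags), collapse = "\n  ")))
  }
  cf <- coef(best$fit)
  if (cf[["top"]] <= cf[["bottom"]]) abort("degenerate 4PL fit: top <= bottom")
  structure(list(bottom = unname(cf[["bottom"]]), top = unname(cf[["top"]]),
                 hill = unname(cf[["hill"]]), ic50 = exp(unname(cf[["log_ic50"]])),
                 rss = best$rss, n = length(y),
                 data = tibble(concentration = x, response = y),
                 fit = best$fit),
            class = "paxs_4pl")
}

#' @export
print.paxs_4pl <- function(x, ...) {
  cat(sprintf(
    "4PL dose-response fit (n = %d wells)\n  IC50 = %.4g nM, hill = %.3g, top = %.4g, bottom = %.4g, RSS = %.4g\n",
    x$n, x$ic50, x$hill, x$top, x$bottom, x$rss))
  invisible(x)
}

#' @export
tidy.paxs_4pl <- function(x, ...) {
  tibble(term = c("bottom", "top", "hill", "ic50"),
         estimate = c(x$bottom, x$top, x$hill, x$ic50))
}

#' @export
glance.paxs_4pl <- function(x, ...) {
  tibble(ic50 = x$ic50, hill = x$hill, top = x$top, bottom = x$bottom,
         rss = x$rss, n = x$n)
}

#' Predicted response of a fitted 4PL curve
#'
#' @param object `paxs_4pl` fit.
#' @param newdata Optional data frame with a `concentration` column.
#' @param ... Unused.
#' @return Numeric vector of fitted responses.
#' @export
predict.paxs_4pl <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$concentration else newdata$concentration
  fourpl(x, object$bottom, object$top, object$hill, object$ic50)
}

#' Resistance index from paired IC50s
#'
#' The fold increase in drug tolerance of a resistant line over its parental
#' sensitive line: `RI = IC50_resistant / IC50_sensitive`. Accepts fitted
#' `paxs_4pl` objects or bare IC50 values.
#'
#' @param fit_resistant,fit_sensitive `paxs_4pl` fits or positive IC50
#'   values (same units).
#' @return One-row tibble: `ri`, `ic50_resistant`, `ic50_sensitive`.
#' @examples
#' resistance_index(1574, 299.7)
#' @export
resistance_index <- function(fit_resistant, fit_sensitive) {
  get_ic50 <- function(f) if (inherits(f, "paxs_4pl")) f$ic50 else as.numeric(f)
  r <- get_ic50(fit_resistant); s <- get_ic50(fit_sensitive)
  if (!is.finite(r) || !is.finite(s) || r <= 0 || s <= 0) {
    abort("both IC50 values must be positive")
  }
  tibble(ri = r / s, ic50_resistant = r, ic50_sensitive = s)
}

#' Relative expression fold change by the delta-delta-Ct method
#'
#' qPCR fold change of a target gene in a treated sample relative to a
#' control sample, each normalized to a reference gene:
#' `2^-((Ct_gene,treat - Ct_ref,treat) - (Ct_gene,ctrl - Ct_ref,ctrl))`.
#'
#' @param ct_gene_treat,ct_ref_treat,ct_gene_ctrl,ct_ref_ctrl Threshold-cycle
#'   values, each in (0, 45).
#' @return Fold change (vectorized over inputs).
#' @examples
#' ddct_fold_change(24, 18, 26, 18)  # ddCt = -2 -> fold 4
#' @export
ddct_fold_change <- function(ct_gene_treat, ct_ref_treat,
                             ct_gene_ctrl, ct_ref_ctrl) {
  cts <- c(ct_gene_treat, ct_ref_treat, ct_gene_ctrl, ct_ref_ctrl)
  if (!all(is.finite(cts)) || any(cts <= 0) || any(cts >= 45)) {
    abort("Ct values must lie in (0, 45)")
  }
  ddct <- (ct_gene_treat - ct_ref_treat) - (ct_gene_ctrl - ct_ref_ctrl)
  2^(-ddct)
}

#' One-way analysis of variance
#'
#' Standard between/within variance decomposition for three or more groups,
#' via [stats::aov()]. Inputs where every value is identical are flagged as
#' degenerate (`F` undefined) instead of erroring.
#'
#' @param data Data frame with columns `value` and `group`, or a list of
#'   numeric vectors (one per group).
#' @return One-row tibble: `f`, `df1`, `df2`, `p`, `degenerate`.
#' @examples
#' one_way_anova(list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(5, 6, 7)))
#' @export
one_way_anova <- function(data) {
  if (is.list(data) && !is.data.frame(data)) {
    if (any(lengths(data) == 0L)) abort("empty group supplied")
    nm <- names(data) %||% as.character(seq_along(data))
    data <- tibble(value = unlist(data, use.names = FALSE),
                   group = rep(nm, lengths(data)))
  }
  stopifnot(all(c("value", "group") %in% names(data)))
  if (dplyr::n_distinct(data$group) < 3L) abort("one-way ANOVA here expects >= 3 groups")
  if (any(table(data$group) < 2L)) abort("every group needs >= 2 values")
  if (sd(data$value) == 0) {
    return(tibble(f = NA_real_, df1 = dplyr::n_distinct(data$group) - 1L,
                  df2 = nrow(data) - dplyr::n_distinct(data$group),
                  p = NA_real_, degenerate = TRUE))
  }
  fit <- aov(value ~ factor(group), data = data)
  s <- summary(fit)[[1]]
  tibble(f = s[["F value"]][1], df1 = s[["Df"]][1], df2 = s[["Df"]][2],
         p = s[["Pr(>F)"]][1], degenerate = FALSE)
}

#' Read a dose-response plate CSV
#'
#' Expected layout: `concentration_nM,rep1,rep2,...` (one column per
#' replicate well). Returns tidy long data ready for [fit_4pl()].
#'
#' @param path CSV path.
#' @return Tibble: `concentration`, `replicate`, `response`.
#' @export
read_dose_response <- function(path) {
  x <- readr::read_csv(path, col_types = readr::cols(.default = "d"),
                       progress = FALSE)
  if (names(x)[1] != "concentration_nM") {
    abort("dose-response CSV must start with a concentration_nM column")
  }
  x |>
    dplyr::rename(concentration = "concentration_nM") |>
    tidyr::pivot_longer(-"concentration", names_to = "replicate",
                        values_to = "response") |>
    dplyr::arrange(.data$concentration)
}
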