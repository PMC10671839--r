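#' @importFrom ggplot2 autoplot ggplot aes geom_step geom_point geom_line
#'   geom_col labs scale_x_log10 theme_minimal
NULL

#' @export
ggplot2::autoplot

#' Plot a Kaplan-Meier curve
#'
#' Step plot of the product-limit estimate, one line per group when the
#' curve is grouped.
#'
#' @param object `paxs_km` tibble from [km_estimate()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.paxs_km <- function(object, ...) {
  dat <- as_tibble(object)
  grouped <- "group" %in% names(dat)
  pad <- if (grouped) {
    dat |> dplyr::group_by(.data$group) |>
      dplyr::group_modify(~ dplyr::bind_rows(
        tibble(time = 0, survival = 1), .x[c("time", "survival")])) |>
      dplyr::ungroup()
  } else {
    dplyr::bind_rows(tibble(time = 0, survival = 1),
                     dat[c("time", "survival")])
  }
  p <- if (grouped) {
    ggplot(pad, aes(.data$time, .data$survival, colour = .data$group))
  } else {
    ggplot(pad, aes(.data$time, .data$survival))
  }
  p + geom_step() +
    labs(x = "Time (days)", y = "Survival probability") +
    theme_minimal()
}

#' Plot a fitted dose-response curve
#'
#' Observed wells plus the fitted 4PL curve on a log concentration axis
#' (zero-dose wells are drawn at the placement position used in fitting).
#'
#' @param object `paxs_4pl` fit.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.paxs_4pl <- function(object, ...) {
  obs <- object$data
  xmin <- min(obs$concentration[obs$concentration > 0])
  obs$conc_plot <- ifelse(obs$concentration == 0, xmin / 100, obs$concentration)
  grid <- tibble(concentration = exp(seq(log(xmin / 100),
                                         log(max(obs$concentration)),
                                         length.out = 200)))
  grid$response <- predict(object, grid)
  ggplot(obs, aes(.data$conc_plot, .data$response)) +
    geom_point(alpha = 0.7) +
    geom_line(data = grid, aes(.data$concentration, .data$response)) +
    scale_x_log10() +
    labs(x = "Concentration (nM)", y = "Viability",
         title = sprintf("IC50 = %.3g nM", object$ic50)) +
    theme_minimal()
}

#' Plot candidate vote supports
#'
#' Bar chart of per-candidate support counts (number of resistant cohorts
#' voting "up"), resistance genes highlighted.
#'
#' @param object `paxs_candidates` tibble from [rank_and_select_prgs()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.paxs_candidates <- function(object, ...) {
  dat <- dplyr::filter(as_tibble(object), .data$is_candidate)
  if ("rank" %in% names(dat)) dat <- dplyr::arrange(dat, .data$rank)
  dat$gene <- factor(dat$gene, levels = rev(dat$gene))
  fill <- if ("is_prg" %in% names(dat)) dat$is_prg else FALSE
  ggplot(dat, aes(.data$support, .data$gene, fill = fill)) +
    geom_col(show.legend = "is_prg" %in% names(dat)) +
    labs(x = "Cohorts voting up", y = NULL, fill = "PRG") +
    theme_minimal()
}
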