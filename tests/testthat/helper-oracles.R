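# independent oracles, written straight from the textbook formulas and kept
# free of any package internals

# pooled two-sample stats and moderated t, one gene at a time
oracle_moderated_t <- function(res_vals, sens_vals, d0, s0_sq) {
  n1 <- length(res_vals); n2 <- length(sens_vals)
  lfc <- mean(res_vals) - mean(sens_vals)
  d <- n1 + n2 - 2
  s2 <- (sum((res_vals - mean(res_vals))^2) +
           sum((sens_vals - mean(sens_vals))^2)) / d
  v <- 1 / n1 + 1 / n2
  if (is.infinite(d0)) {
    st <- s0_sq; df_tot <- Inf
  } else {
    st <- (d0 * s0_sq + d * s2) / (d0 + d); df_tot <- d0 + d
  }
  tval <- lfc / sqrt(st * v)
  c(t = tval, p = 2 * stats::pt(-abs(tval), df = df_tot))
}

# log-rank O/E/V accumulation done by explicit 2x2 tables per death time
oracle_logrank <- function(time, event, group) {
  g2 <- group == sort(unique(group))[2]
  o <- e <- v <- 0
  for (tj in sort(unique(time[event == 1]))) {
    n <- sum(time >= tj)
    n2 <- sum(time >= tj & g2)
    d <- sum(time == tj & event == 1)
    d2 <- sum(time == tj & event == 1 & g2)
    o <- o + d2
    e <- e + d * n2 / n
    if (n > 1) v <- v + d * (n2 / n) * ((n - n2) / n) * (n - d) / (n - 1)
  }
  chi <- (o - e)^2 / v
  c(chi_sq = chi, p = stats::pchisq(chi, 1, lower.tail = FALSE))
}

# brute-force consensus screen on a long DE table (no vectorized tricks)
oracle_screen <- function(de, up_lfc, up_p, floor_lfc, min_support) {
  genes <- sort(unique(de$gene))
  cohorts <- sort(unique(de$cohort))
  out <- lapply(genes, function(g) {
    support <- 0L; floor_ok <- TRUE; measured <- 0L
    for (co in cohorts) {
      row <- de[de$gene == g & de$cohort == co, ]
      if (nrow(row) == 0 || is.na(row$log2fc)) next
      measured <- measured + 1L
      if (row$log2fc >= up_lfc && row$p <= up_p) {
        support <- support + 1L
      } else if (row$log2fc < floor_lfc) {
        floor_ok <- FALSE
      }
    }
    data.frame(gene = g, support = support, floor_ok = floor_ok,
               n_measured = measured,
               is_candidate = support >= min_support && floor_ok &&
                 measured >= ceiling(length(cohorts) / 2))
  })
  do.call(rbind, out)
}

# ordinary equal-variance two-sample t, textbook form
oracle_pooled_t <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) / (n1 + n2 - 2)
  tval <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  c(t = tval, p = 2 * stats::pt(-abs(tval), df = n1 + n2 - 2))
}
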