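# small builders shared across tests

expr_from_matrix <- function(m) {
  if (is.null(rownames(m))) rownames(m) <- sprintf("G%03d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("s%d", seq_len(ncol(m)))
  dplyr::bind_cols(tibble::tibble(gene_id = rownames(m)),
                   tibble::as_tibble(m, .name_repair = "minimal"))
}

two_arm_sheet <- function(n_sens, n_res, cohort = "c1") {
  tibble::tibble(
    sample_id = c(sprintf("%s_S%d", cohort, seq_len(n_sens)),
                  sprintf("%s_R%d", cohort, seq_len(n_res))),
    cohort_id = cohort,
    condition = rep(c("sensitive", "resistant"), c(n_sens, n_res))
  )
}

# one cohort's expression tibble + sheet from two matrices
cohort_data <- function(m_sens, m_res, cohort = "c1") {
  sheet <- two_arm_sheet(ncol(m_sens), ncol(m_res), cohort)
  m <- cbind(m_sens, m_res)
  colnames(m) <- sheet$sample_id
  list(expression = expr_from_matrix(m), samples = sheet)
}
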