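# Shared fixture builders. Everything is generated in code; no binary data.

tiny_expression <- function(G = 3, n = 2, seed = 1) {
  set.seed(seed)
  expression_matrix(matrix(round(rnorm(G * n, 7, 1), 3), G, n),
                    sprintf("G%02d", seq_len(G)), sprintf("S%02d", seq_len(n)))
}

tiny_clinical <- function(n = 10, seed = 1) {
  set.seed(seed)
  vocab <- endokit:::CLINICAL_VOCAB
  data.frame(
    sample_id = sprintf("S%02d", seq_len(n)),
    sex = sample(vocab$sex, n, TRUE),
    age_group = sample(vocab$age_group, n, TRUE),
    admission_reason = sample(vocab$admission_reason, n, TRUE),
    comorbidity = sample(vocab$comorbidity, n, TRUE),
    infection_status = sample(vocab$infection_status, n, TRUE),
    pim2 = round(runif(n, 0.01, 0.4), 4),
    ventilation_days = sample(0:12, n, TRUE),
    died_by_day30 = c(TRUE, rep(FALSE, n - 1)),
    vasoactive = sample(c(TRUE, FALSE), n, TRUE),
    stringsAsFactors = FALSE)
}

# small, fast cohort used where the full default is unnecessary
small_cohort <- function(seed = 1, ...) {
  simulate_cohort(cohort_spec(n_samples = 120, n_genes = 400,
                              n_marker_genes = 40, seed = seed, ...))
}

# Dirichlet concentrations with no endotype difference (null mixtures)
equal_alpha <- function() {
  a <- rep(4, 6)
  names(a) <- endokit:::CELL_TYPES
  list(e1 = a, e2 = a)
}
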