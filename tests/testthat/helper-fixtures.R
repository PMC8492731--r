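# Fixture builders shared across tests. Everything is generated in code.

# small patient table; all HER2-negative unless her2 supplied
toy_patients <- function(arm, hr, mp_hi2 = rep(0, length(arm)),
                         her2 = rep(0, length(arm)),
                         day = rep(1800, length(arm)),
                         pcr = rep(0, length(arm)),
                         deviation = rep("none", length(arm))) {
  as_patient_table(data.frame(
    patient_id = sprintf("T%03d", seq_along(arm)), arm = arm, hr = hr,
    her2 = her2, mp_score = ifelse(mp_hi2 == 1, -0.8, 0.2),
    randomization_day = day, pcr = pcr, deviation = deviation))
}

# a tm_draws object with hand-chosen coefficient draws, for brute-force
# checks of the decision rules
toy_draws <- function(patients, beta, analysis_day = 1800,
                      arms = unique(patients$arm)) {
  model <- build_model(patients, arms = arms, analysis_day = analysis_day)
  stopifnot(ncol(beta) == ncol(model$X))
  colnames(beta) <- colnames(model$X)
  structure(list(beta = beta, delta = NULL, tau2 = NULL,
                 chain = rep(1L, nrow(beta)), rhat = NULL,
                 converged = TRUE, model = model, seed = 0L),
            class = "tm_draws")
}

# expression matrix with named genes/patients from a plain matrix
named_expr <- function(values, genes = NULL, patients = NULL) {
  if (is.null(genes)) genes <- sprintf("G%03d", seq_len(nrow(values)))
  if (is.null(patients)) patients <- sprintf("P%03d", seq_len(ncol(values)))
  dimnames(values) <- list(genes, patients)
  as_expression_matrix(values)
}
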