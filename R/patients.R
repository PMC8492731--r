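#' Patient-level trial records
#'
#' A patient table is a plain `data.frame` with one row per randomized
#' participant and columns:
#' \describe{
#'   \item{patient_id}{character, unique}
#'   \item{arm}{character arm label; the shared control arm is `"control"`
#'     unless stated otherwise}
#'   \item{hr}{hormone-receptor status, 0/1 (1 = positive)}
#'   \item{her2}{HER2 status, 0/1 (1 = positive)}
#'   \item{mp_score}{continuous 70-gene risk index}
#'   \item{mp_class}{`"Hi1"` or `"Hi2"`, derived from `mp_score`}
#'   \item{randomization_day}{integer calendar day of randomization}
#'   \item{pcr}{pathologic complete response (ypT0/is, ypN0), 0/1 or `NA`}
#'   \item{deviation}{one of `"none"`, `"nonprotocol_therapy"`,
#'     `"no_surgery"`, `"withdrew"`}
#' }
#'
#' @param df data.frame with the columns above (`mp_class` optional; it is
#'   recomputed from `mp_score`).
#' @return validated patient table with `mp_class` consistent with
#'   `mp_score`.
#' @export
as_patient_table <- function(df) {
  req <- c("patient_id", "arm", "hr", "her2", "mp_score",
           "randomization_day", "pcr", "deviation")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0) {
    stop("patient table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  df$patient_id <- as.character(df$patient_id)
  if (anyDuplicated(df$patient_id)) {
    dup <- unique(df$patient_id[duplicated(df$patient_id)])
    stop("duplicated patient_id: ", paste(dup, collapse = ", "))
  }
  if (!all(df$hr %in% c(0, 1)) || !all(df$her2 %in% c(0, 1))) {
    stop("hr and her2 must be coded 0/1")
  }
  bad_dev <- setdiff(unique(df$deviation), deviation_levels())
  if (length(bad_dev) > 0) {
    stop("unknown deviation value(s): ", paste(bad_dev, collapse = ", "))
  }
  if (!all(df$pcr %in% c(0, 1, NA))) stop("pcr must be 0, 1 or NA")
  df$mp_class <- mp_class(df$mp_score)
  df
}

deviation_levels <- function() {
  c("none", "nonprotocol_therapy", "no_surgery", "withdrew")
}

#' Dichotomize the 70-gene risk score into Hi1 / Hi2
#'
#' Scores strictly below -0.573 are the higher-risk Hi2 class.
#'
#' @param mp_score numeric vector of 70-gene index values.
#' @return character vector `"Hi1"` / `"Hi2"`.
#' @export
mp_class <- function(mp_score) {
  ifelse(mp_score < -0.573, "Hi2", "Hi1")
}

#' Impute the binary endpoint under the protocol-deviation rule
#'
#' Participants who switch to non-protocol therapy, forgo surgery, or
#' withdraw are counted as non-pCR. An observed outcome is never changed.
#' Records with a missing outcome and no deviation are unevaluable and are
#' returned as `NA` with a warning.
#'
#' @param pcr 0/1/NA outcome vector.
#' @param deviation deviation labels (see [as_patient_table()]).
#' @return 0/1 vector with `NA` only for unevaluable records.
#' @export
impute_endpoint <- function(pcr, deviation) {
  stopifnot(length(pcr) == length(deviation))
  out <- pcr
  dev <- deviation != "none"
  out[is.na(pcr) & dev] <- 0
  n_unev <- sum(is.na(pcr) & !dev)
  if (n_unev > 0) {
    warning(n_unev, " record(s) with missing pCR and no protocol deviation",
            " are unevaluable")
  }
  out
}

#' Build the analysis set: impute the endpoint, drop unevaluable records
#'
#' @param patients patient table ([as_patient_table()]).
#' @return patient table with `pcr` imputed and unevaluable rows removed
#'   (count reported via message).
#' @export
prepare_analysis_set <- function(patients) {
  patients <- as_patient_table(patients)
  pcr <- suppressWarnings(impute_endpoint(patients$pcr, patients$deviation))
  drop <- is.na(pcr)
  if (any(drop)) {
    message("excluding ", sum(drop), " unevaluable record(s) ",
            "(missing pCR, no deviation)")
  }
  patients$pcr <- pcr
  patients[!drop, , drop = FALSE]
}
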