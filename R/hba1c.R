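# Glycemic-control analysis of longitudinal HbA1c: baseline
# classification at the 5.7% upper limit of normal (6.5% for the diabetes
# criterion), on-treatment transition counting, and the pCR-by-glycemia
# comparison.

#' Classify an HbA1c value (%)
#'
#' `normal` at or below 5.7 (the upper limit of normal), `elevated`
#' strictly above 5.7, `diabetic_range` strictly above 6.5 (a subset of
#' elevated; the most specific class is returned).
#'
#' @param value HbA1c in percent (> 0), vectorized.
#' @return factor with levels `normal`, `elevated`, `diabetic_range`.
#' @export
classify_hba1c <- function(value) {
  stopifnot(all(value > 0))
  cls <- ifelse(value > 6.5, "diabetic_range",
                ifelse(value > 5.7, "elevated", "normal"))
  factor(cls, levels = c("normal", "elevated", "diabetic_range"))
}

hba1c_elevated <- function(value) value > 5.7

validate_hba1c <- function(series) {
  req <- c("patient_id", "day", "value", "phase")
  missing_cols <- setdiff(req, names(series))
  if (length(missing_cols) > 0) {
    stop("HbA1c table missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  if (any(series$value <= 0)) stop("HbA1c values must be > 0")
  bad <- setdiff(unique(series$phase),
                 c("baseline", "on_treatment", "post"))
  if (length(bad) > 0) stop("unknown phase label(s): ",
                            paste(bad, collapse = ", "))
  ord <- order(series$patient_id, series$day)
  series[ord, , drop = FALSE]
}

#' Analysis cohort: baseline plus at least one on-treatment measurement
#'
#' @param series long HbA1c table: `patient_id`, `day`, `value`, `phase`
#'   (`baseline` / `on_treatment` / `post`).
#' @return list: `cohort` (qualifying rows), `n`, and mean/SD of the first
#'   on-treatment measurement day.
#' @export
analysis_cohort <- function(series) {
  series <- validate_hba1c(series)
  by_pat <- split(series, series$patient_id)
  ok <- vapply(by_pat, function(d) {
    any(d$phase == "baseline") && any(d$phase == "on_treatment")
  }, logical(1))
  cohort <- do.call(rbind, by_pat[ok])
  rownames(cohort) <- NULL
  first_tx <- vapply(by_pat[ok], function(d) {
    min(d$day[d$phase == "on_treatment"])
  }, numeric(1))
  list(cohort = cohort, n = sum(ok),
       first_on_treatment_day_mean = if (sum(ok)) mean(first_tx) else NA,
       first_on_treatment_day_sd = if (sum(ok) > 1) stats::sd(first_tx)
       else NA)
}

# per-patient baseline value: the latest baseline-phase measurement
baseline_values <- function(cohort) {
  vapply(split(cohort, cohort$patient_id), function(d) {
    b <- d[d$phase == "baseline", ]
    b$value[which.max(b$day)]
  }, numeric(1))
}

#' On-treatment glycemic transitions
#'
#' Splits the cohort by baseline class (elevated = HbA1c > 5.7). A
#' normal-baseline patient "became elevated" if any on-treatment value
#' exceeds 5.7; an elevated-baseline patient "stayed elevated" if all
#' on-treatment values remain above 5.7.
#'
#' @param cohort qualifying rows from [analysis_cohort()].
#' @return named integer vector: `n_normal_baseline`, `n_became_elevated`,
#'   `n_elevated_baseline`, `n_stayed_elevated`.
#' @export
transition_counts <- function(cohort) {
  base <- baseline_values(cohort)
  by_pat <- split(cohort, cohort$patient_id)
  on_tx <- lapply(by_pat, function(d) d$value[d$phase == "on_treatment"])
  elev0 <- hba1c_elevated(base)
  became <- vapply(on_tx[!elev0], function(v) any(hba1c_elevated(v)),
                   logical(1))
  stayed <- vapply(on_tx[elev0], function(v) all(hba1c_elevated(v)),
                   logical(1))
  c(n_normal_baseline = sum(!elev0),
    n_became_elevated = sum(became),
    n_elevated_baseline = sum(elev0),
    n_stayed_elevated = sum(stayed))
}

#' pCR rate by baseline glycemic class
#'
#' @param cohort qualifying rows from [analysis_cohort()].
#' @param pcr named 0/1 vector of outcomes (names = patient ids).
#' @param threshold baseline split point (default 5.7).
#' @return list: per-class `n`, pCR rates, the 2x2 table, and the
#'   two-sided Fisher exact p ([fisher_2x2()]).
#' @export
pcr_by_glycemia <- function(cohort, pcr, threshold = 5.7) {
  base <- baseline_values(cohort)
  ids <- names(base)
  if (!all(ids %in% names(pcr))) {
    stop("pcr missing for patient(s): ",
         paste(setdiff(ids, names(pcr)), collapse = ", "))
  }
  y <- pcr[ids]
  elev <- base > threshold
  tab <- rbind(normal = c(pcr = sum(y[!elev]), no_pcr = sum(!elev) -
                            sum(y[!elev])),
               elevated = c(pcr = sum(y[elev]), no_pcr = sum(elev) -
                              sum(y[elev])))
  p <- if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    suppressWarnings(fisher_2x2(tab))
  } else {
    fisher_2x2(tab)
  }
  list(n_normal = sum(!elev), n_elevated = sum(elev),
       rate_normal = if (sum(!elev)) mean(y[!elev]) else NA,
       rate_elevated = if (sum(elev)) mean(y[elev]) else NA,
       table = tab, fisher_p = p)
}

#' Full glycemic-control report
#'
#' Baseline classification over everyone with a baseline value (both the
#' all-baseline denominator and the analysis-cohort denominator are
#' reported; they can differ), transition counts, and optionally the
#' pCR-by-glycemia comparison.
#'
#' @param series long HbA1c table.
#' @param pcr optional named 0/1 outcome vector.
#' @return list of counts/rates suitable for JSON serialization.
#' @export
hba1c_report <- function(series, pcr = NULL) {
  series <- validate_hba1c(series)
  with_base <- split(series, series$patient_id)
  has_base <- vapply(with_base, function(d) any(d$phase == "baseline"),
                     logical(1))
  base_all <- vapply(with_base[has_base], function(d) {
    b <- d[d$phase == "baseline", ]
    b$value[which.max(b$day)]
  }, numeric(1))
  co <- analysis_cohort(series)
  tr <- transition_counts(co$cohort)
  out <- list(
    n_with_baseline = sum(has_base),
    n_baseline_elevated = sum(hba1c_elevated(base_all)),
    frac_baseline_elevated = mean(hba1c_elevated(base_all)),
    n_baseline_diabetic_range = sum(base_all > 6.5),
    median_baseline = stats::median(base_all),
    cohort_n = co$n,
    first_on_treatment_day_mean = co$first_on_treatment_day_mean,
    first_on_treatment_day_sd = co$first_on_treatment_day_sd,
    transitions = as.list(tr),
    frac_became_elevated = unname(tr["n_became_elevated"] /
                                    tr["n_normal_baseline"])
  )
  if (!is.null(pcr)) out$pcr_by_glycemia <- pcr_by_glycemia(co$cohort, pcr)
  out
}
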