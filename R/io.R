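# Readers and writers for the interchange schemas (patient CSV, expression
# TSV, signature files, HbA1c CSV, JSON reports, YAML configuration) and
# the per-run manifest. CSV dialect: comma-separated, UTF-8, "." decimal,
# NA for missing.

normalize_binary_status <- function(x, column) {
  key <- tolower(trimws(as.character(x)))
  map <- c(pos = 1, positive = 1, "1" = 1, "+" = 1,
           neg = 0, negative = 0, "0" = 0, "-" = 0)
  out <- map[key]
  if (any(is.na(out))) {
    bad <- which(is.na(out))
    stop("unparseable ", column, " value(s) at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), ": ",
         paste(utils::head(unique(x[bad]), 5), collapse = ", "))
  }
  unname(out)
}

#' Read a patient table from CSV
#'
#' Expected header: `patient_id,arm,hr,her2,mp_score,randomization_day,
#' pcr,deviation`; `hr`/`her2` accept `pos`/`positive`/`1` and
#' `neg`/`negative`/`0`; `pcr` is 0/1/NA.
#'
#' @param path CSV file path.
#' @return validated patient table.
#' @export
read_patient_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("patient_id", "arm", "hr", "her2", "mp_score",
           "randomization_day", "pcr", "deviation")
  if (!all(req %in% names(df))) {
    stop("patient CSV header must contain: ", paste(req, collapse = ","))
  }
  df$hr <- normalize_binary_status(df$hr, "hr")
  df$her2 <- normalize_binary_status(df$her2, "her2")
  as_patient_table(df)
}

#' Write a patient table to CSV
#'
#' @param patients patient table.
#' @param path output path.
#' @export
write_patient_table <- function(patients, path) {
  utils::write.csv(patients, path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a genes x patients expression matrix from TSV
#'
#' First column gene symbols (uppercased), remaining columns numeric
#' patient values. Duplicate symbols are collapsed by mean with a message;
#' a non-numeric cell is an error naming its coordinates.
#'
#' @param path TSV file path.
#' @return expression matrix ([as_expression_matrix()]).
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  genes <- as.character(df[[1]])
  body <- df[, -1, drop = FALSE]
  for (j in seq_along(body)) {
    v <- suppressWarnings(as.numeric(body[[j]]))
    bad <- which(is.na(v) & !is.na(body[[j]]))
    if (length(bad) > 0) {
      stop("non-numeric expression value at gene ", genes[bad[1]],
           ", patient ", names(body)[j])
    }
    body[[j]] <- v
  }
  m <- as.matrix(body)
  rownames(m) <- genes
  as_expression_matrix(m)
}

#' Read a signature file
#'
#' One symbol per line, or two tab-separated columns (symbol, sign in
#' -1/+1) for pre-signed signatures. No header.
#'
#' @param path file path.
#' @param name signature name (default: file name).
#' @return a [signed_signature()].
#' @export
read_signature_file <- function(path, name = basename(path)) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t")
  ncols <- lengths(parts)
  if (all(ncols == 1)) {
    signed_signature(name, vapply(parts, `[[`, "", 1))
  } else if (all(ncols == 2)) {
    signed_signature(name, vapply(parts, `[[`, "", 1),
                     as.integer(vapply(parts, `[[`, "", 2)))
  } else {
    stop("signature file must have 1 or 2 tab-separated columns")
  }
}

#' Read an HbA1c long table from CSV
#'
#' Header: `patient_id,day,value,phase` (phase in
#' baseline/on_treatment/post); an `arm` column is carried through if
#' present.
#'
#' @param path CSV file path.
#' @return validated long table.
#' @export
read_hba1c <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_hba1c(df)
}

#' Serialize an analysis report to JSON
#'
#' @param results list or data.frame (e.g. [arm_summary()] output or
#'   [hba1c_report()]).
#' @param path output path.
#' @return the path, invisibly; `read_report()` round-trips it.
#' @export
write_report <- function(results, path) {
  jsonlite::write_json(results, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Read trial configuration from YAML
#'
#' Top-level keys `prior` and `trial` map onto [tm_prior()] and
#' [trial_config()] arguments; `trial$signatures` entries have `name` and
#' optional `hr`, `her2`, `mp`.
#'
#' @param path YAML file path.
#' @return list with elements `prior` and `trial`.
#' @export
read_trial_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  prior <- do.call(tm_prior, as.list(cfg$prior))
  trial_args <- as.list(cfg$trial)
  if (!is.null(trial_args$signatures)) {
    trial_args$signatures <- lapply(trial_args$signatures, function(s) {
      signature_def(s$name,
                    hr = s$hr %||% NA, her2 = s$her2 %||% NA,
                    mp = s$mp %||% NA)
    })
  }
  list(prior = prior, trial = do.call(trial_config, trial_args))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a run manifest
#'
#' Records the seed, a stable hash of the configuration, input paths,
#' package version and a timestamp, so a deterministic stage can be
#' reproduced bit-for-bit from equal manifest inputs.
#'
#' @param seed integer seed of the run.
#' @param config configuration object (hashed).
#' @param inputs character vector of input paths.
#' @return list of class `run_manifest`.
#' @export
run_manifest <- function(seed, config, inputs = character(0)) {
  structure(list(seed = seed,
                 config_hash = rlang::hash(config),
                 inputs = inputs,
                 package_version =
                   as.character(utils::packageVersion("ispyengine")),
                 timestamp = format(Sys.time(), tz = "UTC",
                                    "%Y-%m-%dT%H:%M:%SZ")),
            class = "run_manifest")
}
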