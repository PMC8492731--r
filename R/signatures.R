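# IGF-axis expression signature scoring: the ligand-correlation score
# (ternary sign vector built against an anchor gene, then per-patient
# correlation) and the signed-signature regression t-statistic score, plus
# tertile classification and single-gene biomarkers.

#' Validate a genes x patients expression matrix
#'
#' @param values numeric matrix, rownames = gene symbols, colnames =
#'   patient ids.
#' @return the matrix with uppercased, unique gene symbols (duplicates
#'   collapsed by per-gene mean, count reported via message).
#' @export
as_expression_matrix <- function(values) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("expression must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("expression matrix needs gene rownames and patient colnames")
  }
  rownames(values) <- toupper(rownames(values))
  if (anyDuplicated(rownames(values))) {
    n_dup <- sum(duplicated(rownames(values)))
    values <- collapse_duplicate_genes(values)
    message("collapsed ", n_dup, " duplicate gene row(s) by mean")
  }
  values
}

collapse_duplicate_genes <- function(values) {
  g <- rownames(values)
  agg <- rowsum(values, group = g, reorder = FALSE)
  counts <- as.vector(table(factor(g, levels = rownames(agg))))
  agg / counts
}

#' Center expression gene-wise across the population
#'
#' @param expr expression matrix ([as_expression_matrix()]).
#' @param method `"mean"` or `"median"` centering per gene.
#' @return centered matrix with attribute `centered` recording the method.
#' @export
center_expression <- function(expr, method = c("mean", "median")) {
  method <- match.arg(method)
  ctr <- if (method == "mean") rowMeans(expr) else
    apply(expr, 1, stats::median)
  out <- expr - ctr
  attr(out, "centered") <- method
  out
}

#' A gene signature with per-gene signs
#'
#' @param name signature label.
#' @param genes gene symbols.
#' @param signs integer vector in \{-1, 0, +1\}, same length as `genes`;
#'   may be `NULL` for signatures whose signs are derived at run time.
#' @return object of class `signed_signature`.
#' @export
signed_signature <- function(name, genes, signs = NULL) {
  genes <- toupper(genes)
  if (!is.null(signs)) {
    if (length(signs) != length(genes)) {
      stop("signs must match genes in length")
    }
    if (!all(signs %in% c(-1, 0, 1))) stop("signs must be -1, 0 or +1")
    signs <- stats::setNames(as.integer(signs), genes)
  }
  structure(list(name = name, genes = genes, signs = signs),
            class = "signed_signature")
}

#' Ternary sign vector of signature genes against an anchor gene
#'
#' Each signature gene is correlated (Pearson) with the anchor gene across
#' the population; its sign entry is the sign of the correlation when the
#' two-sided p-value (t transform, n-2 df) is at or below `p_threshold`,
#' and 0 otherwise. Zero-variance genes get sign 0 with a warning.
#'
#' @param expr expression matrix.
#' @param signature_genes symbols to score (absent genes dropped with a
#'   warning).
#' @param anchor_gene symbol of the anchor (default `"IGF1"`).
#' @param p_threshold significance gate on the correlation (default 0.01).
#' @return named integer vector in \{-1, 0, +1\}.
#' @export
ternary_sign_vector <- function(expr, signature_genes,
                                anchor_gene = "IGF1", p_threshold = 0.01) {
  signature_genes <- toupper(signature_genes)
  anchor_gene <- toupper(anchor_gene)
  if (!anchor_gene %in% rownames(expr)) {
    stop("anchor gene ", anchor_gene, " not in expression matrix")
  }
  n <- ncol(expr)
  if (n < 3) stop("need at least 3 patients for the correlation gate")
  present <- signature_genes %in% rownames(expr)
  if (any(!present)) {
    warning(sum(!present), " signature gene(s) absent from the matrix")
  }
  genes <- signature_genes[present]
  anchor <- expr[anchor_gene, ]
  signs <- vapply(genes, function(g) {
    x <- expr[g, ]
    if (stats::sd(x) == 0 || stats::sd(anchor) == 0) {
      warning("zero-variance gene ", g, ": sign set to 0")
      return(0L)
    }
    r <- stats::cor(x, anchor)
    tt <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
    if (p <= p_threshold) as.integer(sign(r)) else 0L
  }, integer(1))
  signs
}

#' Ligand-correlation signature score
#'
#' Per patient, the Pearson correlation between the ternary sign vector and
#' the patient's centered expression over the signature genes. Scores lie
#' in \[-1, 1\].
#'
#' @param expr expression matrix; centered gene-wise with
#'   [center_expression()] unless `center = FALSE`.
#' @param signs named ternary sign vector ([ternary_sign_vector()]).
#' @param center center `expr` (mean) before scoring (default TRUE).
#' @return named numeric vector of per-patient scores.
#' @export
igf1_ligand_score <- function(expr, signs, center = TRUE) {
  genes <- intersect(names(signs), rownames(expr))
  if (length(genes) < 3) stop("fewer than 3 signature genes present")
  s <- signs[genes]
  if (sum(s != 0) < 2) {
    stop("non-informative signature: fewer than 2 nonzero signs")
  }
  if (center) expr <- center_expression(expr, "mean")
  scores <- suppressWarnings(stats::cor(as.numeric(s), expr[genes, ]))
  stats::setNames(as.numeric(scores), colnames(expr))
}

#' Signed-signature regression t-statistic score
#'
#' Expression is median-centered gene-wise over the population; for each
#' patient the slope t-statistic of the regression of the patient's
#' signature-gene expression on the binary (-1/+1) sign vector is computed
#' and negated; the population vector is then z-scored to mean 0, SD 1.
#'
#' @param expr expression matrix.
#' @param signature a [signed_signature()] with binary signs.
#' @param center median-center before scoring (default TRUE).
#' @param zscore return the z-scored population vector (default); set
#'   `FALSE` for the raw negated t-statistics.
#' @return named numeric vector (population mean 0, SD 1 when z-scored).
#' @export
igfr_creighton_score <- function(expr, signature, center = TRUE,
                                 zscore = TRUE) {
  signs <- signature$signs
  if (is.null(signs) || !all(signs %in% c(-1, 1))) {
    stop("signature signs must be binary -1/+1")
  }
  genes <- intersect(names(signs), rownames(expr))
  if (length(genes) < 3) stop("fewer than 3 signature genes present")
  if (center) expr <- center_expression(expr, "median")
  s <- as.numeric(signs[genes])
  X <- expr[genes, , drop = FALSE]
  g <- length(s)
  # closed-form simple regression of each patient column on s
  sc <- s - mean(s)
  ssx <- sum(sc^2)
  slope <- as.vector(crossprod(sc, X)) / ssx
  fitted_int <- colMeans(X)
  rss <- vapply(seq_len(ncol(X)), function(j) {
    res <- X[, j] - fitted_int[j] - slope[j] * sc
    sum(res^2)
  }, numeric(1))
  se <- sqrt(rss / (g - 2) / ssx)
  tstat <- slope / se
  raw <- -tstat
  out <- if (zscore) (raw - mean(raw)) / stats::sd(raw) else raw
  stats::setNames(out, colnames(expr))
}

#' Tertile classification of a score vector
#'
#' Splits the population at the empirical 1/3 and 2/3 quantiles; values at
#' or below a cutpoint fall in the lower class (boundary ties absorbed
#' downward). A degenerate all-equal vector is assigned entirely to `low`
#' with a warning.
#'
#' @param scores numeric vector (>= 3 values).
#' @return factor with levels `low`, `intermediate`, `high`.
#' @export
tertile_class <- function(scores) {
  if (length(scores) < 3) stop("need at least 3 values")
  q <- stats::quantile(scores, c(1, 2) / 3, names = FALSE)
  if (q[1] == q[2] && all(scores == scores[1])) {
    warning("all scores equal: assigning every patient to 'low'")
    return(factor(rep("low", length(scores)),
                  levels = c("low", "intermediate", "high")))
  }
  cls <- ifelse(scores <= q[1], "low",
                ifelse(scores <= q[2], "intermediate", "high"))
  factor(cls, levels = c("low", "intermediate", "high"))
}

igf_axis_genes <- function() {
  c("IGF1", "IGF2", "IGF1R", "INSR", "IGFBP2", "IRS1", "IRS2",
    "IGFBP3", "IGFBP4", "IGFBP5", "CDH1")
}

#' Single-gene IGF-axis biomarkers plus the IGFBP5/IGFBP4 ratio
#'
#' Extracts per-patient expression of the 11 IGF-1R pathway genes (IGF1,
#' IGF2, IGF1R, INSR, IGFBP2, IRS1, IRS2, IGFBP3, IGFBP4, IGFBP5, CDH1) and
#' the IGFBP5/IGFBP4 ratio; expression is log scale so the ratio is the
#' difference of the two rows. Missing genes are omitted with a warning.
#'
#' @param expr expression matrix.
#' @return data.frame: patients x available markers.
#' @export
gene_level_biomarkers <- function(expr) {
  genes <- igf_axis_genes()
  present <- genes %in% rownames(expr)
  if (any(!present)) {
    warning("gene(s) absent, omitted: ",
            paste(genes[!present], collapse = ", "))
  }
  out <- as.data.frame(t(expr[genes[present], , drop = FALSE]))
  if (all(c("IGFBP5", "IGFBP4") %in% rownames(expr))) {
    out$IGFBP5_IGFBP4_ratio <- expr["IGFBP5", ] - expr["IGFBP4", ]
  }
  out
}
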