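#' Two-group fold change and Student's t-test
#'
#' Pooled-variance (Student's) two-sided t-test comparing SCI against sham,
#' plus the fold change on the scale conventional for the layer: for the
#' methylation layer the ratio of group means of percent-m6A; for the
#' expression layer 2 to the difference of group means of log2 expression
#' (pass `log2(expression)` values with `geometric = TRUE`).
#'
#' Degenerate inputs: when both groups have zero within-group variance the
#' p-value is 1 for equal means and 0 otherwise (the difference is then
#' exact).
#'
#' @param values_sham,values_sci Numeric vectors (>= 2 each).
#' @param geometric If TRUE, inputs are log2 values and
#'   `fc = 2^(mean_sci - mean_sham)`; otherwise `fc = mean_sci/mean_sham`.
#' @return A list `mean_sham, mean_sci, fc, log2fc, p_value`.
#' @export
group_test <- function(values_sham, values_sci, geometric = FALSE) {
  if (length(values_sham) < 2 || length(values_sci) < 2)
    stop("need >= 2 values per group")
  m0 <- mean(values_sham); m1 <- mean(values_sci)
  v0 <- stats::var(values_sham); v1 <- stats::var(values_sci)
  if (v0 == 0 && v1 == 0) {
    p <- if (m0 == m1) 1 else 0
  } else {
    p <- stats::t.test(values_sci, values_sham, var.equal = TRUE)$p.value
  }
  fc <- if (geometric) 2^(m1 - m0) else m1 / m0
  list(mean_sham = m0, mean_sci = m1, fc = fc, log2fc = log2(fc),
       p_value = p)
}

#' Screen a fold change / p-value pair into a differential status
#'
#' Methylation layer: `fc >= fc_cutoff` with `p < p_cutoff` is "hyper",
#' `fc <= 1/fc_cutoff` with `p < p_cutoff` is "hypo", anything else "ns".
#' Expression layer analogously with "up"/"down". The fold-change boundary
#' is inclusive: a cutoff of 1.5 is read as a minimum.
#'
#' @param fc Linear fold change (> 0).
#' @param p_value Raw p-value.
#' @param layer "methylation" or "expression".
#' @param fc_cutoff Fold-change cutoff (> 1). Default 1.5.
#' @param p_cutoff p-value cutoff. Default 0.05.
#' @return One of "hyper", "hypo", "up", "down", "ns" (vectorized).
#' @export
screen_status <- function(fc, p_value, layer = c("methylation", "expression"),
                          fc_cutoff = 1.5, p_cutoff = 0.05) {
  layer <- match.arg(layer)
  stopifnot(fc_cutoff > 1)
  up_lab <- if (layer == "methylation") "hyper" else "up"
  dn_lab <- if (layer == "methylation") "hypo" else "down"
  ifelse(p_value < p_cutoff & fc >= fc_cutoff, up_lab,
         ifelse(p_value < p_cutoff & fc <= 1 / fc_cutoff, dn_lab, "ns"))
}

#' Differential table for both layers and both biotypes
#'
#' Runs [group_test()] per transcript on the methylation layer (percent-m6A,
#' arithmetic fold change; optionally logit-transformed via the config flag)
#' and the expression layer (log2 expression, geometric fold change), screens
#' each record with [screen_status()], and reports Benjamini-Hochberg
#' adjusted p-values computed within layer x biotype strata. Screening uses
#' raw p-values; the adjusted values are reported alongside.
#'
#' @param quant Quantification data.frame from [compute_quant()].
#' @param design A `meriparray_design`.
#' @param annotation Annotation data.frame (for biotype).
#' @param config A [run_config()].
#' @return A data.frame of differential records, one row per transcript per
#'   layer, ordered by layer then transcript_id.
#' @export
differential_table <- function(quant, design, annotation,
                               config = run_config()) {
  design <- as_design(as.data.frame(design))
  tx <- sort(unique(quant$transcript_id))
  miss <- setdiff(tx, annotation$transcript_id)
  if (length(miss))
    stop("transcripts missing from annotation: ",
         paste(utils::head(miss, 5), collapse = ", "))
  sham_ids <- design$sample_id[design$group == "sham"]
  sci_ids <- design$sample_id[design$group == "sci"]

  # transcript x sample matrices
  to_mat <- function(values) {
    m <- matrix(NA_real_, nrow = length(tx), ncol = nrow(design),
                dimnames = list(tx, design$sample_id))
    m[cbind(quant$transcript_id, quant$sample_id)] <- values
    if (anyNA(m)) stop("quant table is not complete (transcript x sample)")
    m
  }
  meth <- to_mat(quant$m6a_percent)
  expr <- to_mat(log2(quant$expression))
  if (config$meth_on_logit)
    meth_test <- stats::qlogis(pmin(pmax(meth / 100, 1e-12), 1 - 1e-12))
  else meth_test <- meth

  row_t <- function(mat_test, sham, sci) {
    n0 <- length(sham); n1 <- length(sci)
    m0 <- rowMeans(mat_test[, sham, drop = FALSE])
    m1 <- rowMeans(mat_test[, sci, drop = FALSE])
    v0 <- apply(mat_test[, sham, drop = FALSE], 1, stats::var)
    v1 <- apply(mat_test[, sci, drop = FALSE], 1, stats::var)
    sp2 <- ((n0 - 1) * v0 + (n1 - 1) * v1) / (n0 + n1 - 2)
    se <- sqrt(sp2 * (1 / n0 + 1 / n1))
    tstat <- (m1 - m0) / se
    p <- 2 * stats::pt(abs(tstat), df = n0 + n1 - 2, lower.tail = FALSE)
    degenerate <- se == 0
    p[degenerate] <- ifelse(m0[degenerate] == m1[degenerate], 1, 0)
    p
  }
  p_meth <- row_t(meth_test, sham_ids, sci_ids)
  p_expr <- row_t(expr, sham_ids, sci_ids)

  biotype <- annotation$biotype[match(tx, annotation$transcript_id)]
  mk <- function(layer, mat, p, geometric) {
    m0 <- rowMeans(mat[, sham_ids, drop = FALSE])
    m1 <- rowMeans(mat[, sci_ids, drop = FALSE])
    fc <- if (geometric) 2^(m1 - m0) else m1 / m0
    df <- data.frame(transcript_id = tx, biotype = biotype, layer = layer,
                     mean_sham = m0, mean_sci = m1, fc = fc,
                     log2fc = log2(fc), p_value = p, stringsAsFactors = FALSE)
    df$adj_p <- NA_real_
    for (bt in unique(df$biotype)) {
      sel <- df$biotype == bt
      df$adj_p[sel] <- stats::p.adjust(df$p_value[sel], method = "BH")
    }
    df$status <- screen_status(df$fc, df$p_value, layer,
                               config$fc_cutoff_screen, config$p_cutoff)
    df
  }
  rbind(mk("methylation", meth, p_meth, geometric = FALSE),
        mk("expression", expr, p_expr, geometric = TRUE))
}

#' Summarize differential status counts per layer and biotype
#'
#' @param diff A differential table from [differential_table()].
#' @return A data.frame of counts (layer, biotype, status, n).
#' @export
differential_summary <- function(diff) {
  tab <- as.data.frame(table(layer = diff$layer, biotype = diff$biotype,
                             status = diff$status),
                       stringsAsFactors = FALSE)
  names(tab)[4] <- "n"
  tab[tab$n > 0, , drop = FALSE]
}

#' Count DME transcripts by conjoint mode
#'
#' Counts rows of a quadrant table (or any table with a `mode` column,
#' such as an exported differentially-methylated-and-expressed list) per
#' conjoint mode, optionally split by biotype.
#'
#' @param quadrants Data.frame with columns `mode` and optionally `biotype`.
#' @return Named integer vector (or a data.frame when biotype is present).
#' @export
count_dme_modes <- function(quadrants) {
  if ("biotype" %in% names(quadrants)) {
    tab <- as.data.frame(table(biotype = quadrants$biotype,
                               mode = quadrants$mode),
                         stringsAsFactors = FALSE)
    names(tab)[3] <- "n"
    return(tab[tab$mode != "none", , drop = FALSE])
  }
  cnt <- table(quadrants$mode)
  out <- as.integer(cnt)
  names(out) <- names(cnt)
  out[names(out) != "none"]
}
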