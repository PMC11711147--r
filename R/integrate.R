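#' Nine-quadrant conjoint classification of methylation vs expression
#'
#' Places every transcript in the 3x3 grid {hyper, ns, hypo} x
#' {up, ns, down} using the conjoint thresholds: an axis is non-ns iff its
#' fold change passes `fc_cutoff_conjoint` (default 2, i.e. |log2FC| >= 1,
#' boundary inclusive) AND its raw p-value is below `p_cutoff`. The conjoint
#' mode is one of hyper-up, hyper-down, hypo-up, hypo-down when both axes
#' are non-ns, otherwise "none"; hyper-up and hypo-down are the concordant
#' modes.
#'
#' @param meth,expr Differential records for the methylation and expression
#'   layers (rows of [differential_table()]).
#' @param config A [run_config()].
#' @return A data.frame `transcript_id, biotype, meth_log2fc, expr_log2fc,
#'   meth_p, expr_p, meth_axis, expr_axis, quadrant, mode`.
#' @export
nine_quadrant <- function(meth, expr, config = run_config()) {
  if (!setequal(meth$transcript_id, expr$transcript_id)) {
    only <- c(setdiff(meth$transcript_id, expr$transcript_id),
              setdiff(expr$transcript_id, meth$transcript_id))
    stop("transcripts present in one layer only: ",
         paste(utils::head(only, 5), collapse = ", "))
  }
  e <- expr[match(meth$transcript_id, expr$transcript_id), , drop = FALSE]
  lcut <- log2(config$fc_cutoff_conjoint)
  axis_call <- function(log2fc, p, up, dn) {
    sig <- p < config$p_cutoff & abs(log2fc) >= lcut
    ifelse(sig & log2fc > 0, up, ifelse(sig & log2fc < 0, dn, "ns"))
  }
  meth_axis <- axis_call(meth$log2fc, meth$p_value, "hyper", "hypo")
  expr_axis <- axis_call(e$log2fc, e$p_value, "up", "down")
  mode <- ifelse(meth_axis != "ns" & expr_axis != "ns",
                 paste(meth_axis, expr_axis, sep = "-"), "none")
  data.frame(transcript_id = meth$transcript_id, biotype = meth$biotype,
             meth_log2fc = meth$log2fc, expr_log2fc = e$log2fc,
             meth_p = meth$p_value, expr_p = e$p_value,
             meth_axis = meth_axis, expr_axis = expr_axis,
             quadrant = paste(meth_axis, expr_axis, sep = "/"),
             mode = mode, stringsAsFactors = FALSE)
}

#' Venn-style counts of differential and conjoint transcripts
#'
#' Per biotype: the number of transcripts differential on the methylation
#' axis, on the expression axis, and in each concordant/discordant conjoint
#' mode (the overlap structure behind a methylation-vs-expression Venn
#' diagram).
#'
#' @param quadrants Output of [nine_quadrant()].
#' @return A nested list, by biotype.
#' @export
venn_counts <- function(quadrants) {
  out <- list()
  for (bt in sort(unique(quadrants$biotype))) {
    q <- quadrants[quadrants$biotype == bt, ]
    out[[bt]] <- list(
      meth_differential = sum(q$meth_axis != "ns"),
      expr_differential = sum(q$expr_axis != "ns"),
      both = sum(q$mode != "none"),
      `hyper-up` = sum(q$mode == "hyper-up"),
      `hypo-down` = sum(q$mode == "hypo-down"),
      `hyper-down` = sum(q$mode == "hyper-down"),
      `hypo-up` = sum(q$mode == "hypo-up"))
  }
  out
}

# interval helpers: 0-based half-open; gap 0 when intervals overlap or touch
interval_gap <- function(s1, e1, s2, e2) {
  pmax(0L, pmax(s2 - e1, s1 - e2))
}

#' Positional classification of a lncRNA relative to coding genes
#'
#' Assigns one of six positional classes by precedence:
#' exon-sense-overlapping (overlaps a coding gene span on the same strand),
#' intronic (contained in a coding span, same strand; span containment
#' stands in for intron containment since exon structure is not modeled),
#' natural-antisense (overlaps, opposite strand), intronic-antisense
#' (contained, opposite strand), bidirectional (TSS within 1 kb of a coding
#' TSS on the opposite strand, no overlap), intergenic (none of the above).
#'
#' @param lnc One-row data.frame (annotation record) of the lncRNA.
#' @param mrnas Annotation data.frame of coding genes.
#' @param bidi_window TSS distance for the bidirectional class. Default 1000.
#' @return A single class string.
#' @export
classify_lncrna <- function(lnc, mrnas, bidi_window = 1000L) {
  m <- mrnas[mrnas$chrom == lnc$chrom, , drop = FALSE]
  if (nrow(m) == 0) return("intergenic")
  overlaps <- m$start < lnc$end & lnc$start < m$end
  # strict containment (a proper subinterval) stands in for "inside an
  # intron"; an identical span is exonic overlap, not containment
  inside <- m$start <= lnc$start & lnc$end <= m$end &
    !(m$start == lnc$start & m$end == lnc$end)
  same <- m$strand == lnc$strand
  if (any(overlaps & same & !inside)) return("exon-sense-overlapping")
  if (any(inside & same)) return("intronic")
  if (any(overlaps & !same & !inside)) return("natural-antisense")
  if (any(inside & !same)) return("intronic-antisense")
  tss_l <- if (lnc$strand == "+") lnc$start else lnc$end
  tss_m <- ifelse(m$strand == "+", m$start, m$end)
  if (any(!same & !overlaps & abs(tss_m - tss_l) <= bidi_window))
    return("bidirectional")
  "intergenic"
}

#' Classify every lncRNA in an annotation
#'
#' @param annotation Annotation data.frame with both biotypes.
#' @param bidi_window See [classify_lncrna()].
#' @return A data.frame `transcript_id, lncrna_class`.
#' @export
classify_lncrnas <- function(annotation, bidi_window = 1000L) {
  lncs <- annotation[annotation$biotype == "lncRNA", , drop = FALSE]
  mrnas <- annotation[annotation$biotype == "mRNA", , drop = FALSE]
  cls <- vapply(seq_len(nrow(lncs)), function(i)
    classify_lncrna(lncs[i, ], mrnas, bidi_window), character(1))
  data.frame(transcript_id = lncs$transcript_id, lncrna_class = cls,
             stringsAsFactors = FALSE)
}

#' Map lncRNAs to cis-target mRNAs within a genomic window
#'
#' A pair is emitted iff both genes are on the same chromosome and the gap
#' between their spans (0-based half-open) is at most `window` bp, boundary
#' inclusive and strand-agnostic. Overlapping genes have distance 0.
#'
#' @param lncs Annotation rows of lncRNAs.
#' @param mrnas Annotation rows of mRNAs.
#' @param window Window in bp. Default 100000.
#' @return A data.frame `lncrna_id, mrna_id, distance_bp` ordered by
#'   lncrna_id then mrna_id.
#' @export
find_cis_targets <- function(lncs, mrnas, window = 100000L) {
  out <- list()
  for (ch in intersect(unique(lncs$chrom), unique(mrnas$chrom))) {
    l <- lncs[lncs$chrom == ch, , drop = FALSE]
    m <- mrnas[mrnas$chrom == ch, , drop = FALSE]
    li <- rep(seq_len(nrow(l)), each = nrow(m))
    mi <- rep(seq_len(nrow(m)), times = nrow(l))
    gap <- interval_gap(l$start[li], l$end[li], m$start[mi], m$end[mi])
    keep <- gap <= window
    if (any(keep))
      out[[ch]] <- data.frame(lncrna_id = l$transcript_id[li[keep]],
                              mrna_id = m$transcript_id[mi[keep]],
                              distance_bp = as.integer(gap[keep]),
                              stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(lncrna_id = character(), mrna_id = character(),
                      distance_bp = integer(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$lncrna_id, res$mrna_id), , drop = FALSE]
}
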