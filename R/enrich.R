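#' Hypergeometric over-representation test against gene sets
#'
#' One-sided over-representation: for a study list of size n drawn from a
#' universe of size N, and a set with K members in the universe and k in the
#' study list, p = P(X >= k) for X ~ Hypergeometric(N, K, n), computed by
#' summing the probability mass function. Benjamini-Hochberg adjustment is
#' applied across all tested sets. Study genes outside the universe are
#' dropped with a warning; set members are intersected with the universe to
#' obtain K.
#'
#' @param study Character vector of study genes.
#' @param universe Character vector of background genes (e.g. everything on
#'   the array).
#' @param sets Named list of gene sets (see [read_gmt()]).
#' @param p_cutoff Significance cutoff for the `significant` flag. Default
#'   0.05.
#' @return A data.frame `set_id, k, n, K, N, p_value, adj_p, significant`,
#'   sorted by p-value with ties broken by set_id.
#' @export
hypergeom_enrich <- function(study, universe, sets, p_cutoff = 0.05) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  study <- unique(study)
  outside <- setdiff(study, universe)
  if (length(outside)) {
    warning(length(outside), " study gene(s) outside the universe dropped")
    study <- intersect(study, universe)
  }
  if (!length(study)) stop("empty study list after intersecting the universe")
  N <- length(universe); n <- length(study)
  res <- do.call(rbind, lapply(names(sets), function(sid) {
    members <- intersect(unique(sets[[sid]]), universe)
    K <- length(members)
    k <- length(intersect(members, study))
    p <- hyper_upper_tail(k, N, K, n)
    data.frame(set_id = sid, k = k, n = n, K = K, N = N, p_value = p,
               stringsAsFactors = FALSE)
  }))
  if (is.null(res))
    return(data.frame(set_id = character(), k = integer(), n = integer(),
                      K = integer(), N = integer(), p_value = numeric(),
                      adj_p = numeric(), significant = logical()))
  res$adj_p <- stats::p.adjust(res$p_value, method = "BH")
  res$significant <- res$p_value < p_cutoff
  res[order(res$p_value, res$set_id), , drop = FALSE]
}

# P(X >= k) by summing the hypergeometric pmf; exact, p = 1 when k = 0
hyper_upper_tail <- function(k, N, K, n) {
  if (k <= 0) return(1)
  hi <- min(K, n)
  if (k > hi) return(0)
  sum(stats::dhyper(k:hi, K, N - K, n))
}

#' Enrichment of a lncRNA list through its cis-target mRNAs
#'
#' Maps a list of lncRNAs to the union of their cis-target mRNA gene
#' symbols and runs [hypergeom_enrich()] on that target list. lncRNAs with
#' no cis target contribute nothing (their count is reported in a message).
#'
#' @param lnc_study Character vector of lncRNA transcript ids.
#' @param cis Cis-target pairs from [find_cis_targets()].
#' @param annotation Annotation data.frame (maps mRNA transcript ids to gene
#'   symbols).
#' @param universe,sets,p_cutoff Passed to [hypergeom_enrich()].
#' @return See [hypergeom_enrich()].
#' @export
lncrna_enrich_via_cis <- function(lnc_study, cis, annotation, universe, sets,
                                  p_cutoff = 0.05) {
  lnc_study <- unique(lnc_study)
  hit <- cis[cis$lncrna_id %in% lnc_study, , drop = FALSE]
  n_without <- sum(!(lnc_study %in% cis$lncrna_id))
  if (n_without)
    message(n_without, " lncRNA(s) have no cis target within the window")
  targets <- unique(hit$mrna_id)
  symbols <- unique(annotation$gene_symbol[
    match(targets, annotation$transcript_id)])
  symbols <- symbols[!is.na(symbols)]
  if (!length(symbols)) stop("no cis-target genes for the study lncRNAs")
  hypergeom_enrich(symbols, universe, sets, p_cutoff)
}
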