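#' Run the full m6A array analysis pipeline
#'
#' Orchestrates quantification, dual-layer differential screening,
#' nine-quadrant integration, lncRNA classification and cis-target mapping,
#' optional gene-set enrichment and optional PPI/MCODE network analysis,
#' writing every result table (TSV, 12-significant-digit reals) plus a JSON
#' run manifest to `out_dir`. The run is deterministic given fixed inputs;
#' any stage failure aborts with the stage name in the message.
#'
#' @param intensities Path to an intensity TSV or a validated data.frame.
#' @param annotation Path to an annotation TSV or a data.frame.
#' @param design Path to a design TSV or a `meriparray_design`.
#' @param out_dir Output directory (created if needed).
#' @param config A [run_config()].
#' @param gmt Optional path to a GMT file (or a named list of sets); when
#'   omitted the enrichment stage is skipped.
#' @param ppi Optional path to a PPI edge TSV (or a data.frame); when
#'   omitted the network stage is skipped.
#' @param quiet Suppress progress messages. Default FALSE.
#' @return Invisibly, a list with every computed table and the manifest.
#' @export
run_pipeline <- function(intensities, annotation, design, out_dir,
                         config = run_config(), gmt = NULL, ppi = NULL,
                         quiet = FALSE) {
  log_stage <- function(stage, ...) {
    if (!quiet) message("[", stage, "] ", ...)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  design <- stage("input", {
    if (is.character(design)) read_design_table(design)
    else as_design(as.data.frame(design))
  })
  annotation <- stage("input", {
    if (is.character(annotation)) read_annotation_table(annotation)
    else validate_annotation(annotation)
  })
  raw <- stage("input", {
    if (is.character(intensities)) read_intensity_table(intensities, design)
    else validate_intensities(intensities, design)
  })
  log_stage("input", nrow(raw), " intensity rows, ",
            nrow(annotation), " transcripts")

  quant <- stage("quantify", {
    norm <- normalize_spikein(raw, epsilon = config$epsilon)
    compute_quant(norm)
  })
  write_pipeline_table(quant, file.path(out_dir, "quant.tsv"))
  log_stage("quantify", nrow(quant), " transcript x sample quantifications")

  diff <- stage("differential",
                differential_table(quant, design, annotation, config))
  d_meth <- diff[diff$layer == "methylation", , drop = FALSE]
  d_expr <- diff[diff$layer == "expression", , drop = FALSE]
  write_pipeline_table(d_meth, file.path(out_dir, "diff_methylation.tsv"))
  write_pipeline_table(d_expr, file.path(out_dir, "diff_expression.tsv"))
  log_stage("differential", sum(d_meth$status != "ns"), " methylation and ",
            sum(d_expr$status != "ns"), " expression hits")

  quad <- stage("quadrant", nine_quadrant(d_meth, d_expr, config))
  write_pipeline_table(quad, file.path(out_dir, "quadrants.tsv"))
  vc <- venn_counts(quad)
  jsonlite::write_json(vc, file.path(out_dir, "venn_counts.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  log_stage("quadrant", sum(quad$mode != "none"), " conjoint (DME) calls")

  classes <- stage("classify", classify_lncrnas(annotation))
  write_pipeline_table(classes, file.path(out_dir, "lncrna_classes.tsv"))

  cis <- stage("cis", find_cis_targets(
    annotation[annotation$biotype == "lncRNA", , drop = FALSE],
    annotation[annotation$biotype == "mRNA", , drop = FALSE],
    window = config$cis_window))
  write_pipeline_table(cis, file.path(out_dir, "cis_targets.tsv"))
  log_stage("cis", nrow(cis), " lncRNA-mRNA pairs within ",
            config$cis_window, " bp")

  dme_mrna <- quad$transcript_id[quad$mode %in% c("hyper-up", "hypo-down") &
                                   quad$biotype == "mRNA"]
  dme_symbols <- unique(annotation$gene_symbol[
    match(dme_mrna, annotation$transcript_id)])

  enrichment <- NULL
  if (!is.null(gmt)) {
    sets <- if (is.character(gmt)) stage("enrich", read_gmt(gmt)) else gmt
    universe <- unique(annotation$gene_symbol[annotation$biotype == "mRNA"])
    if (length(dme_symbols)) {
      enrichment <- stage("enrich",
                          hypergeom_enrich(dme_symbols, universe, sets,
                                           p_cutoff = config$p_cutoff))
      write_pipeline_table(enrichment, file.path(out_dir, "enrichment.tsv"))
      log_stage("enrich", sum(enrichment$significant), " of ",
                nrow(enrichment), " sets significant")
    } else log_stage("enrich", "no DME mRNAs; enrichment skipped")
  } else log_stage("enrich", "no gene sets supplied; stage skipped")

  clusters <- NULL
  if (!is.null(ppi)) {
    edges <- if (is.character(ppi)) stage("network", read_ppi_table(ppi))
             else ppi
    clusters <- stage("network", {
      sel <- edges$node_a %in% dme_symbols & edges$node_b %in% dme_symbols
      g <- build_graph(edges[sel, , drop = FALSE],
                       score_cutoff = config$ppi_score_cutoff)
      cl <- mcode_find_clusters(g, vwp = config$mcode_vwp)
      igraph::write_graph(g, file.path(out_dir, "network.graphml"),
                          format = "graphml")
      cl
    })
    write_pipeline_table(clusters_table(clusters),
                         file.path(out_dir, "clusters.tsv"))
    log_stage("network", length(clusters), " MCODE clusters")
  } else log_stage("network", "no PPI edges supplied; stage skipped")

  manifest <- list(
    package = "meriparray",
    config = unclass(config),
    seed = config$seed,
    n_transcripts = length(unique(quant$transcript_id)),
    differential_counts = differential_summary(diff),
    dme_counts = lapply(vc, function(x) x[c("hyper-up", "hypo-down")]),
    outputs = list.files(out_dir))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(quant = quant, differential = diff, quadrants = quad,
                 venn = vc, lncrna_classes = classes, cis_targets = cis,
                 enrichment = enrichment, clusters = clusters,
                 manifest = manifest))
}
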