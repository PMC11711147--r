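#' Pipeline run configuration
#'
#' Collects every tunable threshold of the analysis in one validated list.
#' Defaults follow the screening conventions of m6A epitranscriptomic
#' microarray studies: differential screening at 1.5-fold and p < 0.05,
#' conjoint (nine-quadrant) classification at 2-fold (|log2FC| >= 1),
#' a 100-kb cis window, STRING combined-score cutoff 0.4, and MCODE
#' vertex-weight percentage 0.2.
#'
#' @param fc_cutoff_screen Fold-change cutoff for differential screening
#'   (linear scale, > 1; boundary inclusive). Default 1.5.
#' @param p_cutoff Raw p-value cutoff used by every screen. Default 0.05.
#' @param fc_cutoff_conjoint Fold-change cutoff for nine-quadrant conjoint
#'   classification (linear; 2 means |log2FC| >= 1). Default 2.
#' @param cis_window Window in bp around a lncRNA within which an mRNA
#'   counts as a cis target (boundary inclusive). Default 100000.
#' @param ppi_score_cutoff Combined-score cutoff for PPI edges; edges with
#'   score strictly greater than this are kept. Default 0.4.
#' @param mcode_vwp MCODE vertex weight percentage in [0, 1). Default 0.2.
#' @param epsilon Intensity floor added before log2 to avoid log2(0), in
#'   fluorescence units. Default 1.
#' @param meth_on_logit Test the methylation layer on logit-transformed
#'   fractions instead of raw percents. Default FALSE (raw percents).
#' @param seed Integer seed recorded in the run manifest.
#' @return A list of class `"meriparray_config"`.
#' @export
run_config <- function(fc_cutoff_screen = 1.5, p_cutoff = 0.05,
                       fc_cutoff_conjoint = 2, cis_window = 100000L,
                       ppi_score_cutoff = 0.4, mcode_vwp = 0.2,
                       epsilon = 1, meth_on_logit = FALSE, seed = 1L) {
  cfg <- list(fc_cutoff_screen = fc_cutoff_screen, p_cutoff = p_cutoff,
              fc_cutoff_conjoint = fc_cutoff_conjoint,
              cis_window = as.integer(cis_window),
              ppi_score_cutoff = ppi_score_cutoff, mcode_vwp = mcode_vwp,
              epsilon = epsilon, meth_on_logit = isTRUE(meth_on_logit),
              seed = as.integer(seed))
  stopifnot(cfg$fc_cutoff_screen > 1, cfg$p_cutoff > 0,
            cfg$fc_cutoff_conjoint > 1, cfg$cis_window >= 0,
            cfg$ppi_score_cutoff >= 0, cfg$ppi_score_cutoff <= 1,
            cfg$mcode_vwp >= 0, cfg$mcode_vwp < 1, cfg$epsilon > 0)
  class(cfg) <- "meriparray_config"
  cfg
}

#' Read a run configuration from a YAML file
#'
#' Unknown keys are rejected; missing keys take the `run_config()` defaults.
#'
#' @param path Path to a YAML file whose keys match `run_config()` arguments.
#' @return A `"meriparray_config"` list.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(run_config, vals)
}

#' @export
print.meriparray_config <- function(x, ...) {
  cat("m6A array pipeline configuration\n")
  for (k in names(x)) cat(sprintf("  %-18s %s\n", k, format(x[[k]])))
  invisible(x)
}
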