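#' @importFrom utils read.delim write.table
NULL

# Format reals with 12 significant digits so that output tables are
# byte-identical across runs and round-trip exactly enough for testing.
fmt_real <- function(x) {
  out <- sprintf("%.12g", x)
  out[is.na(x)] <- "NA"
  out
}

#' Write a pipeline output table as TSV
#'
#' Numeric columns are formatted with 12 significant digits; a comment line
#' records that genomic coordinates, where present, are 0-based half-open.
#'
#' @param df A data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pipeline_table <- function(df, path) {
  out <- df
  for (j in seq_along(out))
    if (is.double(out[[j]])) out[[j]] <- fmt_real(out[[j]])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# coordinates: 0-based half-open; reals: 12 significant digits", con)
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a table written by [write_pipeline_table()]
#'
#' @param path Path to a TSV written by this package.
#' @return A data.frame.
#' @export
read_pipeline_table <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Read a sample design table
#'
#' Two-column TSV `sample_id group` with groups exactly "sham" and "sci",
#' at least two samples in each.
#'
#' @param path Path to the design TSV.
#' @return A data.frame `sample_id`, `group` of class `meriparray_design`.
#' @export
read_design_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need_cols(df, c("sample_id", "group"), path)
  as_design(df)
}

#' Construct and validate a group design
#'
#' @param df Data.frame with columns `sample_id`, `group`.
#' @return The validated design, classed `meriparray_design`.
#' @export
as_design <- function(df) {
  stopifnot(is.data.frame(df))
  need_cols(df, c("sample_id", "group"), "design")
  if (anyDuplicated(df$sample_id))
    stop("duplicated sample_id in design")
  if (!setequal(unique(df$group), c("sham", "sci")))
    stop("design groups must be exactly {sham, sci}")
  n <- table(df$group)
  if (any(n < 2))
    stop("need >= 2 samples per group; got ",
         paste(sprintf("%s=%d", names(n), n), collapse = ", "))
  df <- df[, c("sample_id", "group")]
  class(df) <- c("meriparray_design", "data.frame")
  df
}

need_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(what, ": missing required column(s): ", paste(miss, collapse = ", "))
  invisible(TRUE)
}

#' Read a raw probe intensity table
#'
#' The table is the pipeline's entry point: one row per probe x sample x
#' channel with columns `probe_id`, `transcript_id`, `sample_id`, `channel`
#' ("IP" or "Sup"), `intensity` (non-negative fluorescence units) and
#' `is_spike_in` (logical). Validation enforces the structural invariants the
#' downstream quantification relies on.
#'
#' @param path Path to the intensity TSV.
#' @param design A `meriparray_design` (see [as_design()]).
#' @return A data.frame of validated probe intensities with a `group` column
#'   joined from the design.
#' @export
read_intensity_table <- function(path, design) {
  if (!file.exists(path)) stop("intensity table not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need_cols(df, c("probe_id", "transcript_id", "sample_id", "channel",
                  "intensity", "is_spike_in"), path)
  df$is_spike_in <- as.logical(df$is_spike_in)
  validate_intensities(df, design)
}

#' Validate probe intensities against a design
#'
#' @param df Intensity data.frame (see [read_intensity_table()]).
#' @param design A `meriparray_design`.
#' @return `df` with a `group` column, invariants checked.
#' @export
validate_intensities <- function(df, design) {
  design <- as_design(as.data.frame(design))
  bad_chan <- setdiff(unique(df$channel), c("IP", "Sup"))
  if (length(bad_chan))
    stop("unknown channel value(s): ", paste(bad_chan, collapse = ", "))
  neg <- which(df$intensity < 0)
  if (length(neg))
    stop("negative intensity at row ", neg[1L],
         " (", fmt_real(df$intensity[neg[1L]]), ")")
  unknown <- setdiff(unique(df$sample_id), design$sample_id)
  if (length(unknown))
    stop("sample_id not in design: ", paste(unknown, collapse = ", "))
  missing_samp <- setdiff(design$sample_id, unique(df$sample_id))
  if (length(missing_samp))
    stop("design sample(s) absent from table: ",
         paste(missing_samp, collapse = ", "))
  for (s in design$sample_id) {
    have <- unique(df$channel[df$sample_id == s])
    lack <- setdiff(c("IP", "Sup"), have)
    if (length(lack))
      stop("sample ", s, " is missing channel ", paste(lack, collapse = ","))
  }
  key <- paste(df$probe_id, df$sample_id, df$channel, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicated (probe_id, sample_id, channel) at row ",
         which(duplicated(key))[1L])
  sc <- unique(df[, c("sample_id", "channel")])
  for (i in seq_len(nrow(sc))) {
    sel <- df$sample_id == sc$sample_id[i] & df$channel == sc$channel[i]
    if (!any(df$is_spike_in[sel]))
      stop("no spike-in probe for sample ", sc$sample_id[i],
           " channel ", sc$channel[i])
  }
  df$group <- design$group[match(df$sample_id, design$sample_id)]
  df
}

#' Read a transcript annotation table
#'
#' BED-like TSV with columns `transcript_id gene_symbol biotype chrom start
#' end strand`; coordinates 0-based half-open, biotype "mRNA" or "lncRNA",
#' strand "+" or "-".
#'
#' @param path Path to the annotation TSV.
#' @return A validated data.frame.
#' @export
read_annotation_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need_cols(df, c("transcript_id", "gene_symbol", "biotype", "chrom",
                  "start", "end", "strand"), path)
  validate_annotation(df)
}

#' Validate a transcript annotation data.frame
#' @param df Annotation data.frame.
#' @return `df`, checked.
#' @export
validate_annotation <- function(df) {
  bad <- setdiff(unique(df$biotype), c("mRNA", "lncRNA"))
  if (length(bad)) stop("unknown biotype: ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(df$strand), c("+", "-"))
  if (length(bad)) stop("unknown strand: ", paste(bad, collapse = ", "))
  if (anyDuplicated(df$transcript_id)) stop("duplicated transcript_id")
  if (any(!(df$start >= 0 & df$start < df$end)))
    stop("require 0 <= start < end for all records")
  df
}

#' Read gene sets in GMT format
#'
#' Standard GMT: `set_id <tab> description <tab> member...`. Duplicate
#' members within a set are dropped; empty sets are dropped with a warning.
#'
#' @param path Path to the GMT file.
#' @return A named list of character vectors (members), with set
#'   descriptions in attribute `"descriptions"`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  descs <- character()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop("GMT line ", i, ": fewer than 3 fields")
    members <- unique(f[-(1:2)])
    members <- members[nzchar(members)]
    if (!length(members)) {
      warning("GMT set ", f[1L], " is empty; dropped")
      next
    }
    sets[[f[1L]]] <- members
    descs[f[1L]] <- f[2L]
  }
  attr(sets, "descriptions") <- descs
  sets
}

#' Read a PPI edge list
#'
#' TSV with columns `node_a node_b combined_score` (scores in [0, 1]).
#'
#' @param path Path to the edge TSV.
#' @return A data.frame of edges.
#' @export
read_ppi_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need_cols(df, c("node_a", "node_b", "combined_score"), path)
  if (any(df$combined_score < 0 | df$combined_score > 1))
    stop("combined_score outside [0, 1]")
  df
}
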