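#' Spike-in anchored normalization of raw two-channel intensities
#'
#' For each sample s and channel c the anchor is the mean over spike-in
#' probes of log2(raw + epsilon). Each probe's normalized signal is
#' log2(raw + epsilon) - anchor(s, c) + G, where G is the grand mean of all
#' anchors; subtracting the per-array anchor on the log2 scale is equivalent
#' to dividing by the geometric-mean spike-in level on the linear scale, and
#' adding G restores an interpretable absolute scale (it cancels in every
#' downstream ratio). This removes any multiplicative factor common to all
#' probes of one array channel exactly.
#'
#' @param raw Validated intensity data.frame (see [read_intensity_table()]).
#' @param epsilon Intensity floor added before taking log2. Default 1.
#' @return A data.frame `probe_id, transcript_id, sample_id, channel,
#'   log2_norm, is_spike_in`.
#' @export
normalize_spikein <- function(raw, epsilon = 1) {
  stopifnot(epsilon > 0)
  sc <- paste(raw$sample_id, raw$channel, sep = "\r")
  log2raw <- log2(raw$intensity + epsilon)
  sp <- raw$is_spike_in
  if (!all(unique(sc) %in% unique(sc[sp]))) {
    miss <- setdiff(unique(sc), unique(sc[sp]))[1L]
    stop("no spike-in probe for sample x channel: ",
         gsub("\r", " / ", miss))
  }
  anchors <- tapply(log2raw[sp], sc[sp], mean)
  G <- mean(anchors)
  out <- raw[, c("probe_id", "transcript_id", "sample_id", "channel",
                 "is_spike_in")]
  out$log2_norm <- log2raw - as.numeric(anchors[sc]) + G
  out[, c("probe_id", "transcript_id", "sample_id", "channel",
          "log2_norm", "is_spike_in")]
}

#' Percent-m6A and expression per transcript per sample
#'
#' Probes are summarized to transcript level by averaging log2-normalized
#' values per transcript x sample x channel (the standard two-channel
#' convention; a no-op with one probe per transcript). With linear values
#' ip = 2^log2_norm(IP) and sup = 2^log2_norm(Sup):
#' \deqn{m6A\% = 100 \cdot ip / (ip + sup), \quad expression = ip + sup.}
#' Spike-in probes are excluded.
#'
#' @param norm Normalized signal data.frame from [normalize_spikein()].
#' @return A data.frame `transcript_id, sample_id, m6a_percent, expression`.
#' @export
compute_quant <- function(norm) {
  x <- norm[!norm$is_spike_in, , drop = FALSE]
  agg <- stats::aggregate(list(log2_norm = x$log2_norm),
                          by = list(transcript_id = x$transcript_id,
                                    sample_id = x$sample_id,
                                    channel = x$channel), FUN = mean)
  ip <- agg[agg$channel == "IP", c("transcript_id", "sample_id", "log2_norm")]
  sup <- agg[agg$channel == "Sup", c("transcript_id", "sample_id", "log2_norm")]
  m <- merge(ip, sup, by = c("transcript_id", "sample_id"),
             suffixes = c("_ip", "_sup"), all = TRUE)
  if (anyNA(m$log2_norm_ip) || anyNA(m$log2_norm_sup)) {
    bad <- m[is.na(m$log2_norm_ip) | is.na(m$log2_norm_sup), ]
    stop("missing channel for transcript ", bad$transcript_id[1L],
         " sample ", bad$sample_id[1L])
  }
  ipv <- 2^m$log2_norm_ip; supv <- 2^m$log2_norm_sup
  out <- data.frame(transcript_id = m$transcript_id,
                    sample_id = m$sample_id,
                    m6a_percent = 100 * ipv / (ipv + supv),
                    expression = ipv + supv, stringsAsFactors = FALSE)
  out[order(out$transcript_id, out$sample_id), , drop = FALSE]
}
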