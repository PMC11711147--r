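#' Simulation configuration for a synthetic two-channel MeRIP array
#'
#' Describes a 3-vs-3 (sham vs SCI) two-channel epitranscriptomic array
#' experiment with spike-in controls and planted differential effects. The
#' generative model mirrors what the quantification assumes: each transcript
#' has a methylated fraction pi and a total expression E; the IP channel
#' measures E*pi and the Sup channel E*(1-pi), each multiplied by a
#' per-array-per-channel scale factor (which spike-in normalization must
#' remove) and by log-normal replicate noise.
#'
#' Methylation effects are planted on the odds scale (logit-additive), so
#' the modified fraction stays inside (0, 1) for any effect size. Because an
#' odds fold change of 2^e can only produce a percent-m6A fold change >= 2
#' when the baseline odds are at most 1 - 2^(1-e), baselines for transcripts
#' carrying a planted methylation effect are drawn from the configured Beta
#' truncated to `meth_planted_max_pi`; this guarantees the planted effects
#' are expressible as fold changes at the screening scale (see the methods
#' vignette).
#'
#' @param n_mrna,n_lncrna Number of mRNA / lncRNA transcripts.
#' @param n_per_group Replicates per group (sham and SCI). Default 3.
#' @param planted Named counts of planted modes among
#'   `c(hyper_up, hypo_down, hyper_only, up_only)`; remaining transcripts are
#'   null. Counts are split between biotypes proportionally.
#' @param meth_effect_log2 Planted methylation effect, log2 odds units.
#' @param expr_effect_log2 Planted expression effect, log2 units.
#' @param noise_sd_log2 Replicate noise SD (log2), applied independently to
#'   each transcript x sample x channel measurement.
#' @param array_scale_sd_log2 SD (log2) of the per-array-per-channel
#'   multiplicative scale factor.
#' @param n_spikein Spike-in probes per array (>= 1).
#' @param spikein_log2 Nominal spike-in intensity, log2 units.
#' @param baseline_meth_alpha,baseline_meth_beta Beta parameters of the sham
#'   methylated fraction.
#' @param meth_planted_max_pi Upper truncation of the baseline fraction for
#'   transcripts with a planted methylation effect.
#' @param expr_mu_log2,expr_sd_log2 Log2-normal parameters of sham expression.
#' @param cis_fraction Fraction of lncRNAs placed within the 100-kb cis
#'   window of an mRNA; the rest are placed > 100 kb from every mRNA.
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @return A list of class `"meriparray_simconfig"`.
#' @export
sim_config <- function(n_mrna = 2000L, n_lncrna = 500L, n_per_group = 3L,
                       planted = c(hyper_up = 100L, hypo_down = 100L,
                                   hyper_only = 50L, up_only = 50L),
                       meth_effect_log2 = 2, expr_effect_log2 = 1.5,
                       noise_sd_log2 = 0.25, array_scale_sd_log2 = 0.25,
                       n_spikein = 10L, spikein_log2 = 10,
                       baseline_meth_alpha = 2, baseline_meth_beta = 6,
                       meth_planted_max_pi = 0.3,
                       expr_mu_log2 = 10, expr_sd_log2 = 1.5,
                       cis_fraction = 0.6, seed = 1L) {
  full <- c(hyper_up = 0L, hypo_down = 0L, hyper_only = 0L, up_only = 0L)
  bad <- setdiff(names(planted), names(full))
  if (length(bad)) stop("unknown planted mode(s): ", paste(bad, collapse = ", "))
  full[names(planted)] <- as.integer(planted)
  cfg <- list(n_mrna = as.integer(n_mrna), n_lncrna = as.integer(n_lncrna),
              n_per_group = as.integer(n_per_group), planted = full,
              meth_effect_log2 = meth_effect_log2,
              expr_effect_log2 = expr_effect_log2,
              noise_sd_log2 = noise_sd_log2,
              array_scale_sd_log2 = array_scale_sd_log2,
              n_spikein = as.integer(n_spikein), spikein_log2 = spikein_log2,
              baseline_meth_alpha = baseline_meth_alpha,
              baseline_meth_beta = baseline_meth_beta,
              meth_planted_max_pi = meth_planted_max_pi,
              expr_mu_log2 = expr_mu_log2, expr_sd_log2 = expr_sd_log2,
              cis_fraction = cis_fraction, seed = as.integer(seed))
  stopifnot(cfg$n_mrna >= 0, cfg$n_lncrna >= 0, cfg$n_per_group >= 2,
            all(cfg$planted >= 0), cfg$noise_sd_log2 >= 0,
            cfg$array_scale_sd_log2 >= 0, cfg$n_spikein >= 1,
            cfg$baseline_meth_alpha > 0, cfg$baseline_meth_beta > 0,
            cfg$meth_planted_max_pi > 0, cfg$meth_planted_max_pi < 1,
            cfg$cis_fraction >= 0, cfg$cis_fraction <= 1,
            cfg$expr_sd_log2 >= 0)
  if (sum(cfg$planted) > cfg$n_mrna + cfg$n_lncrna)
    stop("planted counts exceed the number of transcripts")
  class(cfg) <- "meriparray_simconfig"
  cfg
}

# split a planted count between biotypes proportionally to their sizes
split_count <- function(count, n_mrna, n_lncrna) {
  total <- n_mrna + n_lncrna
  lnc <- if (total == 0) 0L else as.integer(round(count * n_lncrna / total))
  c(mrna = count - lnc, lnc = lnc)
}

#' Simulate a two-channel MeRIP array experiment with planted truth
#'
#' Generates raw probe intensities (one probe per transcript plus shared
#' spike-in probes), a transcript annotation with genomic coordinates
#' arranged so that `cis_fraction` of lncRNAs have exactly one mRNA within
#' 100 kb, a sample design, and a ground-truth table. Per transcript t the
#' sham methylated fraction is pi_t ~ Beta(alpha, beta) (truncated for
#' methylation-planted transcripts, see [sim_config()]) and sham expression
#' E_t = 2^N(mu, sd). SCI values apply the planted log2 effects to the odds
#' pi/(1-pi) and to E. Raw intensities are
#' IP = A_(s,IP) * E * pi * 2^N(0, noise_sd) and
#' Sup = A_(s,Sup) * E * (1-pi) * 2^N(0, noise_sd), with per-array-channel
#' factors A = 2^N(0, array_scale_sd). Spike-in probes have a fixed nominal
#' intensity scaled only by A (no biological noise), which makes the
#' normalization exactly identifiable.
#'
#' The truth table stores `true_meth_log2fc` on the scale the pipeline
#' measures: log2 of the SCI/sham percent-m6A ratio implied by the planted
#' odds effect. `true_expr_log2fc` is the planted expression effect.
#'
#' @param config A [sim_config()] list.
#' @return A list with data.frames `intensities`, `annotation`, `truth`, and
#'   a `design` (class `meriparray_design`).
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "meriparray_simconfig"))
  set.seed(config$seed)
  n_m <- config$n_mrna; n_l <- config$n_lncrna
  n_tx <- n_m + n_l
  tx_id <- c(sprintf("mRNA_%05d", seq_len(n_m)),
             sprintf("lnc_%05d", seq_len(n_l)))
  gene <- c(sprintf("GENE%05d", seq_len(n_m)),
            sprintf("LNC%05d", seq_len(n_l)))
  biotype <- rep(c("mRNA", "lncRNA"), c(n_m, n_l))

  # --- planted modes, split proportionally between biotypes
  mode <- rep("null", n_tx)
  free_m <- seq_len(n_m); free_l <- n_m + seq_len(n_l)
  for (md in names(config$planted)) {
    cnt <- config$planted[[md]]
    if (cnt == 0) next
    sh <- split_count(cnt, length(free_m), length(free_l))
    if (sh["mrna"] > length(free_m) || sh["lnc"] > length(free_l))
      stop("planted counts exceed available transcripts for a biotype")
    pick_m <- if (sh["mrna"] > 0) sample(free_m, sh["mrna"]) else integer()
    pick_l <- if (sh["lnc"] > 0) sample(free_l, sh["lnc"]) else integer()
    mode[c(pick_m, pick_l)] <- gsub("_", "-", md)
    free_m <- setdiff(free_m, pick_m); free_l <- setdiff(free_l, pick_l)
  }

  # --- baselines
  a <- config$baseline_meth_alpha; b <- config$baseline_meth_beta
  pi0 <- stats::rbeta(n_tx, a, b)
  meth_planted <- mode %in% c("hyper-up", "hypo-down", "hyper-only")
  if (any(meth_planted)) {
    # inverse-CDF draw from Beta truncated to (0, max_pi]
    u <- stats::runif(sum(meth_planted))
    pi0[meth_planted] <- stats::qbeta(
      u * stats::pbeta(config$meth_planted_max_pi, a, b), a, b)
  }
  E0 <- 2^stats::rnorm(n_tx, config$expr_mu_log2, config$expr_sd_log2)

  meth_delta <- ifelse(mode %in% c("hyper-up", "hyper-only"),
                       config$meth_effect_log2,
                       ifelse(mode == "hypo-down", -config$meth_effect_log2, 0))
  expr_delta <- ifelse(mode %in% c("hyper-up", "up-only"),
                       config$expr_effect_log2,
                       ifelse(mode == "hypo-down", -config$expr_effect_log2, 0))
  odds0 <- pi0 / (1 - pi0)
  odds1 <- odds0 * 2^meth_delta
  pi1 <- odds1 / (1 + odds1)
  E1 <- E0 * 2^expr_delta

  truth <- data.frame(transcript_id = tx_id, true_mode = mode,
                      true_meth_log2fc = log2(pi1 / pi0),
                      true_expr_log2fc = expr_delta,
                      stringsAsFactors = FALSE)

  # --- design and per-array-channel scale factors
  samples <- c(sprintf("sham_%d", seq_len(config$n_per_group)),
               sprintf("sci_%d", seq_len(config$n_per_group)))
  groups <- rep(c("sham", "sci"), each = config$n_per_group)
  design <- as_design(data.frame(sample_id = samples, group = groups,
                                 stringsAsFactors = FALSE))
  n_s <- length(samples)
  A <- matrix(2^stats::rnorm(n_s * 2, 0, config$array_scale_sd_log2),
              nrow = n_s, ncol = 2, dimnames = list(samples, c("IP", "Sup")))

  # --- raw intensities: transcript probes
  pi_mat <- outer(rep(1, n_s), pi0)
  pi_mat[groups == "sci", ] <- matrix(pi1, nrow = sum(groups == "sci"),
                                      ncol = n_tx, byrow = TRUE)
  E_mat <- outer(rep(1, n_s), E0)
  E_mat[groups == "sci", ] <- matrix(E1, nrow = sum(groups == "sci"),
                                     ncol = n_tx, byrow = TRUE)
  noise <- function() 2^stats::rnorm(n_s * n_tx, 0, config$noise_sd_log2)
  ip <- as.vector(A[, "IP"] * E_mat * pi_mat) * noise()
  sup <- as.vector(A[, "Sup"] * E_mat * (1 - pi_mat)) * noise()

  tx_rows <- data.frame(
    probe_id = rep(paste0("p_", tx_id), each = n_s),
    transcript_id = rep(tx_id, each = n_s),
    sample_id = rep(samples, times = n_tx),
    channel = "IP",
    intensity = as.vector(matrix(ip, nrow = n_s)),
    is_spike_in = FALSE, stringsAsFactors = FALSE)
  tx_rows2 <- tx_rows
  tx_rows2$channel <- "Sup"
  tx_rows2$intensity <- as.vector(matrix(sup, nrow = n_s))

  # --- spike-in probes: nominal level scaled only by the array factor
  nominal <- 2^config$spikein_log2
  sp_id <- sprintf("spike_%02d", seq_len(config$n_spikein))
  sp <- expand.grid(probe_id = sp_id, sample_id = samples,
                    channel = c("IP", "Sup"), stringsAsFactors = FALSE)
  sp$transcript_id <- sp$probe_id
  sp$intensity <- nominal * A[cbind(sp$sample_id, sp$channel)]
  sp$is_spike_in <- TRUE
  sp <- sp[, names(tx_rows)]

  intensities <- rbind(tx_rows, tx_rows2, sp)
  intensities <- validate_intensities(intensities, design)

  annotation <- simulate_annotation(tx_id, gene, biotype, config)
  list(intensities = intensities, annotation = annotation,
       truth = truth, design = design)
}

# Genomic layout: mRNAs on a 300-kb grid across 20 chromosomes (2-kb genes,
# alternating strand). "cis" lncRNAs sit 10 kb downstream of a random mRNA
# (inside the 100-kb window of exactly that mRNA); the others sit 145 kb
# downstream, out of range of every mRNA.
simulate_annotation <- function(tx_id, gene, biotype, config) {
  n_m <- config$n_mrna; n_l <- config$n_lncrna
  n_chr <- 20L
  i <- seq_len(n_m)
  m_chr <- paste0("chr", ((i - 1L) %% n_chr) + 1L)
  m_start <- ((i - 1L) %/% n_chr) * 300000L
  m_end <- m_start + 2000L
  m_strand <- ifelse(i %% 2L == 1L, "+", "-")

  l_chr <- character(n_l); l_start <- integer(n_l)
  l_strand <- character(n_l)
  if (n_l > 0) {
    n_cis <- as.integer(round(config$cis_fraction * n_l))
    is_cis <- rep(FALSE, n_l)
    if (n_cis > 0) is_cis[sample.int(n_l, n_cis)] <- TRUE
    host <- if (n_m > 0) sample.int(n_m, n_l, replace = TRUE) else
      stop("cannot place lncRNAs without mRNAs")
    off <- ifelse(is_cis, 10000L, 145000L)
    l_chr <- m_chr[host]
    l_start <- m_end[host] + off
    l_strand <- sample(c("+", "-"), n_l, replace = TRUE)
  }
  data.frame(
    transcript_id = tx_id, gene_symbol = gene, biotype = biotype,
    chrom = c(m_chr, l_chr),
    start = c(m_start, l_start),
    end = c(m_end, l_start + 1000L),
    strand = c(m_strand, l_strand), stringsAsFactors = FALSE)
}

#' Confusion matrix of called conjoint modes against planted truth
#'
#' Compares nine-quadrant mode calls with the generator's truth table. True
#' modes `hyper-only`, `up-only` and `null` are expected to be called
#' `none` (a conjoint mode requires both axes); `hyper-up` and `hypo-down`
#' are expected to be called as themselves.
#'
#' @param truth Truth data.frame from [simulate_experiment()].
#' @param calls Quadrant data.frame from [nine_quadrant()] (columns
#'   `transcript_id`, `mode`).
#' @return A list with the full `confusion` cross-tabulation and a `stats`
#'   data.frame (per conjoint mode: planted, called, TP, sensitivity, FDR).
#' @export
truth_confusion <- function(truth, calls) {
  if (!setequal(truth$transcript_id, calls$transcript_id))
    stop("truth and calls cover different transcripts")
  called <- calls$mode[match(truth$transcript_id, calls$transcript_id)]
  confusion <- table(true = truth$true_mode, called = called)
  modes <- c("hyper-up", "hypo-down", "hyper-down", "hypo-up")
  expected <- ifelse(truth$true_mode %in% c("hyper-up", "hypo-down"),
                     truth$true_mode, "none")
  stats_df <- do.call(rbind, lapply(modes, function(md) {
    planted <- sum(truth$true_mode == md)
    ncalled <- sum(called == md)
    tp <- sum(called == md & expected == md)
    data.frame(mode = md, planted = planted, called = ncalled, tp = tp,
               sensitivity = if (planted > 0) tp / planted else NA_real_,
               fdr = if (ncalled > 0) (ncalled - tp) / ncalled else NA_real_,
               stringsAsFactors = FALSE)
  }))
  list(confusion = confusion, stats = stats_df)
}
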