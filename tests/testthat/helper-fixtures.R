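# Shared fixtures and independent oracles.

tiny_design <- function(n = 3L) {
  as_design(data.frame(
    sample_id = c(sprintf("sham_%d", seq_len(n)), sprintf("sci_%d", seq_len(n))),
    group = rep(c("sham", "sci"), each = n), stringsAsFactors = FALSE))
}

# hand-built intensity table: `n_probe` transcript probes plus one spike-in,
# all channels present, spike-in at 2^10
tiny_intensities <- function(n_probe = 10L, design = tiny_design()) {
  probes <- c(sprintf("p%02d", seq_len(n_probe)), "spike_01")
  tx <- c(sprintf("t%02d", seq_len(n_probe)), "spike_01")
  grid <- expand.grid(probe_idx = seq_along(probes),
                      sample_id = design$sample_id,
                      channel = c("IP", "Sup"), stringsAsFactors = FALSE)
  data.frame(probe_id = probes[grid$probe_idx],
             transcript_id = tx[grid$probe_idx],
             sample_id = grid$sample_id, channel = grid$channel,
             intensity = ifelse(grid$probe_idx > n_probe, 1024,
                                100 + 7 * grid$probe_idx),
             is_spike_in = grid$probe_idx > n_probe,
             stringsAsFactors = FALSE)
}

# --- independent oracles -----------------------------------------------

# closed-form pooled-variance two-sample t-test (two-sided)
oracle_pooled_t_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  tstat <- (mean(y) - mean(x)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  2 * pt(abs(tstat), df = n1 + n2 - 2, lower.tail = FALSE)
}

# hypergeometric upper tail through the survival function (different code
# path than the pmf sum used by the package)
oracle_hyper_p <- function(k, N, K, n) {
  if (k <= 0) return(1)
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

# hand-enumerated nine-quadrant truth: sign in {-1, 0, 1} per axis plus a
# significance flag per axis; an axis counts only when significant AND the
# sign is non-zero (|log2fc| at/above threshold encodes the non-zero sign)
oracle_quadrant_mode <- function(ms, msig, es, esig) {
  meth <- if (msig && ms > 0) "hyper" else if (msig && ms < 0) "hypo" else "ns"
  expr <- if (esig && es > 0) "up" else if (esig && es < 0) "down" else "ns"
  if (meth != "ns" && expr != "ns") paste(meth, expr, sep = "-") else "none"
}

# brute-force lncRNA positional classification (independent restatement of
# the precedence rules, scalar logic over every coding gene)
oracle_classify <- function(lnc, mrnas, bidi_window = 1000L) {
  best <- "intergenic"
  rank <- c("exon-sense-overlapping" = 1, "intronic" = 2,
            "natural-antisense" = 3, "intronic-antisense" = 4,
            "bidirectional" = 5, "intergenic" = 6)
  for (i in seq_len(nrow(mrnas))) {
    m <- mrnas[i, ]
    if (m$chrom != lnc$chrom) next
    ov <- m$start < lnc$end && lnc$start < m$end
    inside <- m$start <= lnc$start && lnc$end <= m$end &&
      !(m$start == lnc$start && m$end == lnc$end)
    same <- m$strand == lnc$strand
    cls <- if (ov && same && !inside) "exon-sense-overlapping"
      else if (inside && same) "intronic"
      else if (ov && !same && !inside) "natural-antisense"
      else if (inside && !same) "intronic-antisense"
      else {
        tss_l <- if (lnc$strand == "+") lnc$start else lnc$end
        tss_m <- if (m$strand == "+") m$start else m$end
        if (!same && !ov && abs(tss_m - tss_l) <= bidi_window)
          "bidirectional" else "intergenic"
      }
    if (rank[cls] < rank[best]) best <- cls
  }
  best
}

# O(n^2) all-pairs cis-target oracle over full outer-product matrices
oracle_cis <- function(lncs, mrnas, window) {
  same <- outer(lncs$chrom, mrnas$chrom, "==")
  gap <- pmax(outer(lncs$start, mrnas$end, "-"),
              outer(-lncs$end, mrnas$start, "+"), 0)
  hit <- which(same & gap <= window, arr.ind = TRUE)
  res <- data.frame(lncrna_id = lncs$transcript_id[hit[, 1]],
                    mrna_id = mrnas$transcript_id[hit[, 2]],
                    distance_bp = as.integer(gap[hit]),
                    stringsAsFactors = FALSE)
  res[order(res$lncrna_id, res$mrna_id), , drop = FALSE]
}

# exhaustive k-core oracle on small graphs: for each vertex, enumerate every
# subset of its closed neighborhood, find the highest attainable minimum
# degree k, take the union of all subsets attaining it (the k-core), and
# score k * density of that union
oracle_mcode_weights <- function(adj) {
  n <- nrow(adj)
  vnames <- rownames(adj)
  w <- setNames(numeric(n), vnames)
  for (v in seq_len(n)) {
    nb <- sort(unique(c(v, which(adj[v, ] > 0))))
    if (length(nb) < 2) next
    sub <- adj[nb, nb, drop = FALSE]
    m <- length(nb)
    best_k <- 0L
    members <- NULL
    for (mask in seq_len(2^m - 1)) {
      idx <- which(bitwAnd(mask, 2^(seq_len(m) - 1)) > 0)
      if (length(idx) < 2) next
      degs <- rowSums(sub[idx, idx, drop = FALSE])
      k <- min(degs)
      if (k > best_k) { best_k <- k; members <- idx }
      else if (k == best_k && k > 0) members <- union(members, idx)
    }
    if (best_k == 0) next
    # union of all subsets attaining best_k is the best_k-core
    core <- sub[members, members, drop = FALSE]
    nc <- length(members)
    dens <- sum(core) / (nc * (nc - 1))
    w[v] <- best_k * dens
  }
  w
}

random_adj <- function(n, p = 0.4) {
  a <- matrix(0L, n, n, dimnames = list(paste0("v", seq_len(n)),
                                        paste0("v", seq_len(n))))
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if (runif(1) < p) a[i, j] <- a[j, i] <- 1L
  a
}

graph_from_adj <- function(adj) {
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
}
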