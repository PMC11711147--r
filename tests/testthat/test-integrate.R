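mk_layer <- function(tx, layer, log2fc, p) {
  data.frame(transcript_id = tx, biotype = "mRNA", layer = layer,
             mean_sham = NA_real_, mean_sci = NA_real_,
             fc = 2^log2fc, log2fc = log2fc, p_value = p,
             adj_p = p, status = "ns", stringsAsFactors = FALSE)
}

test_that("nine-quadrant assignment matches the enumerated truth table", {
  signs <- c(-1, 0, 1); sigs <- c(TRUE, FALSE)
  grid <- expand.grid(ms = signs, msig = sigs, es = signs, esig = sigs)
  tx <- sprintf("t%02d", seq_len(nrow(grid)))
  meth <- mk_layer(tx, "methylation", grid$ms * 1.5,
                   ifelse(grid$msig, 0.01, 0.50))
  expr <- mk_layer(tx, "expression", grid$es * 2.0,
                   ifelse(grid$esig, 0.02, 0.60))
  q <- nine_quadrant(meth, expr, run_config())
  expected <- mapply(oracle_quadrant_mode, grid$ms, grid$msig,
                     grid$es, grid$esig)
  expect_equal(q$mode[match(tx, q$transcript_id)], unname(expected))

  # center cell: no change on either axis
  expect_equal(q$mode[q$meth_log2fc == 0 & q$expr_log2fc == 0][1], "none")
  # concordant example at the documented thresholds
  one <- nine_quadrant(mk_layer("x", "methylation", 1.5, 0.01),
                       mk_layer("x", "expression", 2.0, 0.02))
  expect_equal(one$mode, "hyper-up")
  # boundary inclusive: |log2fc| exactly 1 with small p qualifies
  bdry <- nine_quadrant(mk_layer("x", "methylation", 1, 0.01),
                        mk_layer("x", "expression", -1, 0.01))
  expect_equal(bdry$mode, "hyper-down")
})

test_that("quadrant cells partition the transcripts and Venn counts agree", {
  set.seed(41)
  tx <- sprintf("t%03d", 1:200)
  meth <- mk_layer(tx, "methylation", rnorm(200, 0, 1.2), runif(200))
  expr <- mk_layer(tx, "expression", rnorm(200, 0, 1.2), runif(200))
  q <- nine_quadrant(meth, expr)
  expect_equal(sum(table(q$quadrant)), 200)
  vc <- venn_counts(q)$mRNA
  expect_equal(vc$both, vc$`hyper-up` + vc$`hypo-down` +
                 vc$`hyper-down` + vc$`hypo-up`)
  expect_gte(vc$meth_differential, vc$both)
  expect_gte(vc$expr_differential, vc$both)

  expect_error(nine_quadrant(meth, expr[-1, ]), "one layer only")
})

ann_row <- function(id, bt, chrom, start, end, strand) {
  data.frame(transcript_id = id, gene_symbol = toupper(id), biotype = bt,
             chrom = chrom, start = start, end = end, strand = strand,
             stringsAsFactors = FALSE)
}

test_that("lncRNA positional classes follow the precedence rules", {
  mrnas <- rbind(ann_row("m1", "mRNA", "chr1", 1000, 5000, "+"),
                 ann_row("m2", "mRNA", "chr2", 1000, 5000, "-"))
  # no coding gene on its chromosome
  expect_equal(classify_lncrna(ann_row("l1", "lncRNA", "chr9", 0, 100, "+"),
                               mrnas), "intergenic")
  # identical span and strand: exonic sense overlap wins
  expect_equal(classify_lncrna(ann_row("l2", "lncRNA", "chr1", 1000, 5000, "+"),
                               mrnas), "exon-sense-overlapping")
  # strict containment, same strand
  expect_equal(classify_lncrna(ann_row("l3", "lncRNA", "chr1", 2000, 3000, "+"),
                               mrnas), "intronic")
  # overlap, opposite strand
  expect_equal(classify_lncrna(ann_row("l4", "lncRNA", "chr1", 4000, 6000, "-"),
                               mrnas), "natural-antisense")
  # containment, opposite strand
  expect_equal(classify_lncrna(ann_row("l5", "lncRNA", "chr1", 2000, 3000, "-"),
                               mrnas), "intronic-antisense")
  # divergent promoters within 1 kb, no overlap
  expect_equal(classify_lncrna(ann_row("l6", "lncRNA", "chr1", 200, 900, "-"),
                               mrnas), "bidirectional")
  # nearby but out of promoter range
  expect_equal(classify_lncrna(ann_row("l7", "lncRNA", "chr1", 8000, 9000, "-"),
                               mrnas), "intergenic")
})

test_that("random lncRNA placements match the brute-force classifier", {
  set.seed(53)
  mrnas <- do.call(rbind, lapply(1:40, function(i)
    ann_row(paste0("m", i), "mRNA", sample(paste0("chr", 1:4), 1),
            s <- sample.int(50000, 1), s + sample.int(8000, 1),
            sample(c("+", "-"), 1))))
  for (i in 1:500) {
    s <- sample.int(60000, 1)
    lnc <- ann_row(paste0("l", i), "lncRNA", sample(paste0("chr", 1:5), 1),
                   s, s + sample.int(6000, 1), sample(c("+", "-"), 1))
    expect_equal(classify_lncrna(lnc, mrnas), oracle_classify(lnc, mrnas),
                 info = paste("case", i))
  }
})

test_that("cis-target pairing respects the window and chromosome", {
  lnc <- ann_row("l1", "lncRNA", "chr1", 10000, 11000, "+")
  # overlapping mRNA: distance zero
  m_ov <- ann_row("m1", "mRNA", "chr1", 10500, 12000, "-")
  p <- find_cis_targets(lnc, m_ov, 100000L)
  expect_equal(p$distance_bp, 0L)
  # gap exactly the window: included (boundary inclusive)
  m_edge <- ann_row("m2", "mRNA", "chr1", 111000, 115000, "+")
  p <- find_cis_targets(lnc, m_edge, 100000L)
  expect_equal(p$distance_bp, 100000L)
  # one base further: excluded
  m_out <- ann_row("m3", "mRNA", "chr1", 111001, 115000, "+")
  expect_equal(nrow(find_cis_targets(lnc, m_out, 100000L)), 0L)
  # same coordinates on a different chromosome: excluded
  m_chr <- ann_row("m4", "mRNA", "chr2", 10500, 12000, "+")
  expect_equal(nrow(find_cis_targets(lnc, m_chr, 100000L)), 0L)
})

test_that("cis pairs equal the all-pairs oracle and are symmetric", {
  set.seed(61)
  mk <- function(prefix, n, bt) do.call(rbind, lapply(seq_len(n), function(i)
    ann_row(paste0(prefix, i), bt, sample(paste0("chr", 1:3), 1),
            s <- sample.int(500000, 1), s + sample.int(20000, 1),
            sample(c("+", "-"), 1))))
  lncs <- mk("l", 60, "lncRNA"); mrnas <- mk("m", 120, "mRNA")
  got <- find_cis_targets(lncs, mrnas, 100000L)
  want <- oracle_cis(lncs, mrnas, 100000L)
  rownames(got) <- rownames(want) <- NULL
  expect_equal(got, want)
  # distance is symmetric in which list is the query
  swapped <- find_cis_targets(mrnas, lncs, 100000L)
  key1 <- paste(got$lncrna_id, got$mrna_id, got$distance_bp)
  key2 <- paste(swapped$mrna_id, swapped$lncrna_id, swapped$distance_bp)
  expect_setequal(key1, key2)
})
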