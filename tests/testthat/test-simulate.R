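small_cfg <- function(...) {
  sim_config(n_mrna = 120L, n_lncrna = 30L,
             planted = c(hyper_up = 12L, hypo_down = 12L,
                         hyper_only = 6L, up_only = 6L), ...)
}

test_that("the generator is deterministic given a seed", {
  a <- simulate_experiment(small_cfg(seed = 7L))
  b <- simulate_experiment(small_cfg(seed = 7L))
  expect_identical(a, b)
  c <- simulate_experiment(small_cfg(seed = 8L))
  expect_false(identical(a$intensities$intensity, c$intensities$intensity))
})

test_that("noise-free intensities satisfy the generative arithmetic", {
  sim <- simulate_experiment(small_cfg(
    noise_sd_log2 = 0, array_scale_sd_log2 = 0, expr_sd_log2 = 0,
    expr_mu_log2 = 10, seed = 2L))
  ints <- sim$intensities
  tx <- ints[!ints$is_spike_in, ]
  # IP + Sup = E exactly: pi*E + (1-pi)*E, with E = 2^10 in sham and
  # 2^(10 + planted expression effect) in SCI
  sums <- tapply(tx$intensity, paste(tx$transcript_id, tx$sample_id), sum)
  tx_of <- sub(" .*", "", names(sums))
  is_sci <- grepl("sci", names(sums))
  eff <- sim$truth$true_expr_log2fc[match(tx_of, sim$truth$transcript_id)]
  expected <- 1024 * 2^(eff * is_sci)
  expect_true(all(abs(sums - expected) < 1e-9))
  expect_true(all(ints$intensity > 0))
})

test_that("spike-ins carry the array factor but no biological noise", {
  sim <- simulate_experiment(small_cfg(array_scale_sd_log2 = 0.6, seed = 4L))
  sp <- sim$intensities[sim$intensities$is_spike_in, ]
  spread <- tapply(sp$intensity, paste(sp$sample_id, sp$channel),
                   function(x) diff(range(x)))
  expect_true(all(spread == 0))
  # the array factor itself varies across arrays
  level <- tapply(sp$intensity, paste(sp$sample_id, sp$channel), mean)
  expect_gt(diff(range(level)), 0)
})

test_that("a planted odds effect maps to the derived percent-m6A change", {
  # with zero noise, sham percent = 100*pi and an odds effect of 2^1 gives
  # sci percent = 100 * 2*pi/(1+pi): check the quantified values against
  # that closed form, and pi = 0.5 => 66.666...%
  sim <- simulate_experiment(small_cfg(
    noise_sd_log2 = 0, array_scale_sd_log2 = 0, meth_effect_log2 = 1,
    seed = 9L))
  norm <- normalize_spikein(sim$intensities, epsilon = 1e-12)
  quant <- compute_quant(norm)
  hyper <- sim$truth$transcript_id[sim$truth$true_mode %in%
                                     c("hyper-up", "hyper-only")]
  for (t in hyper[1:5]) {
    q <- quant[quant$transcript_id == t, ]
    p_sham <- q$m6a_percent[grepl("sham", q$sample_id)][1] / 100
    p_sci <- q$m6a_percent[grepl("sci", q$sample_id)][1]
    expect_equal(p_sci, 100 * 2 * p_sham / (1 + p_sham), tolerance = 1e-9)
  }
  expect_equal(100 * 2 * 0.5 / (1 + 0.5), 66.66667, tolerance = 1e-5)
})

test_that("planted counts exceeding the transcript total are rejected", {
  expect_error(sim_config(n_mrna = 5L, n_lncrna = 0L,
                          planted = c(hyper_up = 10L)),
               "exceed")
})

test_that("the configured fraction of lncRNAs has an mRNA in the cis window", {
  cfg <- small_cfg(cis_fraction = 0.4, seed = 6L)
  sim <- simulate_experiment(cfg)
  ann <- sim$annotation
  cis <- find_cis_targets(ann[ann$biotype == "lncRNA", ],
                          ann[ann$biotype == "mRNA", ], window = 100000L)
  expect_equal(length(unique(cis$lncrna_id)), round(0.4 * 30))
})

test_that("truth_confusion scores perfect and degenerate call sets", {
  truth <- data.frame(
    transcript_id = paste0("t", 1:10),
    true_mode = c(rep("hyper-up", 3), rep("hypo-down", 3), rep("null", 4)),
    stringsAsFactors = FALSE)
  perfect <- data.frame(
    transcript_id = truth$transcript_id,
    mode = ifelse(truth$true_mode == "null", "none", truth$true_mode),
    stringsAsFactors = FALSE)
  tc <- truth_confusion(truth, perfect)
  st <- tc$stats
  expect_equal(st$sensitivity[st$mode == "hyper-up"], 1)
  expect_equal(st$fdr[st$mode == "hyper-up"], 0)
  expect_equal(st$sensitivity[st$mode == "hypo-down"], 1)

  allnone <- perfect
  allnone$mode <- "none"
  st0 <- truth_confusion(truth, allnone)$stats
  expect_equal(st0$sensitivity[st0$mode == "hyper-up"], 0)

  expect_error(truth_confusion(truth, perfect[-1, ]), "different transcripts")
})

test_that("null false calls track the test level over simulated replicates", {
  # randomized calling on nulls: screening nulls at p < 0.05 should flag
  # about 5%; pooled over a few seeds the fraction stays in the binomial
  # 99% band
  hits <- 0L; total <- 0L
  for (seed in 1:3) {
    sim <- simulate_experiment(sim_config(
      n_mrna = 400L, n_lncrna = 0L, planted = c(), seed = seed))
    out <- run_pipeline(sim$intensities, sim$annotation, sim$design,
                        withr::local_tempdir(), quiet = TRUE)
    d <- out$differential[out$differential$layer == "expression", ]
    hits <- hits + sum(d$p_value < 0.05)
    total <- total + nrow(d)
  }
  band <- qbinom(c(0.005, 0.995), total, 0.05) / total
  expect_gte(hits / total, band[1])
  expect_lte(hits / total, band[2])
})
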