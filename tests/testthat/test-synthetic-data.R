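test_that("generation is deterministic given the seed", {
  cfg <- sim_config(seed = 11)
  a <- gen_expression(cfg)
  b <- gen_expression(cfg)
  expect_identical(a$expression$values, b$expression$values)
  expect_identical(a$truth, b$truth)
  ra <- gen_regions(cfg, a$truth)
  rb <- gen_regions(cfg, b$truth)
  expect_identical(ra$sequences, rb$sequences)
  expect_identical(ra$embedded, rb$embedded)
  tc <- gen_titration(80, seq(0, 80, 8), noise_sd = 0.01, seed = 3)
  expect_identical(tc, gen_titration(80, seq(0, 80, 8), noise_sd = 0.01,
                                     seed = 3))
})

test_that("noise-free generation equals the analytic expectations", {
  cfg <- sim_config(
    n_genes = c(aft = 3, cth2 = 2, ace1 = 2, mac1 = 2, yap5 = 1,
                null = 2),
    effect_ranges = list(aft = c(8, 8), cth2 = c(2, 5), ace1 = c(4, 19),
                         mac1 = c(5, 22), yap5 = c(1.2, 2)),
    noise_cv = 0, seed = 5
  )
  sim <- gen_expression(cfg)
  v <- sim$expression$values
  sheet <- sim$expression$samples
  tr <- sim$truth
  pick <- function(genotype, condition) {
    v[, sheet$sample[sheet$genotype == genotype &
                       sheet$condition == condition], drop = FALSE]
  }
  # fixed-effect class: every treated replicate exactly 8x baseline
  aft <- tr$gene[tr$class == "aft"]
  expect_identical(unname(pick("wt", "cu_bpq")[aft, ]),
                   unname(matrix(tr$baseline[tr$class == "aft"] * 8,
                                 ncol = 3, nrow = length(aft))))
  # all classes: expectations hold exactly across conditions
  expect_equal(unname(pick("wt", "untreated")[, 1]), tr$baseline)
  expect_equal(unname(pick("wt", "cu")[, 1]), tr$baseline * tr$effect_cu)
  expect_equal(unname(pick("fra2", "cu_bpq")[, 1]),
               tr$baseline * tr$effect_cu_bpq)
  expect_equal(unname(pick("fra2", "untreated")[, 1]),
               tr$baseline *
                 (1 + tr$fra2_fraction * (tr$effect_cu_bpq - 1)))
})

test_that("config invariants are enforced", {
  expect_error(sim_config(n_replicates = 0), "replicates")
  expect_error(sim_config(n_genes = c(aft = 0, null = 0)), "class")
  expect_error(sim_config(noise_cv = -0.1), "noise_cv")
  expect_error(sim_config(fra2_fraction_range = c(-0.2, 1)), "fra2")
  expect_error(sim_config(effect_ranges = list(aft = c(5, 2)),
                          n_genes = c(aft = 3)), "effect_ranges")
})

test_that("noisy fold-change estimates recover the planted effects", {
  cfg <- sim_config(n_genes = c(aft = 600, cth2 = 400),
                    noise_cv = 0.1, seed = 17)
  sim <- gen_expression(cfg)
  fc <- fold_changes(sim$expression, c("wt", "untreated"),
                     c("wt", "cu_bpq"))
  # compare on the log scale, where the shared replicate-mean noise of
  # numerator and denominator cancels in expectation
  err <- log(fc$mean_fc[match(sim$truth$gene, fc$gene)]) -
    log(sim$truth$effect_cu_bpq)
  se <- sd(err) / sqrt(length(err))
  expect_lt(abs(mean(err)), 3 * se)
})

test_that("planted motifs sit at the recorded positions and are unique", {
  cfg <- sim_config(n_genes = c(aft = 15, cth2 = 10, null = 5),
                    seed = 23)
  sim <- gen_expression(cfg)
  reg <- gen_regions(cfg, sim$truth)
  emb <- reg$embedded
  expect_gt(nrow(emb), 0)
  for (i in seq_len(nrow(emb))) {
    rec <- reg$sequences[reg$sequences$gene == emb$gene[i] &
                           reg$sequences$region == emb$region[i], ]
    w <- emb$word[i]
    stored <- if (emb$strand[i] == "-") oracle_revcomp(w) else w
    expect_identical(
      substr(rec$seq, emb$start[i], emb$start[i] + nchar(w) - 1),
      stored)
    # planted positions lie within region bounds
    expect_gte(emb$start[i], 1)
    expect_lte(emb$start[i] + nchar(w) - 1, nchar(rec$seq))
  }
  # planted sites are the unique hits: scanner finds all of them, and in
  # embedded sequences nothing outside the planted window
  are_hits <- scan_motifs(reg$sequences, consensus_are(), dedupe = "all")
  for (g in emb$gene[emb$region == "utr3"]) {
    h <- are_hits[are_hits$gene == g, ]
    s0 <- emb$start[emb$gene == g & emb$region == "utr3"]
    expect_true(any(h$start == s0 & h$word == "TTATTTATT"))
    expect_true(all(h$start >= s0 & h$start + nchar(h$word) - 1 <= s0 + 8))
  }
})

test_that("without embedding, hit counts match the analytic background", {
  cfg <- sim_config(n_genes = c(null = 300), embed_rate = 0, seed = 29)
  sim <- gen_expression(cfg)
  reg <- gen_regions(cfg, sim$truth)
  expect_identical(nrow(reg$embedded), 0L)
  hits_aft <- scan_motifs(reg$sequences, consensus_aft1(), dedupe = "all")
  hits_are <- scan_motifs(reg$sequences, consensus_are(), dedupe = "all")
  exp_aft <- 300 * 2 * 8 * (600 - 8 + 1) / 4^8
  exp_are <- 300 * ((200 - 9 + 1) / 4^9 + 2 * (200 - 8 + 1) / 4^8)
  expect_lt(abs(nrow(hits_aft) - exp_aft), 4 * sqrt(exp_aft) + 1)
  expect_lt(abs(nrow(hits_are) - exp_are), 4 * sqrt(exp_are) + 1)
})

test_that("minus-strand promoter sites need double-strand scanning", {
  cfg <- sim_config(n_genes = c(aft = 30, null = 2), seed = 31)
  sim <- gen_expression(cfg)
  reg <- gen_regions(cfg, sim$truth)
  minus <- reg$embedded[reg$embedded$strand == "-", ]
  expect_gt(nrow(minus), 0)
  both <- scan_motifs(reg$sequences, consensus_aft1(), dedupe = "all")
  sense <- scan_motifs(
    reg$sequences,
    degenerate_consensus("PyPuCACCCPu", name = "Aft1",
                         region_target = "promoter",
                         strand_policy = "sense"),
    dedupe = "all")
  for (i in seq_len(nrow(minus))) {
    found_both <- any(both$gene == minus$gene[i] &
                        both$strand == "-" &
                        both$start == minus$start[i])
    found_sense <- any(sense$gene == minus$gene[i] &
                         sense$start == minus$start[i])
    expect_true(found_both)
    expect_false(found_sense)
  }
})

test_that("titration generator honours the tight-binding mass balance", {
  tight <- gen_titration(80, c(20, 40, 120), epsilon = 0.01)
  expect_equal(tight$absorbance, c(0.20, 0.40, 0.40)) # plateau at L/2
  # finite affinity stays strictly below the tight limit before
  # saturation
  finite <- gen_titration(80, c(20, 40, 120), beta2 = 1e11,
                          epsilon = 0.01)
  expect_true(all(finite$absorbance < tight$absorbance))
  expect_error(gen_titration(80, c(-5, 10)), "negative")
  expect_error(gen_titration(80, c(10, 10)), "increasing")
})
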