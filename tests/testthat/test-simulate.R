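test_that("generation is deterministic under a fixed seed", {
  cfg <- sim_config(n_genes = 10L, seed = 99L)
  g1 <- generate_annotation(cfg)
  g2 <- generate_annotation(cfg)
  expect_equal(as.data.frame(g1$annotation$exons),
               as.data.frame(g2$annotation$exons))
  expect_equal(as.character(g1$sequences), as.character(g2$sequences))
  t1 <- generate_expression(g1$annotation, cfg, 3L)
  t2 <- generate_expression(g2$annotation, cfg, 3L)
  expect_equal(t1$cpm, t2$cpm)
  r1 <- simulate_long_reads(t1$cpm[, 1L], g1$annotation,
                            protocol_profile("dRNA-like"), 500L, 7L)
  r2 <- simulate_long_reads(t2$cpm[, 1L], g2$annotation,
                            protocol_profile("dRNA-like"), 500L, 7L)
  expect_equal(r1, r2)
})

test_that("subset-isoform genes contain a junction containment pair", {
  cfg <- sim_config(n_genes = 30L, subset_isoform_fraction = 1,
                    isoform_probs = c(0, 1), seed = 21L)
  gen <- generate_annotation(cfg)
  ann <- gen$annotation
  expect_gt(length(gen$subset_genes), 0L)
  for (g in gen$subset_genes) {
    chains <- ann$transcripts[ann$transcripts$gene_id == g, chain]
    chains <- chains[order(nchar(chains), decreasing = TRUE)]
    expect_length(chains, 2L)
    expect_true(grepl(chains[2L], chains[1L], fixed = TRUE))
    expect_lt(nchar(chains[2L]), nchar(chains[1L]))
  }
})

test_that("ground-truth expression is normalised and honest about majors", {
  cfg <- sim_config(n_genes = 25L, seed = 4L)
  gen <- generate_annotation(cfg)
  tr <- generate_expression(gen$annotation, cfg, 4L)
  expect_equal(unname(colSums(tr$cpm)), rep(1e6, 4L), tolerance = 1e-9)
  expect_equal(sum(tr$base_cpm), 1e6, tolerance = 1e-9)
  # major = argmax of noise-free CPM within gene
  tx <- gen$annotation$transcripts
  for (i in seq_len(nrow(tr$major))) {
    g <- tr$major$gene_id[i]
    ids <- tx[tx$gene_id == g, transcript_id]
    expect_equal(tr$major$major_tx[i],
                 ids[which.max(tr$base_cpm[ids])])
  }
  # degenerate noise: replicates identical
  cfg0 <- sim_config(n_genes = 10L, replicate_sdlog = 0, seed = 4L)
  gen0 <- generate_annotation(cfg0)
  tr0 <- generate_expression(gen0$annotation, cfg0, 2L)
  expect_equal(tr0$cpm[, 1L], tr0$cpm[, 2L])
})

test_that("long-read truncation behaviour matches the protocol profile", {
  cfg <- sim_config(n_genes = 15L, seed = 8L)
  gen <- generate_annotation(cfg)
  tr <- generate_expression(gen$annotation, cfg, 1L)
  lens <- setNames(gen$annotation$transcripts$length,
                   gen$annotation$transcripts$transcript_id)
  full <- protocol_profile("dRNA-like"); full$p_truncation <- 0
  rd <- simulate_long_reads(tr$cpm[, 1L], gen$annotation, full, 400L, 5L)
  expect_true(all(rd$start == 0L))
  expect_equal(rd$end, unname(lens[rd$transcript_id]))
  trunc <- protocol_profile("dRNA-like"); trunc$p_truncation <- 1
  rt <- simulate_long_reads(tr$cpm[, 1L], gen$annotation, trunc, 400L, 5L)
  # 3'-anchored: every end at the transcript end, starts inside
  expect_equal(rt$end, unname(lens[rt$transcript_id]))
  expect_true(any(rt$start > 0L))
  expect_true(all(rt$start >= 0L & rt$start < rt$end))
  expect_error(simulate_long_reads(tr$cpm[, 1L], gen$annotation, full,
                                   0L, 5L), "positive")
})

test_that("read counts per transcript stay inside the multinomial envelope", {
  cfg <- sim_config(n_genes = 20L, seed = 13L)
  gen <- generate_annotation(cfg)
  tr <- generate_expression(gen$annotation, cfg, 1L)
  prof <- protocol_profile("dRNA-like")
  n <- 20000L
  rd <- simulate_long_reads(tr$cpm[, 1L], gen$annotation, prof, n, 31L)
  p <- tr$cpm[, 1L] / sum(tr$cpm[, 1L])
  obs <- table(factor(rd$transcript_id, levels = names(p)))
  keep <- p * n >= 5
  expect_gt(suppressWarnings(
    chisq.test(as.integer(obs[keep]), p = p[keep] / sum(p[keep]))$p.value),
    0.001)
})

test_that("short reads respect fragment-length bounds and source truth", {
  cfg <- sim_config(n_genes = 15L, seed = 17L)
  gen <- generate_annotation(cfg)
  tr <- generate_expression(gen$annotation, cfg, 1L)
  rd <- simulate_short_reads(tr$cpm[, 1L], gen$annotation, 150L, 3000L, 9L)
  expect_true(all(rd$end - rd$start == 150L))
  lens <- setNames(gen$annotation$transcripts$length,
                   gen$annotation$transcripts$transcript_id)
  expect_true(all(rd$end <= lens[rd$transcript_id]))
  expect_true(all(rd$start >= 0L))
})

test_that("spike-in generation matches the design and the binomial CI", {
  mix <- data.frame(transcript_id = c("S1", "S2"),
                    concentration = c(0.5, 0.5))
  lens <- c(S1 = 1000L, S2 = 1000L)
  sp <- generate_spikein(mix, lens, 0.01, 1e6, 3L)
  n1 <- sum(sp$reads$transcript_id == "S1")
  n2 <- sum(sp$reads$transcript_id == "S2")
  expect_equal(sp$sheet$expected_reads, c(5000, 5000))
  # 99% binomial envelope around 5,000 of 1e6 at p = 0.005
  ci <- qbinom(c(0.005, 0.995), 1e6, 0.005)
  expect_true(n1 >= ci[1L] && n1 <= ci[2L])
  expect_true(n2 >= ci[1L] && n2 <= ci[2L])
  # zero fraction: no spike reads
  sp0 <- generate_spikein(mix, lens, 0, 1e6, 3L)
  expect_equal(nrow(sp0$reads), 0L)
  expect_error(generate_spikein(
    data.frame(transcript_id = "S1", concentration = 0.7), lens, 0.1,
    1e4, 1L), "sum to 1")
})

test_that("every generated read is consistent with its source transcript", {
  cfg <- sim_config(n_genes = 12L, seed = 23L)
  gen <- generate_annotation(cfg)
  tr <- generate_expression(gen$annotation, cfg, 1L)
  lens <- setNames(gen$annotation$transcripts$length,
                   gen$annotation$transcripts$transcript_id)
  for (prot in c("dRNA-like", "dcDNA-like", "PCR-cDNA-like", "IsoSeq-like")) {
    rd <- simulate_long_reads(tr$cpm[, 1L], gen$annotation,
                              protocol_profile(prot), 1000L, 2L)
    expect_true(all(rd$start >= 0L))
    expect_true(all(rd$end <= lens[rd$transcript_id]))
    expect_true(all(rd$end > rd$start))
  }
})
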