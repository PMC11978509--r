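# Gene with four isoforms on the plus strand used across event tests:
#   FULL : E1 [0,100)  E2 [200,300)  E3 [400,500)
#   SKIP : E1, E3 (skips E2)
#   INT  : E2, E3 (first exon = FULL's internal E2)
#   ALT5 : E1 with a shifted donor, E2, E3
events_annotation <- function(strand = "+") {
  tx_annotation(data.frame(
    transcript_id = rep(c("FULL", "SKIP", "INT", "ALT5"),
                        c(3L, 2L, 2L, 3L)),
    gene_id = "G1", chrom = "c", strand = strand,
    start = c(0L, 200L, 400L,  0L, 400L,  200L, 400L,  0L, 200L, 400L),
    end = c(100L, 300L, 500L,  100L, 500L,  300L, 500L,  80L, 300L, 500L)))
}

test_that("identical transcripts yield an empty event set", {
  ann <- events_annotation()
  for (t in c("FULL", "SKIP", "INT", "ALT5"))
    expect_true(all(compare_transcripts(ann, t, t) == 0L))
  gen <- generate_annotation(sim_config(n_genes = 10L, seed = 12L))
  for (t in gen$annotation$transcripts$transcript_id)
    expect_true(all(compare_transcripts(gen$annotation, t, t) == 0L))
})

test_that("exon skipping is detected with matched intron boundaries", {
  ann <- events_annotation()
  ev <- compare_transcripts(ann, "SKIP", "FULL")
  expect_equal(unname(ev["exon_skipping"]), 1L)
  expect_equal(unname(ev["internal_first_exon"]), 0L)
  # reciprocal: FULL retains no intron and skips nothing of SKIP
  ev2 <- compare_transcripts(ann, "FULL", "SKIP")
  expect_equal(unname(ev2["exon_skipping"]), 0L)
})

test_that("internal first exon and its reciprocal exclusion", {
  ann <- events_annotation()
  ev <- compare_transcripts(ann, "INT", "FULL")
  expect_equal(unname(ev["internal_first_exon"]), 1L)
  expect_equal(unname(ev["alternative_first_exon"]), 0L)
  # reciprocal comparison must not call the same pair alternative-first
  ev2 <- compare_transcripts(ann, "FULL", "INT")
  expect_equal(unname(ev2["alternative_first_exon"]), 0L)
  # minus strand mirrors: the genomic-last exon becomes the first exon
  annm <- events_annotation("-")
  evm <- compare_transcripts(annm, "INT", "FULL")
  expect_equal(unname(evm["internal_last_exon"]), 1L)
})

test_that("alternative 5'/3' splice sites are strand-aware", {
  ann <- events_annotation()
  ev <- compare_transcripts(ann, "ALT5", "FULL")
  # donor of junction 1 shifted (80 vs 100), acceptor shared -> alt 5' on +
  expect_equal(unname(ev["alt_5prime_splice"]), 1L)
  expect_equal(unname(ev["alt_3prime_splice"]), 0L)
  annm <- events_annotation("-")
  evm <- compare_transcripts(annm, "ALT5", "FULL")
  expect_equal(unname(evm["alt_3prime_splice"]), 1L)
  expect_equal(unname(evm["alt_5prime_splice"]), 0L)
})

test_that("intron retention spans a subject junction plus flanks", {
  ann <- tx_annotation(data.frame(
    transcript_id = c("SPLICED", "SPLICED", "RETAINED"),
    gene_id = "G", chrom = "c", strand = "+",
    start = c(0L, 200L, 0L), end = c(100L, 300L, 300L)))
  ev <- compare_transcripts(ann, "RETAINED", "SPLICED")
  expect_equal(unname(ev["intron_retention"]), 1L)
  ev2 <- compare_transcripts(ann, "SPLICED", "RETAINED")
  expect_equal(unname(ev2["intron_retention"]), 0L)
})

test_that("different genes are refused", {
  ann <- tx_annotation(data.frame(
    transcript_id = c("A", "B"), gene_id = c("GA", "GB"), chrom = "c",
    strand = "+", start = c(0L, 1000L), end = c(100L, 1100L)))
  expect_error(compare_transcripts(ann, "A", "B"), "different genes")
})

test_that("background distribution is degenerate for 2-isoform genes", {
  ann <- tx_annotation(data.frame(
    transcript_id = c("T1", "T1", "T2"), gene_id = "G", chrom = "c",
    strand = "+", start = c(0L, 200L, 0L), end = c(100L, 300L, 300L)))
  tg <- data.frame(gene_id = "G", target = "T1")
  bg <- background_event_distribution(ann, tg, n_rep = 5L, seed = 1L)
  expect_true(all(bg$sd == 0))
  expect_equal(bg[bg$event == "intron_retention", ]$mean, 1)
  # determinism
  bg2 <- background_event_distribution(ann, tg, n_rep = 5L, seed = 1L)
  expect_equal(bg, bg2)
  # single-isoform genes are excluded and counted
  ann2 <- events_annotation()
  tg2 <- rbind(tg <- data.frame(gene_id = "G1", target = "FULL"))
  bg3 <- background_event_distribution(ann2, tg2, n_rep = 3L, seed = 2L)
  expect_equal(attr(bg3, "n_excluded"), 0L)
})

test_that("background mean approaches the exhaustive average over draws", {
  ann <- events_annotation()
  tg <- data.frame(gene_id = "G1", target = "FULL")
  # non-target isoforms: SKIP, INT, ALT5; exhaustive mean for exon_skipping
  evs <- vapply(c("SKIP", "INT", "ALT5"), function(q)
    compare_transcripts(ann, q, "FULL")["exon_skipping"] > 0L, logical(1L))
  exact <- mean(evs)
  bg <- background_event_distribution(ann, tg, n_rep = 2000L, seed = 3L)
  # binomial s.e. at n_rep = 2000 is ~0.011; allow ~3 s.e.
  expect_lt(abs(bg[bg$event == "exon_skipping", ]$mean - exact), 0.035)
})

test_that("enrichment test matches the two-proportion formula with Bonferroni", {
  r <- event_enrichment_test(0.4, 200, 0.25, 400, n_events = 8L)
  z_expect <- (0.4 - 0.25) /
    sqrt(0.4 * 0.6 / 200 + 0.25 * 0.75 / 400)
  expect_equal(r$z, z_expect, tolerance = 1e-12)
  expect_equal(r$p_adjusted, min(1, r$p * 8))
  same <- event_enrichment_test(0.3, 100, 0.3, 100)
  expect_equal(same$z, 0)
  expect_equal(same$p_adjusted, 1)
})
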