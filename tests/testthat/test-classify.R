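test_that("full-splice-match, partial and unassigned labels are assigned", {
  ann <- toy_annotation()
  # T1 spans 0..300 in transcript space (three 100-bp exons)
  reads <- data.frame(
    read_id = c("full", "two_of_two", "one_junction", "contained",
                "exonic"),
    transcript_id = c("T1", "T1", "T1", "T1", "T1"),
    start = c(0L, 0L, 0L, 50L, 110L),
    end = c(300L, 300L, 150L, 250L, 180L))
  cl <- classify_reads(reads, ann)
  lab <- setNames(cl$label, cl$read_id)
  expect_equal(lab[["full"]], "full_splice_match")
  expect_equal(lab[["two_of_two"]], "full_splice_match")
  expect_equal(lab[["one_junction"]], "partial")      # first of T1's 2 junctions
  expect_equal(lab[["contained"]], "full_splice_match")
  expect_equal(lab[["exonic"]], "partial")            # junction-free in exon 2
  # read with the skip junction matches T2 exactly
  cl2 <- classify_reads(data.frame(read_id = "skip", transcript_id = "T2",
                                   start = 0L, end = 200L), ann)
  expect_equal(cl2$label, "full_splice_match")
  expect_equal(cl2$compatible[[1L]], "T2")
})

test_that("labels imply the right compatibility invariants", {
  cfg <- sim_config(n_genes = 25L, seed = 6L)
  gen <- generate_annotation(cfg)
  tr <- generate_expression(gen$annotation, cfg, 1L)
  rd <- simulate_long_reads(tr$cpm[, 1L], gen$annotation,
                            protocol_profile("dRNA-like"), 3000L, 11L)
  cl <- classify_reads(rd, gen$annotation)
  expect_equal(nrow(cl), nrow(rd))
  expect_true(all(cl$n_compatible[cl$label == "full_splice_match"] >= 1L))
  expect_true(all(cl$n_compatible[cl$label == "partial"] >= 1L))
  expect_true(all(cl$n_compatible[cl$label == "unassigned"] == 0L))
  # junction count equals token count in the chain key
  ntok <- ifelse(cl$chain == "", 0L,
                 lengths(strsplit(gsub("^\\||\\|$", "", cl$chain),
                                  "|", fixed = TRUE)))
  expect_equal(cl$n_junctions, unname(ntok))
})

test_that("translation invariance: shifting all coordinates changes no label", {
  ann <- toy_annotation()
  ex <- as.data.frame(ann$exons)
  ex$start <- ex$start + 10000L
  ex$end <- ex$end + 10000L
  ann_shift <- tx_annotation(ex)
  reads <- data.frame(read_id = sprintf("r%d", 1:4),
                      transcript_id = c("T1", "T1", "T2", "T1"),
                      start = c(0L, 50L, 0L, 110L),
                      end = c(300L, 250L, 200L, 180L))
  a <- classify_reads(reads, ann)
  b <- classify_reads(reads, ann_shift)
  expect_equal(a$label, b$label)
  expect_equal(a$compatible, b$compatible)
})

test_that("classification agrees with the brute-force oracle on generated data", {
  cfg <- sim_config(n_genes = 10L, seed = 14L)
  gen <- generate_annotation(cfg)
  tr <- generate_expression(gen$annotation, cfg, 1L)
  rd <- simulate_long_reads(tr$cpm[, 1L], gen$annotation,
                            protocol_profile("dRNA-like"), 200L, 3L)
  cl <- classify_reads(rd, gen$annotation)
  for (i in seq_len(nrow(cl))) {
    o <- oracle_classify(gen$annotation, cl$target[i],
                         rd$start[match(cl$read_id[i], rd$read_id)],
                         rd$end[match(cl$read_id[i], rd$read_id)])
    expect_equal(cl$label[i], o$label, info = cl$read_id[i])
    expect_equal(sort(cl$compatible[[i]]), o$compatible,
                 info = cl$read_id[i])
  }
})

test_that("spliced-only mode leaves junction-free reads unassigned", {
  ann <- toy_annotation()
  reads <- data.frame(read_id = c("spliced", "exonic"),
                      transcript_id = "T1",
                      start = c(0L, 110L), end = c(300L, 180L))
  cl <- classify_reads(reads, ann, spliced_only = TRUE)
  lab <- setNames(cl$label, cl$read_id)
  expect_equal(lab[["spliced"]], "full_splice_match")
  expect_equal(lab[["exonic"]], "unassigned")
})

test_that("read classes aggregate counts, widths and compatibility", {
  ann <- toy_annotation()
  reads <- data.frame(read_id = sprintf("r%d", 1:5),
                      transcript_id = c("T1", "T1", "T1", "T2", "T1"),
                      start = c(0L, 0L, 0L, 0L, 110L),
                      end = c(300L, 300L, 150L, 200L, 180L))
  cl <- classify_reads(reads, ann)
  rc <- build_read_classes(cl, ann)
  expect_equal(sum(rc$count), 5L)
  full <- rc[rc$label == "full_splice_match" & rc$count == 2L, ]
  expect_equal(full$width, 300L)   # exonic span, introns excluded
  expect_equal(rc$gene_id, rep("G1", nrow(rc)))
  # two reads differing in one junction -> separate classes
  expect_gte(nrow(rc), 4L)
  # class compatibility equals per-read classification
  for (i in seq_len(nrow(rc))) {
    member <- cl[cl$chain == rc$chain[i] & cl$label == rc$label[i], ]
    expect_true(all(vapply(member$compatible, identical,
                           logical(1L), rc$compatible[[i]])))
  }
})

test_that("unique-assignment stats count reads, not classes", {
  ann <- toy_annotation()
  reads <- data.frame(read_id = sprintf("r%d", 1:4),
                      transcript_id = c("T1", "T1", "T2", "T1"),
                      start = c(0L, 0L, 0L, 110L),
                      end = c(300L, 300L, 200L, 180L))
  rc <- build_read_classes(classify_reads(reads, ann), ann)
  st <- unique_assignment_stats(rc)
  # 3 FSM unique reads; the exonic read sits in an exon shared by T1 only
  # (T2 skips exon 2), so all 4 are unique here
  expect_equal(st$fraction_unique, 1)
  # shared first exon: junction-free read inside exon 1 is compatible with
  # both isoforms
  rc2 <- build_read_classes(classify_reads(
    data.frame(read_id = "shared", transcript_id = "T1",
               start = 10L, end = 90L), ann), ann)
  st2 <- unique_assignment_stats(rc2)
  expect_equal(names(st2$histogram), "2")
  expect_equal(st2$fraction_unique, 0)
})
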