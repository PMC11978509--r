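mk_mat <- function(values, samples = 1L) {
  m <- matrix(rep(values, samples), ncol = samples)
  rownames(m) <- names(values)
  colnames(m) <- sprintf("s%d", seq_len(samples))
  m
}

three_iso_annotation <- function() {
  tx_annotation(data.frame(
    transcript_id = c("T1", "T1", "T2", "T2", "T3"),
    gene_id = c("G1", "G1", "G1", "G1", "G1"),
    chrom = "c", strand = "+",
    start = c(0L, 200L, 0L, 400L, 0L),
    end = c(100L, 300L, 100L, 500L, 100L)))
}

test_that("major isoform is the arg-max with lexicographic ties", {
  ann <- three_iso_annotation()
  mj <- major_isoforms(mk_mat(c(T1 = 5, T2 = 3, T3 = 1)), ann)
  expect_equal(mj$major_tx, "T1")
  mj2 <- major_isoforms(mk_mat(c(T1 = 4, T2 = 4, T3 = 1)), ann)
  expect_equal(mj2$major_tx, "T1")   # tie -> smallest id
  mj3 <- major_isoforms(mk_mat(c(T1 = 0, T2 = 0, T3 = 0)), ann)
  expect_equal(nrow(mj3), 0L)
  expect_equal(attr(mj3, "n_excluded"), 1L)
  # mean over replicates, not any single sample
  m <- cbind(c(T1 = 10, T2 = 0, T3 = 0), c(T1 = 0, T2 = 4, T3 = 0))
  rownames(m) <- c("T1", "T2", "T3")
  expect_equal(major_isoforms(m, ann)$major_tx, "T1")
})

test_that("four-way categorisation partitions the transcripts", {
  ann <- three_iso_annotation()
  lr <- major_isoforms(mk_mat(c(T1 = 5, T2 = 3, T3 = 1)), ann)
  sr_same <- major_isoforms(mk_mat(c(T1 = 9, T2 = 1, T3 = 0)), ann)
  cats <- categorize_isoforms(lr, sr_same, ann)
  ct <- setNames(cats$transcripts$category, cats$transcripts$transcript_id)
  expect_equal(ct[["T1"]], "major_shared")
  expect_equal(unname(ct[c("T2", "T3")]), c("minor", "minor"))
  sr_diff <- major_isoforms(mk_mat(c(T1 = 1, T2 = 9, T3 = 0)), ann)
  cats2 <- categorize_isoforms(lr, sr_diff, ann)
  ct2 <- setNames(cats2$transcripts$category,
                  cats2$transcripts$transcript_id)
  expect_equal(ct2[["T1"]], "major_LR_specific")
  expect_equal(ct2[["T2"]], "major_SR_specific")
  expect_equal(ct2[["T3"]], "minor")
  expect_equal(nrow(cats2$transcripts), 3L)
  expect_error(categorize_isoforms(lr, sr_diff[0L, ], ann), "mismatched")
})

test_that("concordance counts agree/disagree and sums to the gene universe", {
  ann <- three_iso_annotation()
  lr <- major_isoforms(mk_mat(c(T1 = 5, T2 = 3, T3 = 1)), ann)
  sr <- major_isoforms(mk_mat(c(T1 = 1, T2 = 9, T3 = 0)), ann)
  cc <- concordance(categorize_isoforms(lr, sr, ann))
  expect_equal(unname(cc), c(0L, 1L))
  cc2 <- concordance(categorize_isoforms(lr, lr, ann))
  expect_equal(unname(cc2), c(1L, 0L))
  expect_equal(sum(cc), 1L)
})

test_that("planted disagreement rate is recovered within the binomial CI", {
  set.seed(19)
  n <- 400L
  q <- 0.3
  ids <- sprintf("G%03d", seq_len(n))
  ex <- do.call(rbind, lapply(seq_len(n), function(i) data.frame(
    transcript_id = sprintf("%s.T%d", ids[i], 1:2),
    gene_id = ids[i], chrom = "c", strand = "+",
    start = c(0L, 0L) + (i - 1L) * 10000L,
    end = c(500L, 800L) + (i - 1L) * 10000L)))
  ann <- tx_annotation(ex)
  flip <- runif(n) < q
  lr_v <- unlist(lapply(seq_len(n), function(i)
    setNames(c(2, 1), sprintf("%s.T%d", ids[i], 1:2))))
  sr_v <- unlist(lapply(seq_len(n), function(i)
    setNames(if (flip[i]) c(1, 2) else c(2, 1),
             sprintf("%s.T%d", ids[i], 1:2))))
  lr <- major_isoforms(mk_mat(lr_v), ann)
  sr <- major_isoforms(mk_mat(sr_v), ann)
  cc <- concordance(categorize_isoforms(lr, sr, ann))
  expect_equal(sum(cc), n)
  ci <- qbinom(c(0.005, 0.995), n, q)
  expect_true(cc["n_disagree"] >= ci[1L] && cc["n_disagree"] <= ci[2L])
})

test_that("per-category agreement metrics behave at the identities", {
  ann <- three_iso_annotation()
  lr <- major_isoforms(mk_mat(c(T1 = 5, T2 = 3, T3 = 1)), ann)
  sr <- major_isoforms(mk_mat(c(T1 = 1, T2 = 9, T3 = 0)), ann)
  cats <- categorize_isoforms(lr, sr, ann)
  a <- mk_mat(c(T1 = 3, T2 = 2, T3 = 1))
  sp <- category_agreement(a, a, cats, "spearman")
  ma <- category_agreement(a, a, cats, "mae")
  # categories with < 3 transcripts are undefined
  expect_true(all(is.na(sp$value)))
  expect_true(all(is.na(ma$value)))
  # a 5-transcript minor category with hand-computed MAE
  ex <- data.frame(transcript_id = sprintf("T%d", 1:6), gene_id = "G",
                   chrom = "c", strand = "+",
                   start = (0:5) * 1000L, end = (0:5) * 1000L + 500L)
  ann6 <- tx_annotation(ex)
  v <- setNames(c(9, 5, 4, 3, 2, 1), sprintf("T%d", 1:6))
  mj <- major_isoforms(mk_mat(v), ann6)
  cats6 <- categorize_isoforms(mj, mj, ann6)
  b <- mk_mat(v + c(0, 1, -1, 2, 0, -2))
  ma6 <- category_agreement(mk_mat(v), b, cats6, "mae")
  expect_equal(ma6[ma6$category == "minor", ]$value, mean(c(1, 1, 2, 0, 2)))
})

test_that("random permutation drives Spearman toward zero", {
  set.seed(7)
  ex <- data.frame(transcript_id = sprintf("T%02d", 1:40), gene_id = "G",
                   chrom = "c", strand = "+",
                   start = (0:39) * 1000L, end = (0:39) * 1000L + 500L)
  ann <- tx_annotation(ex)
  v <- setNames(seq(40, 1), sprintf("T%02d", 1:40))
  mj <- major_isoforms(mk_mat(v), ann)
  cats <- categorize_isoforms(mj, mj, ann)
  perm <- sample(v)
  names(perm) <- names(v)
  sp <- category_agreement(mk_mat(v), mk_mat(perm), cats, "spearman")
  expect_lt(abs(sp[sp$category == "minor", ]$value), 0.45)
})

test_that("expressed fraction counts members at the CPM gate", {
  ann <- three_iso_annotation()
  mj <- major_isoforms(mk_mat(c(T1 = 5, T2 = 3, T3 = 0.2)), ann)
  cats <- categorize_isoforms(mj, mj, ann)
  ef <- expressed_fraction(mk_mat(c(T1 = 5, T2 = 3, T3 = 0.2)), cats,
                           threshold = 1)
  expect_equal(ef[ef$category == "minor", ]$fraction_expressed, 0.5)
  expect_equal(ef[ef$category == "major_shared", ]$fraction_expressed, 1)
})
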