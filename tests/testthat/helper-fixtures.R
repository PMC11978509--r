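# Shared fixtures: small hand-built annotations and an independent
# brute-force classification oracle used to cross-check classify_reads().

# one gene, two isoforms: T1 = three exons, T2 = skips the middle exon
toy_annotation <- function() {
  tx_annotation(data.frame(
    transcript_id = c("T1", "T1", "T1", "T2", "T2"),
    gene_id = "G1",
    chrom = "chr1",
    start = c(100L, 300L, 500L, 100L, 500L),
    end = c(200L, 400L, 600L, 200L, 600L),
    strand = "+",
    biotype = "protein_coding"))
}

# subset-isoform pair: LONG = exons 1..3, SUB = exons 2..3 with the outer
# exon extended 50 bp into the dropped intron
subset_annotation <- function(strand = "+") {
  tx_annotation(data.frame(
    transcript_id = c("LONG", "LONG", "LONG", "SUB", "SUB"),
    gene_id = "G1",
    chrom = "chr1",
    start = c(1000L, 2000L, 3000L, 1950L, 3000L),
    end = c(1200L, 2300L, 3400L, 2300L, 3400L),
    strand = strand,
    biotype = "protein_coding"))
}

# Independent oracle: classify a transcriptome-space read by direct
# enumeration over exon structures, without junction-chain string keys.
oracle_classify <- function(ann, target, start, end) {
  ex_t <- as.data.frame(ann$exons[ann$exons$transcript_id == target, ])
  ex_t <- ex_t[order(ex_t$start), ]
  w <- ex_t$end - ex_t$start
  # per-base transcript -> genome map (5'->3')
  gpos <- unlist(lapply(seq_len(nrow(ex_t)), function(i)
    seq(ex_t$start[i], ex_t$end[i] - 1L)))
  if (ex_t$strand[1L] == "-") gpos <- rev(gpos)
  bases <- sort(gpos[(start + 1L):end])          # genomic bases covered
  gs <- bases[1L]; ge <- bases[length(bases)] + 1L
  # read junction chain: gaps in the covered base set
  gaps <- which(diff(bases) > 1L)
  rchain <- cbind(bases[gaps] + 1L, bases[gaps + 1L])
  all_tx <- unique(ann$exons$transcript_id)
  fsm <- character(0L); part <- character(0L)
  for (tt in all_tx) {
    ex <- as.data.frame(ann$exons[ann$exons$transcript_id == tt, ])
    ex <- ex[order(ex$start), ]
    tchain <- if (nrow(ex) > 1L)
      cbind(ex$end[-nrow(ex)], ex$start[-1L]) else
        matrix(integer(0L), ncol = 2L)
    if (nrow(rchain) == 0L) {
      inside <- any(ex$start <= gs & ge <= ex$end)
      if (inside && nrow(ex) == 1L) fsm <- c(fsm, tt)
      else if (inside) part <- c(part, tt)
    } else {
      if (nrow(rchain) == nrow(tchain) && all(rchain == tchain)) {
        fsm <- c(fsm, tt)
      } else if (nrow(tchain) > nrow(rchain)) {
        # consecutive sub-chain at any offset, plus span containment
        hit <- FALSE
        for (o in 0:(nrow(tchain) - nrow(rchain))) {
          if (all(tchain[o + seq_len(nrow(rchain)), , drop = FALSE] ==
                    rchain)) hit <- TRUE
        }
        if (hit && gs >= min(ex$start) && ge <= max(ex$end))
          part <- c(part, tt)
      }
    }
  }
  if (length(fsm)) list(label = "full_splice_match", compatible = sort(fsm))
  else if (length(part)) list(label = "partial", compatible = sort(part))
  else list(label = "unassigned", compatible = character(0L))
}
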