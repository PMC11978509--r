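# Read classification: full-splice-match vs partial vs unassigned.
#
# Reads are accepted in transcriptome space (read_id, transcript_id, start,
# end; 0-based half-open on the transcript) and projected to genomic junction
# chains through the annotation, so transcriptome- and genome-space inputs
# share one code path. A read's chain is the consecutive run of its target
# transcript's junctions strictly inside the aligned interval.

#' Classify reads against an annotation
#'
#' Labels each read `full_splice_match` (its junction chain equals the
#' complete chain of at least one annotated transcript), `partial` (its chain
#' is a non-empty consecutive sub-chain of at least one transcript chain but
#' equals none, with the read span contained in that transcript's extent; or
#' the read is junction-free and contained within one exon of a multi-exon
#' transcript), or `unassigned`. The compatible set holds the transcripts
#' satisfying the matched condition.
#'
#' Junction-free reads contained in a single-exon transcript are
#' full-splice-match to it; `spliced_only = TRUE` instead leaves all
#' junction-free reads unassigned.
#'
#' @param reads data.frame with columns `read_id`, `transcript_id` (alignment
#'   target), `start`, `end` (0-based half-open transcript coordinates).
#' @param annotation A [tx_annotation()].
#' @param spliced_only Logical; classify spliced reads only.
#' @return data.table with one row per read: `read_id`, `target`,
#'   `label`, `n_junctions`, `chain` (junction-chain key), `gs`/`ge`
#'   (genomic span, 0-based half-open), `compatible` (list column of
#'   transcript ids), `n_compatible`.
#' @export
classify_reads <- function(reads, annotation, spliced_only = FALSE) {
  rd <- as.data.table(reads)
  req <- c("read_id", "transcript_id", "start", "end")
  if (!all(req %in% names(rd)))
    stop("reads need columns: ", paste(req, collapse = ", "))
  tx <- annotation$transcripts
  unknown <- setdiff(unique(rd$transcript_id), tx$transcript_id)
  if (length(unknown))
    stop("reads aligned to unknown transcript(s): ",
         paste(head(unknown, 3L), collapse = ", "))
  if (any(rd$start < 0L) ||
      any(rd$end > tx[J(rd$transcript_id), length]) ||
      any(rd$end <= rd$start))
    stop("read interval outside its transcript")

  jn <- annotation$junctions
  # covered junction range per read, in transcript order
  rd[, `:=`(j_lo = 0L, j_hi = -1L)]
  jl <- jn[, .(pos = list(sort(tx_pos))), by = transcript_id]
  rd <- jl[rd, on = "transcript_id"]
  rd[, c("j_lo", "j_hi") := {
    if (is.null(pos[[1L]])) list(1L, 0L) else {
      p <- pos[[1L]]
      lo <- findInterval(start, p) + 1L          # first junction with tx_pos > start
      hi <- findInterval(end - 1L, p)            # last junction with tx_pos < end
      list(lo, hi)
    }
  }, by = transcript_id]
  rd[, pos := NULL]
  rd[, n_junctions := pmax(0L, j_hi - j_lo + 1L)]

  # genomic span of each read
  info <- tx[J(rd$transcript_id)]
  rd[, `:=`(chrom = info$chrom, strand = info$strand, tlen = info$length)]
  # genomic coordinates of read ends (per target transcript, vectorised)
  rd[, c("gs", "ge") := {
    a <- transcript_to_genome(annotation, .BY[[1L]], start)
    b <- transcript_to_genome(annotation, .BY[[1L]], end - 1L)
    list(pmin(a, b), pmax(a, b) + 1L)
  }, by = transcript_id]

  # map covered transcript-order junction range to genomic-order range
  nj_tbl <- jn[, .(k = max(g_index)), by = transcript_id]
  rd <- nj_tbl[rd, on = "transcript_id"]
  rd[is.na(k), k := 0L]
  rd[, `:=`(
    g_lo = fifelse(n_junctions == 0L, 0L,
                   fifelse(strand == "+", j_lo, k + 1L - j_hi)),
    g_hi = fifelse(n_junctions == 0L, -1L,
                   fifelse(strand == "+", j_hi, k + 1L - j_lo)))]

  # ---- spliced reads: match chain keys ------------------------------------
  spliced <- rd[n_junctions > 0L]
  res_spliced <- NULL
  if (nrow(spliced)) {
    combos <- unique(spliced[, .(transcript_id, g_lo, g_hi)])
    setkey(jn, transcript_id)
    combos[, chain := {
      toks <- jn[J(.BY$transcript_id)][g_index >= .BY$g_lo &
                                         g_index <= .BY$g_hi][order(g_index),
                                                              token]
      paste0("|", paste(toks, collapse = "|"), "|")
    }, by = .(transcript_id, g_lo, g_hi)]
    combos[, first_token := jn[J(.BY$transcript_id)][g_index == .BY$g_lo,
                                                     token],
           by = .(transcript_id, g_lo, g_hi)]
    spliced <- combos[spliced, on = c("transcript_id", "g_lo", "g_hi")]

    # candidate transcripts share the read's first junction
    jidx <- jn[, .(token, cand = transcript_id)]
    matches <- merge(unique(spliced[, .(chain, first_token, gs, ge)]),
                     jidx, by.x = "first_token", by.y = "token",
                     allow.cartesian = TRUE)
    cand_info <- tx[, .(cand = transcript_id, cchain = chain,
                        cstart = tx_start, cend = tx_end)]
    matches <- cand_info[matches, on = "cand"]
    matches[, hit := vapply(seq_len(.N), function(i)
      grepl(chain[i], cchain[i], fixed = TRUE), logical(1L))]
    matches <- matches[hit == TRUE & gs >= cstart & ge <= cend]
    matches[, exact := chain == cchain]
    msum <- matches[, .(
      fsm = any(exact),
      compat_fsm = list(sort(cand[exact])),
      compat_any = list(sort(cand))), by = .(chain, gs, ge)]
    res_spliced <- msum[spliced, on = c("chain", "gs", "ge")]
    res_spliced[is.na(fsm), fsm := FALSE]
    res_spliced[, label := fifelse(fsm, "full_splice_match",
                                   fifelse(lengths(compat_any) > 0L, "partial",
                                           "unassigned"))]
    res_spliced[, compatible := compat_any]
    res_spliced[label == "full_splice_match", compatible := compat_fsm]
    res_spliced[label == "unassigned",
                compatible := list(list(character(0L)))]
    res_spliced[, compatible := lapply(compatible, function(x)
      if (is.null(x)) character(0L) else x)]
  }

  # ---- junction-free reads: exon containment ------------------------------
  jfree <- rd[n_junctions == 0L]
  if (nrow(jfree)) {
    if (spliced_only) {
      jfree[, chain := ""]
      jfree[, label := "unassigned"]
      jfree[, compatible := list(rep(list(character(0L)), .N))]
    } else {
      ex <- annotation$exons
      qry <- GenomicRanges::GRanges(jfree$chrom,
                                    IRanges::IRanges(jfree$gs + 1L, jfree$ge))
      sbj <- GenomicRanges::GRanges(ex$chrom,
                                    IRanges::IRanges(ex$start + 1L, ex$end))
      ov <- GenomicRanges::findOverlaps(qry, sbj, type = "within",
                                        ignore.strand = TRUE)
      hits <- data.table(row = S4Vectors::queryHits(ov),
                         cand = ex$transcript_id[S4Vectors::subjectHits(ov)])
      hits <- unique(hits)
      hits <- tx[, .(cand = transcript_id, cse = single_exon)][hits, on = "cand"]
      hsum <- hits[, .(
        any_se = any(cse),
        compat_se = list(sort(cand[cse])),
        compat_me = list(sort(cand[!cse]))), by = row]
      jfree[, row := .I]
      jfree <- hsum[jfree, on = "row"]
      jfree[is.na(any_se), any_se := FALSE]
      jfree[, label := fifelse(any_se, "full_splice_match",
                               fifelse(lengths(compat_me) > 0L, "partial",
                                       "unassigned"))]
      jfree[, compatible := compat_me]
      jfree[label == "full_splice_match", compatible := compat_se]
      jfree[label == "unassigned", compatible := list(list(character(0L)))]
      jfree[, compatible := lapply(compatible, function(x)
        if (is.null(x)) character(0L) else x)]
      jfree[, chain := ""]
    }
  }

  cols <- c("read_id", "transcript_id", "label", "n_junctions", "chain",
            "gs", "ge", "compatible")
  out <- rbind(
    if (!is.null(res_spliced)) res_spliced[, ..cols],
    if (nrow(jfree)) jfree[, ..cols])
  setnames(out, "transcript_id", "target")
  out[, n_compatible := lengths(compatible)]
  out[]
}

#' Junctions covered per read
#'
#' @param classified Output of [classify_reads()].
#' @return Integer vector, one per read (the junction-chain length; equals
#'   the aligned block count minus one).
#' @export
junctions_per_read <- function(classified) classified$n_junctions

#' Group classified reads into read classes
#'
#' Reads sharing a junction chain (and, for junction-free reads, the same
#' compatible set on the same chromosome) and label are collapsed into one
#' class carrying the read count, the span of the class's exonic projection
#' (`width`, in exonic bases), and the compatible transcript set.
#'
#' @param classified Output of [classify_reads()].
#' @param annotation The matching [tx_annotation()].
#' @param drop_unassigned Exclude unassigned reads from the classes
#'   (their count is recorded in the `n_unassigned` attribute).
#' @return data.table of classes: `class_id`, `chain`, `label`, `count`,
#'   `width`, `compatible` (list), `gene_id` (NA when compatible transcripts
#'   span several genes).
#' @export
build_read_classes <- function(classified, annotation, drop_unassigned = TRUE) {
  cl <- as.data.table(classified)
  n_un <- sum(cl$label == "unassigned")
  if (drop_unassigned) cl <- cl[label != "unassigned"]
  compat_key <- vapply(cl$compatible, function(x) paste(x, collapse = ","),
                       character(1L))
  cl[, key_ := paste0(label, "/", fifelse(chain == "",
                                          paste0(".", compat_key), chain))]
  jn <- annotation$junctions
  out <- cl[, {
    span <- max(ge) - min(gs)
    intron <- 0L
    if (chain[1L] != "") {
      toks <- strsplit(substr(chain[1L], 2L, nchar(chain[1L]) - 1L),
                       "|", fixed = TRUE)[[1L]]
      co <- do.call(rbind, strsplit(sub("^.*:", "", toks), "-", fixed = TRUE))
      intron <- sum(as.integer(co[, 2L]) - as.integer(co[, 1L]))
    }
    .(chain = chain[1L], label = label[1L], count = .N,
      width = span - intron, compatible = list(compatible[[1L]]))
  }, by = key_]
  tx2gene <- setNames(annotation$transcripts$gene_id,
                      annotation$transcripts$transcript_id)
  out[, gene_id := vapply(compatible, function(tt) {
    g <- unique(tx2gene[tt])
    if (length(g) == 1L) g else NA_character_
  }, "")]
  out[, class_id := seq_len(.N)]
  out[, key_ := NULL]
  setcolorder(out, c("class_id", "chain", "label", "count", "width",
                     "compatible", "gene_id"))
  setattr(out, "n_unassigned", n_un)
  out[]
}

#' Distribution of compatible-set sizes per read
#'
#' Histogram of the number of compatible transcripts per read (weighted by
#' read count when given classes), plus the fraction of reads uniquely
#' assigned to a single transcript.
#'
#' @param classes Output of [build_read_classes()] (or of
#'   [classify_reads()], in which case each read counts once).
#' @return `list(histogram = named integer vector, fraction_unique)`.
#' @export
unique_assignment_stats <- function(classes) {
  cl <- as.data.table(classes)
  w <- if ("count" %in% names(cl)) cl$count else rep(1L, nrow(cl))
  sizes <- lengths(cl$compatible)
  h <- tapply(w, factor(sizes, levels = sort(unique(sizes))), sum)
  h <- setNames(as.integer(h), names(h))
  list(histogram = h,
       fraction_unique = sum(w[sizes == 1L]) / sum(w))
}
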