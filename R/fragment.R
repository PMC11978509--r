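# In-silico fragmentation of long reads into fixed-length short fragments,
# the 5'-anchored trimming series, and the fragmentation-impact experiment.

#' Fragment long reads into fixed-length short fragments
#'
#' Each read with mapped length (alignment span on the transcript) of at
#' least `min_mapped` bases yields `N = floor(mapped / L)` fragments whose
#' start positions are drawn independently from the discrete uniform on
#' `[aln_start, aln_end - L]` (inclusive); shorter reads are skipped and
#' counted. With `n_rule = "uniform"`, N is instead drawn uniformly on
#' `[1, floor(mapped / L)]` per read (sensitivity mode).
#'
#' @param reads data.table(read_id, transcript_id, start, end) in transcript
#'   coordinates.
#' @param L Fragment length (default 150).
#' @param min_mapped Minimum mapped length to fragment (default `L`).
#' @param n_rule `"floor"` (deterministic) or `"uniform"`.
#' @param seed Integer seed (required; fragmentation is a random resample).
#' @return data.table(read_id = fragment id, source_read, transcript_id,
#'   start, end) with `end - start == L`; attribute `n_skipped` counts
#'   reads below `min_mapped`.
#' @export
fragment_reads <- function(reads, L = 150L, min_mapped = L,
                           n_rule = c("floor", "uniform"), seed) {
  n_rule <- match.arg(n_rule)
  if (missing(seed)) stop("seed is required")
  if (min_mapped < L) stop("min_mapped must be >= L")
  set.seed(seed)
  rd <- as.data.table(reads)
  rd[, mapped := end - start]
  skipped <- sum(rd$mapped < min_mapped)
  rd <- rd[mapped >= min_mapped]
  if (nrow(rd) == 0L) {
    out <- data.table(read_id = character(), source_read = character(),
                      transcript_id = character(), start = integer(),
                      end = integer())
    setattr(out, "n_skipped", skipped)
    return(out)
  }
  nmax <- rd$mapped %/% L
  n <- if (n_rule == "floor") nmax
  else 1L + as.integer(floor(runif(nrow(rd)) * nmax))
  idx <- rep(seq_len(nrow(rd)), n)
  lo <- rd$start[idx]
  hi <- rd$end[idx] - L                       # inclusive upper start bound
  fstart <- lo + as.integer(floor(runif(length(idx)) * (hi - lo + 1L)))
  out <- data.table(
    read_id = sprintf("F%08d", seq_along(idx)),
    source_read = rd$read_id[idx],
    transcript_id = rd$transcript_id[idx],
    start = fstart, end = fstart + as.integer(L))
  stopifnot(all(out$start >= lo), all(out$end <= rd$end[idx]))
  setattr(out, "n_skipped", skipped)
  out[]
}

#' Extract fragment sequences from transcript sequences
#'
#' Fragment sequences are reference substrings (error-corrected by
#' construction); no reverse complement is applied, as fragments live in
#' transcript space.
#'
#' @param fragments Output of [fragment_reads()].
#' @param sequences Named `Biostrings::DNAStringSet` of transcript
#'   sequences.
#' @return data.table(read_id, transcript_id, sequence).
#' @export
fragments_to_reads <- function(fragments, sequences) {
  fr <- as.data.table(fragments)
  if (nrow(fr) == 0L)
    return(data.table(read_id = character(), transcript_id = character(),
                      sequence = character()))
  lens <- Biostrings::width(sequences)[match(fr$transcript_id,
                                             names(sequences))]
  if (anyNA(lens)) stop("fragment on transcript without sequence")
  if (any(fr$end > lens)) stop("fragment exceeds transcript end")
  seqs <- as.character(Biostrings::subseq(sequences[fr$transcript_id],
                                          start = fr$start + 1L,
                                          end = fr$end))
  data.table(read_id = fr$read_id, transcript_id = fr$transcript_id,
             sequence = unname(seqs))
}

#' Write fragment sequences as FASTQ
#'
#' Uniform quality (no error model); a thin convenience wrapper.
#'
#' @param frag_seqs Output of [fragments_to_reads()].
#' @param path Output FASTQ path.
#' @return `path`, invisibly.
#' @export
write_fragment_fastq <- function(frag_seqs, path) {
  x <- Biostrings::DNAStringSet(frag_seqs$sequence)
  names(x) <- frag_seqs$read_id
  Biostrings::writeXStringSet(
    x, path, format = "fastq",
    qualities = Biostrings::BStringSet(
      vapply(Biostrings::width(x), function(w)
        paste(rep("I", w), collapse = ""), character(1L))))
  invisible(path)
}

#' 5'-anchored read trimming
#'
#' Retains the first `target_length` bases of every sequence; shorter
#' sequences pass through unchanged and are counted.
#'
#' @param sequences Character vector of read sequences.
#' @param target_length Target length (e.g. 150, 125, 100, 75, 50).
#' @return Character vector of trimmed sequences; attribute `n_short`
#'   counts sequences shorter than the target.
#' @export
trim_reads <- function(sequences, target_length) {
  n_short <- sum(nchar(sequences) < target_length)
  out <- substr(sequences, 1L, target_length)
  attr(out, "n_short") <- n_short
  out
}

#' Fragmentation-impact experiment
#'
#' Quantifies a long-read sample before and after in-silico fragmentation
#' and measures per-category agreement. The long-read estimates come from
#' the EM in count mode; fragment estimates use molar mode (effective-length
#' weighted E-step), the convention of short-read quantifiers. When an
#' independent short-read sample's estimates are supplied, the overall
#' Spearman correlation of the short-read estimates with the original
#' versus the fragmented long-read estimates is also reported.
#'
#' @param lr_reads data.table of long-read transcriptome alignments.
#' @param annotation A [tx_annotation()].
#' @param categorized Output of [categorize_isoforms()] defining the
#'   categories to stratify by (optional; when NULL only the overall
#'   statistics are computed).
#' @param sr_cpm Optional named short-read abundance vector (CPM/TPM scale)
#'   for the independent comparison.
#' @param L Fragment length (default 150).
#' @param seed Integer seed for the fragmentation resample.
#' @return list(lr = long-read quantification, frag = fragment
#'   quantification, per_category = data.table(category, sample_pair,
#'   spearman, mae) or NULL, overall = list(spearman_lr_frag,
#'   spearman_sr_lr, spearman_sr_frag), n_fragments).
#' @export
fragmentation_experiment <- function(lr_reads, annotation,
                                     categorized = NULL, sr_cpm = NULL,
                                     L = 150L, seed) {
  if (missing(seed)) stop("seed is required")
  cls_lr <- build_read_classes(classify_reads(lr_reads, annotation),
                               annotation)
  q_lr <- em_quantify(cls_lr, annotation, weights = "count")
  frags <- fragment_reads(lr_reads, L = L, seed = seed)
  cls_fr <- build_read_classes(classify_reads(frags, annotation),
                               annotation)
  q_fr <- em_quantify(cls_fr, annotation, weights = "molar",
                      fragment_length = L)
  lr_v <- setNames(q_lr$cpm, q_lr$transcript_id)
  fr_v <- setNames(q_fr$tpm, q_fr$transcript_id)[names(lr_v)]
  lg_lr <- log2_transform(lr_v)
  lg_fr <- log2_transform(fr_v)
  per_cat <- NULL
  if (!is.null(categorized)) {
    a <- matrix(lg_lr, ncol = 1L, dimnames = list(names(lr_v), "s1"))
    b <- matrix(lg_fr, ncol = 1L, dimnames = list(names(lr_v), "s1"))
    sp <- category_agreement(a, b, categorized, "spearman")
    ma <- category_agreement(a, b, categorized, "mae")
    per_cat <- merge(setnames(sp, "value", "spearman"),
                     setnames(ma, "value", "mae"),
                     by = c("category", "sample_pair"))
  }
  overall <- list(
    spearman_lr_frag = suppressWarnings(
      cor(lg_lr, lg_fr, method = "spearman")),
    spearman_sr_lr = NA_real_, spearman_sr_frag = NA_real_)
  if (!is.null(sr_cpm)) {
    sr <- log2_transform(sr_cpm[names(lr_v)])
    overall$spearman_sr_lr <- suppressWarnings(
      cor(sr, lg_lr, method = "spearman"))
    overall$spearman_sr_frag <- suppressWarnings(
      cor(sr, lg_fr, method = "spearman"))
  }
  list(lr = q_lr, frag = q_fr, per_category = per_cat, overall = overall,
       n_fragments = nrow(frags))
}

#' Fragmentation benchmark across seeds
#'
#' Runs the full fragmentation-impact experiment on subset-isoform synthetic
#' genomes for a series of seeds: for each seed a genome is generated, one
#' long-read and one independent short-read replicate are simulated and
#' quantified, major isoforms are categorised between the technologies, the
#' long-read sample is fragmented in silico, and per-category Spearman
#' agreement between original and fragmented estimates is recorded together
#' with the overall short-read correlations before and after fragmentation.
#'
#' @param seeds Integer vector of seeds (one experiment per seed).
#' @param n_genes,subset_isoform_fraction,n_reads Genome and library size of
#'   each experiment.
#' @return data.table with one row per seed: Spearman per category
#'   (`sp_shared`, `sp_lr_specific`, `sp_sr_specific`, `sp_minor`),
#'   `spearman_sr_lr`, `spearman_sr_frag`, and the category ordering flag
#'   `ordering_ok` (shared >= LR-specific >= SR-specific).
#' @export
fragmentation_benchmark <- function(seeds, n_genes = 150L,
                                    subset_isoform_fraction = 0.5,
                                    n_reads = 15000L) {
  rows <- lapply(seeds, function(seed) {
    cfg <- sim_config(n_genes = n_genes,
                      isoform_probs = c(0.2, 0.5, 0.3),
                      subset_isoform_fraction = subset_isoform_fraction,
                      n_reads = n_reads, seed = seed)
    gen <- generate_annotation(cfg)
    ann <- gen$annotation
    tr <- generate_expression(ann, cfg, n_samples = 2L)
    prof <- protocol_profile("dcDNA-like")
    lr <- simulate_long_reads(tr$cpm[, 1L], ann, prof, n_reads,
                              seed + 100L)
    sr <- simulate_short_reads(tr$cpm[, 2L], ann, cfg$fragment_length,
                               n_reads, seed + 200L)
    qlr <- em_quantify(build_read_classes(classify_reads(lr, ann), ann),
                       ann)
    qsr <- suppressWarnings(
      em_quantify(build_read_classes(classify_reads(sr, ann), ann), ann,
                  weights = "molar",
                  fragment_length = cfg$fragment_length))
    ids <- ann$transcripts$transcript_id
    lrm <- matrix(setNames(qlr$cpm, qlr$transcript_id)[ids], ncol = 1L,
                  dimnames = list(ids, "s"))
    srm <- matrix(setNames(qsr$tpm, qsr$transcript_id)[ids], ncol = 1L,
                  dimnames = list(ids, "s"))
    glr <- gene_expression(lrm, ann)
    gsr <- gene_expression(srm, ann)
    shared <- intersect(rownames(glr)[glr[, 1L] > 0],
                        rownames(gsr)[gsr[, 1L] > 0])
    keep <- ids[ann$transcripts[J(ids), gene_id] %in% shared]
    ml <- major_isoforms(lrm[keep, , drop = FALSE], ann)
    ms <- major_isoforms(srm[keep, , drop = FALSE], ann)
    g2 <- intersect(ml$gene_id, ms$gene_id)
    cats <- categorize_isoforms(ml[ml$gene_id %in% g2, ],
                                ms[ms$gene_id %in% g2, ], ann)
    fx <- suppressWarnings(fragmentation_experiment(
      lr, ann, categorized = cats,
      sr_cpm = setNames(srm[, 1L], ids), L = cfg$fragment_length,
      seed = seed + 300L))
    sp <- setNames(fx$per_category$spearman, fx$per_category$category)
    pick <- function(k) if (k %in% names(sp)) unname(sp[k]) else NA_real_
    data.table(
      seed = seed,
      sp_shared = pick("major_shared"),
      sp_lr_specific = pick("major_LR_specific"),
      sp_sr_specific = pick("major_SR_specific"),
      sp_minor = pick("minor"),
      spearman_sr_lr = fx$overall$spearman_sr_lr,
      spearman_sr_frag = fx$overall$spearman_sr_frag,
      ordering_ok = isTRUE(pick("major_shared") >=
                             pick("major_LR_specific") &&
                             pick("major_LR_specific") >=
                             pick("major_SR_specific")))
  })
  rbindlist(rows)
}
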