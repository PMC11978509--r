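#' @import data.table
#' @importFrom stats rbinom rgamma rlnorm rmultinom runif rnorm setNames
#'   pnorm cor sd median quantile chisq.test
#' @importFrom utils head tail
NULL

.datatable.aware <- TRUE

utils::globalVariables(c(
  ".", ".N", ".SD", "transcript_id", "gene_id", "chrom", "start", "end",
  "strand", "biotype", "width", "tx_order", "donor_end", "acceptor_start",
  "g_index", "tx_pos", "token", "length", "n_exons", "tx_start", "tx_end",
  "chain", "single_exon", "gene_length", "n_tx", "read_id", "label",
  "n_junctions", "compatible", "n_compatible", "count", "class_id",
  "j_lo", "j_hi", "gs", "ge", "est_count", "cpm", "category", "sample_id",
  "weight", "denom", "share", "frag_id", "source_read", "mapped", "n_frag",
  "exon_idx", "target", "value", "key_", "cell_line", "protocol", "replicate"
))

# ---------------------------------------------------------------------------
# Annotation container
# ---------------------------------------------------------------------------

#' Build a transcript annotation object
#'
#' Constructs the package's central annotation container from an exon table.
#' Coordinates are 0-based half-open internally; [read_gtf()] performs the
#' conversion from the 1-based closed GTF convention.
#'
#' @param exons A data.frame with columns `transcript_id`, `gene_id`,
#'   `chrom`, `start`, `end` (0-based half-open), `strand` (`"+"`/`"-"`),
#'   and optionally `biotype` (per-transcript gene biotype).
#' @return An object of class `tx_annotation`: a list of data.tables
#'   (`exons`, `transcripts`, `genes`, `junctions`) plus a junction index.
#'   Junction chains are stored as strings of `chrom:donor-acceptor` tokens
#'   delimited by `|`, so consecutive sub-chain containment is substring
#'   containment.
#' @export
tx_annotation <- function(exons) {
  ex <- as.data.table(exons)
  req <- c("transcript_id", "gene_id", "chrom", "start", "end", "strand")
  miss <- setdiff(req, names(ex))
  if (length(miss)) stop("exon table missing columns: ", paste(miss, collapse = ", "))
  if (!"biotype" %in% names(ex)) ex[, biotype := NA_character_]
  if (nrow(ex) == 0L) stop("empty exon table")
  if (any(ex$start >= ex$end)) stop("exon with start >= end")
  setorder(ex, transcript_id, start)
  # per-transcript sanity: single chrom/strand, non-overlapping exons
  bad <- ex[, .(one = uniqueN(chrom) == 1L && uniqueN(strand) == 1L &&
                  uniqueN(gene_id) == 1L &&
                  (.N == 1L || all(start[-1L] >= end[-.N]))),
            by = transcript_id][one == FALSE]
  if (nrow(bad)) stop("inconsistent exons for transcript(s): ",
                      paste(head(bad$transcript_id, 5L), collapse = ", "))

  tx <- ex[, .(gene_id = gene_id[1L], chrom = chrom[1L], strand = strand[1L],
               biotype = biotype[1L], length = sum(end - start), n_exons = .N,
               tx_start = min(start), tx_end = max(end)),
           by = transcript_id]

  # junctions in genomic order; tx_pos is the transcript-space coordinate of
  # the junction (number of transcript bases 5' of it)
  jn <- ex[, if (.N > 1L) {
    w <- end - start
    pos_plus <- cumsum(w)[-.N]
    pos <- if (strand[1L] == "+") pos_plus else rev(cumsum(rev(w))[-.N])
    .(chrom = chrom[1L], strand = strand[1L],
      donor_end = end[-.N], acceptor_start = start[-1L],
      g_index = seq_len(.N - 1L), tx_pos = pos)
  }, by = transcript_id]
  if (nrow(jn)) {
    jn[, token := paste0(chrom, ":", donor_end, "-", acceptor_start)]
    chains <- jn[, .(chain = paste0("|", paste(token, collapse = "|"), "|")),
                 by = transcript_id]
  } else {
    jn <- data.table(transcript_id = character(), chrom = character(),
                     strand = character(), donor_end = integer(),
                     acceptor_start = integer(), g_index = integer(),
                     tx_pos = integer(), token = character())
    chains <- data.table(transcript_id = character(), chain = character())
  }
  tx <- chains[tx, on = "transcript_id"]
  tx[is.na(chain), chain := ""]
  tx[, single_exon := n_exons == 1L]
  setcolorder(tx, c("transcript_id", "gene_id", "chrom", "strand", "biotype",
                    "length", "n_exons", "tx_start", "tx_end", "chain",
                    "single_exon"))
  if (anyDuplicated(tx$transcript_id)) stop("duplicate transcript ids")

  gn <- tx[, .(chrom = chrom[1L], strand = strand[1L], biotype = biotype[1L],
               n_tx = .N, gene_length = max(length),
               start = min(tx_start), end = max(tx_end)),
           by = gene_id]
  setkey(ex, transcript_id)
  setkey(tx, transcript_id)
  setkey(gn, gene_id)
  setkey(jn, transcript_id)
  structure(list(exons = ex, transcripts = tx, genes = gn, junctions = jn),
            class = "tx_annotation")
}

#' @export
print.tx_annotation <- function(x, ...) {
  cat(sprintf("tx_annotation: %d genes, %d transcripts, %d exons\n",
              nrow(x$genes), nrow(x$transcripts), nrow(x$exons)))
  invisible(x)
}

#' Number of genes / transcripts in an annotation
#' @param annotation A `tx_annotation`.
#' @return Integer count.
#' @export
n_genes <- function(annotation) nrow(annotation$genes)

#' @rdname n_genes
#' @export
n_transcripts <- function(annotation) nrow(annotation$transcripts)

# ---------------------------------------------------------------------------
# GTF I/O (Ensembl dialect), via rtracklayer
# ---------------------------------------------------------------------------

#' Read a GTF annotation
#'
#' Reads gene/transcript/exon features from an Ensembl-style GTF
#' (1-based closed coordinates, `gene_id`/`transcript_id`/`gene_biotype`
#' attributes) into the internal 0-based half-open representation.
#'
#' @param path Path to a GTF file.
#' @param strip_versions Drop trailing `.N` version suffixes from gene and
#'   transcript ids.
#' @return A [tx_annotation()].
#' @export
read_gtf <- function(path, strip_versions = FALSE) {
  gr <- rtracklayer::import(path, format = "gtf")
  md <- S4Vectors::mcols(gr)
  keep <- md$type == "exon"
  if (!any(keep)) stop("no exon features in GTF: ", path)
  gr <- gr[keep]
  md <- S4Vectors::mcols(gr)
  if (is.null(md$transcript_id) || anyNA(md$transcript_id))
    stop("exon feature without transcript_id in ", path)
  if (is.null(md$gene_id) || anyNA(md$gene_id))
    stop("exon feature without gene_id in ", path)
  bt <- if ("gene_biotype" %in% names(md)) md$gene_biotype else NA_character_
  ex <- data.table(
    transcript_id = as.character(md$transcript_id),
    gene_id = as.character(md$gene_id),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,   # 1-based closed -> 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    biotype = as.character(bt))
  if (strip_versions) {
    ex[, transcript_id := strip_id_versions(transcript_id)]
    ex[, gene_id := strip_id_versions(gene_id)]
  }
  tx_annotation(ex)
}

#' Write an annotation as GTF
#'
#' Emits gene, transcript and exon features with `gene_id`, `transcript_id`
#' and `gene_biotype` attributes, converting back to 1-based closed
#' coordinates. `read_gtf(write_gtf(x))` is the identity.
#'
#' @param annotation A `tx_annotation`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(annotation, path) {
  ex <- annotation$exons
  gr <- GenomicRanges::GRanges(
    seqnames = ex$chrom,
    ranges = IRanges::IRanges(start = ex$start + 1L, end = ex$end),
    strand = ex$strand)
  S4Vectors::mcols(gr)$type <- "exon"
  S4Vectors::mcols(gr)$source <- "txcompare"
  S4Vectors::mcols(gr)$gene_id <- ex$gene_id
  S4Vectors::mcols(gr)$transcript_id <- ex$transcript_id
  S4Vectors::mcols(gr)$gene_biotype <- ex$biotype
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Strip trailing version suffixes from feature ids
#' @param ids Character vector, e.g. `"ENST0000123.4"`.
#' @return Ids without the final `.N` component.
#' @export
strip_id_versions <- function(ids) sub("\\.[0-9]+$", "", ids)

# ---------------------------------------------------------------------------
# Accessors / core operations
# ---------------------------------------------------------------------------

#' Splice-junction chain of a transcript
#'
#' The ordered list of (donor end, acceptor start) pairs, in ascending
#' genomic order regardless of strand; empty for single-exon transcripts.
#' Junction identity is purely genomic, matching how junction equality is
#' evaluated from read alignments.
#'
#' @param annotation A `tx_annotation`.
#' @param transcript A transcript id.
#' @return data.table with columns `donor_end`, `acceptor_start`.
#' @export
junction_chain <- function(annotation, transcript) {
  if (!transcript %in% annotation$transcripts$transcript_id)
    stop("unknown transcript: ", transcript)
  jn <- annotation$junctions[transcript_id == transcript]
  setorder(jn, g_index)
  jn[, .(donor_end, acceptor_start)]
}

#' Gene length (maximum isoform length)
#'
#' @param annotation A `tx_annotation`.
#' @param gene A gene id (vectorised).
#' @return Length in bases: the maximum transcript length of the gene.
#' @export
gene_length <- function(annotation, gene) {
  gl <- annotation$genes[J(gene), gene_length]
  if (anyNA(gl)) stop("unknown gene id(s)")
  gl
}

#' Restrict an annotation to genes fully present in a transcript catalog
#'
#' Removes every gene with at least one transcript absent from `catalog`
#' (typically the ids of a transcriptome FASTA), so genomic and
#' transcriptomic annotations describe the same transcript universe.
#'
#' @param annotation A `tx_annotation` (must be non-empty).
#' @param catalog Character vector of transcript ids.
#' @param strip_versions Strip version suffixes from both sides before
#'   matching.
#' @return `list(annotation = filtered tx_annotation or NULL if all genes
#'   removed, removed_genes = count)`.
#' @export
match_annotations <- function(annotation, catalog, strip_versions = FALSE) {
  if (n_genes(annotation) == 0L) stop("empty annotation")
  tx <- annotation$transcripts
  ids <- tx$transcript_id
  cat_ids <- as.character(catalog)
  if (strip_versions) {
    ids <- strip_id_versions(ids)
    cat_ids <- strip_id_versions(cat_ids)
  }
  present <- ids %in% cat_ids
  keep_genes <- tx[, .(all_present = all(present[.I])), by = gene_id][
    all_present == TRUE, gene_id]
  removed <- n_genes(annotation) - length(keep_genes)
  list(annotation = subset_genes(annotation, keep_genes),
       removed_genes = removed)
}

#' Filter genes by biotype
#'
#' Keeps genes whose biotype is in `allowed`; the default set is
#' protein-coding genes, antisense RNAs, long intergenic noncoding RNAs,
#' noncoding RNAs and macro long-noncoding RNAs (Ensembl labels).
#' Genes with an unknown/NA biotype are removed and counted, never silently
#' dropped.
#'
#' @param annotation A `tx_annotation`.
#' @param allowed Character vector of Ensembl biotype labels.
#' @return `list(annotation, removed_genes)`.
#' @export
filter_biotypes <- function(annotation,
                            allowed = c("protein_coding", "antisense",
                                        "lincRNA", "non_coding",
                                        "macro_lncRNA")) {
  gn <- annotation$genes
  keep <- gn[!is.na(biotype) & biotype %in% allowed, gene_id]
  list(annotation = subset_genes(annotation, keep),
       removed_genes = nrow(gn) - length(keep))
}

subset_genes <- function(annotation, gene_ids) {
  if (length(gene_ids) == 0L) return(NULL)
  ex <- annotation$exons[gene_id %in% gene_ids]
  tx_annotation(ex)
}

#' Map a transcript-space offset to a genomic position
#'
#' Transcript space runs 5' to 3' (reverse of genomic order on the minus
#' strand); offsets are 0-based.
#'
#' @param annotation A `tx_annotation`.
#' @param transcript A transcript id.
#' @param pos Integer vector of offsets, `0 <= pos < length`.
#' @return Integer vector of genomic positions (0-based).
#' @export
transcript_to_genome <- function(annotation, transcript, pos) {
  ex <- annotation$exons[J(transcript)]
  if (anyNA(ex$start)) stop("unknown transcript: ", transcript)
  len <- sum(ex$end - ex$start)
  pos <- as.integer(pos)
  if (any(pos < 0L | pos >= len)) stop("position out of transcript range")
  w <- ex$end - ex$start
  if (ex$strand[1L] == "+") {
    cum <- c(0L, cumsum(w))
    i <- findInterval(pos, cum, rightmost.closed = FALSE)  # exon index
    ex$start[i] + (pos - cum[i])
  } else {
    # transcript order = descending genomic order
    wr <- rev(w)
    cum <- c(0L, cumsum(wr))
    i <- findInterval(pos, cum)
    k <- nrow(ex) + 1L - i   # genomic exon index
    ex$end[k] - 1L - (pos - cum[i])
  }
}
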