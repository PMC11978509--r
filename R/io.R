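# Alignment and sequence I/O: transcriptome BAM / tabular TSV readers and
# result writers.

#' Read a transcript sequence catalogue (FASTA)
#'
#' Sequence ids must match the annotation's transcript ids; version-suffix
#' handling is explicit, never silent.
#'
#' @param path FASTA path.
#' @param strip_versions Drop trailing `.N` suffixes from sequence ids.
#' @return A named `Biostrings::DNAStringSet`.
#' @export
read_transcript_fasta <- function(path, strip_versions = FALSE) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))      # keep first token of header
  if (strip_versions) names(x) <- strip_id_versions(names(x))
  if (anyDuplicated(names(x))) stop("duplicate sequence ids in ", path)
  x
}

#' Read transcriptome-space alignments from BAM or TSV
#'
#' BAM input (transcriptome reference) keeps primary alignments only
#' (secondary/supplementary and unmapped records are skipped); the aligned
#' interval is the reference span of the record, so deletions are part of
#' the span. TSV input must have columns `read_id`, `transcript_id`,
#' `start`, `end` (0-based half-open).
#'
#' @param path `.bam` or `.tsv` file.
#' @return data.table(read_id, transcript_id, start, end).
#' @export
read_alignments <- function(path) {
  if (grepl("\\.bam$", path, ignore.case = TRUE)) {
    if (!requireNamespace("Rsamtools", quietly = TRUE) ||
        !requireNamespace("GenomicAlignments", quietly = TRUE))
      stop("Rsamtools and GenomicAlignments are required for BAM input")
    flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                   isSecondaryAlignment = FALSE,
                                   isSupplementaryAlignment = FALSE)
    p <- Rsamtools::ScanBamParam(flag = flag,
                                 what = c("qname", "rname", "pos", "cigar"))
    b <- Rsamtools::scanBam(path, param = p)[[1L]]
    width <- GenomicAlignments::cigarWidthAlongReferenceSpace(b$cigar)
    data.table(read_id = b$qname,
               transcript_id = as.character(b$rname),
               start = b$pos - 1L,
               end = b$pos - 1L + width)
  } else {
    rd <- fread(path)
    req <- c("read_id", "transcript_id", "start", "end")
    if (!all(req %in% names(rd)))
      stop("alignment TSV needs columns: ", paste(req, collapse = ", "))
    rd[, .(read_id = as.character(read_id),
           transcript_id = as.character(transcript_id),
           start = as.integer(start), end = as.integer(end))]
  }
}

#' Write alignments as tabular TSV
#'
#' @param reads data.table(read_id, transcript_id, start, end).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignments <- function(reads, path) {
  fwrite(as.data.table(reads)[, .(read_id, transcript_id, start, end)],
         path, sep = "\t")
  invisible(path)
}

#' Write classification results as TSV
#'
#' One row per read: `read_id`, `label`, `n_junctions`, `n_compatible`,
#' `transcript_ids` (comma-separated compatible set).
#'
#' @param classified Output of [classify_reads()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_classification_tsv <- function(classified, path) {
  cl <- as.data.table(classified)
  out <- cl[, .(read_id, label, n_junctions, n_compatible,
                transcript_ids = vapply(compatible, paste, character(1L),
                                        collapse = ","))]
  fwrite(out, path, sep = "\t")
  invisible(path)
}
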