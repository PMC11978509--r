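# Major-isoform identification and cross-technology concordance.

#' Major isoform per gene
#'
#' The major isoform of a gene is the transcript with the highest mean
#' expression across the technology's replicates; ties are broken by the
#' lexicographically smallest transcript id. Genes with all-zero expression
#' have no major isoform and are excluded (counted in the `n_excluded`
#' attribute).
#'
#' @param mat Numeric matrix, transcripts x replicate samples, rownames =
#'   transcript ids.
#' @param annotation A [tx_annotation()].
#' @return data.table(gene_id, major_tx, mean_expr), one row per expressed
#'   gene.
#' @export
major_isoforms <- function(mat, annotation) {
  mat <- as.matrix(mat)
  tx <- annotation$transcripts
  g <- tx[J(rownames(mat)), gene_id]
  if (anyNA(g)) stop("transcript(s) not in annotation")
  dt <- data.table(transcript_id = rownames(mat), gene_id = g,
                   m = rowMeans(mat))
  expressed <- dt[, .(tot = sum(m)), by = gene_id]
  excl <- expressed[tot <= 0, gene_id]
  out <- dt[!gene_id %in% excl][order(-m, transcript_id),
                                .(major_tx = transcript_id[1L],
                                  mean_expr = m[1L]), by = gene_id]
  setorder(out, gene_id)
  setattr(out, "n_excluded", length(excl))
  out[]
}

#' Four-way major-isoform categorisation
#'
#' Compares long-read and short-read major isoforms per gene and labels each
#' transcript of the shared gene universe: `major_shared` (the same major in
#' both technologies), `major_LR_specific` / `major_SR_specific` (the major
#' in one technology only), or `minor` (never the most highly expressed).
#'
#' @param lr_majors,sr_majors Outputs of [major_isoforms()] on the long-read
#'   and short-read matrices. Gene universes must agree (genes quantified by
#'   only one technology should be dropped by the caller's expression gate
#'   first; a mismatch is an error).
#' @param annotation A [tx_annotation()].
#' @return list(genes = data.table(gene_id, lr_major, sr_major, agree),
#'   transcripts = data.table(transcript_id, gene_id, category)).
#' @export
categorize_isoforms <- function(lr_majors, sr_majors, annotation) {
  lr <- as.data.table(lr_majors)
  sr <- as.data.table(sr_majors)
  if (!setequal(lr$gene_id, sr$gene_id))
    stop("mismatched gene universes between technologies")
  genes <- merge(lr[, .(gene_id, lr_major = major_tx)],
                 sr[, .(gene_id, sr_major = major_tx)], by = "gene_id")
  genes[, agree := lr_major == sr_major]
  tx <- annotation$transcripts[gene_id %in% genes$gene_id,
                               .(transcript_id, gene_id)]
  tx <- genes[tx, on = "gene_id"]
  tx[, category := fifelse(
    transcript_id == lr_major & agree, "major_shared",
    fifelse(transcript_id == lr_major, "major_LR_specific",
            fifelse(transcript_id == sr_major, "major_SR_specific",
                    "minor")))]
  list(genes = genes[],
       transcripts = tx[, .(transcript_id, gene_id, category)])
}

#' Major-isoform concordance counts
#'
#' @param categorized Output of [categorize_isoforms()].
#' @return c(n_agree, n_disagree) over genes.
#' @export
concordance <- function(categorized) {
  g <- categorized$genes
  c(n_agree = sum(g$agree), n_disagree = sum(!g$agree))
}

#' Per-category agreement between two expression matrices
#'
#' Computes a statistic within each major-isoform category separately, per
#' sample pair (column i of `a` against column i of `b`). Matrices are
#' expected on the log2 scale and on a shared transcript set. Categories
#' with fewer than 3 transcripts yield NA.
#'
#' @param a,b Numeric matrices with identical rownames (transcripts) and the
#'   same number of columns.
#' @param categorized Output of [categorize_isoforms()].
#' @param metric `"spearman"` or `"mae"`.
#' @return data.table(category, sample_pair, value).
#' @export
category_agreement <- function(a, b, categorized,
                               metric = c("spearman", "mae")) {
  metric <- match.arg(metric)
  a <- as.matrix(a); b <- as.matrix(b)
  if (!identical(rownames(a), rownames(b)) || ncol(a) != ncol(b))
    stop("matrices must share transcripts and sample count")
  cats <- categorized$transcripts
  out <- list()
  for (cc in unique(cats$category)) {
    ids <- intersect(cats[category == cc, transcript_id], rownames(a))
    for (j in seq_len(ncol(a))) {
      v <- if (length(ids) < 3L) NA_real_
      else if (metric == "spearman")
        suppressWarnings(cor(a[ids, j], b[ids, j], method = "spearman"))
      else mean(abs(a[ids, j] - b[ids, j]))
      out[[length(out) + 1L]] <- data.table(category = cc, sample_pair = j,
                                            value = v)
    }
  }
  rbindlist(out)
}

#' Fraction of category members expressed above a CPM threshold
#'
#' @param cpm_mat CPM matrix (transcripts x samples); a transcript counts as
#'   expressed when its mean CPM reaches the threshold.
#' @param categorized Output of [categorize_isoforms()].
#' @param threshold Expression gate in CPM (default 1).
#' @return data.table(category, n, fraction_expressed).
#' @export
expressed_fraction <- function(cpm_mat, categorized, threshold = 1) {
  m <- rowMeans(as.matrix(cpm_mat))
  cats <- categorized$transcripts
  cats[, .(n = .N,
           fraction_expressed = mean(m[transcript_id] >= threshold)),
       by = category]
}
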