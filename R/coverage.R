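# Coverage profiles, transcript-diversity curves, and the length-adjusted
# gene-coverage ratio with its two-sided z-test.

#' Per-base coverage of one transcript
#'
#' Depth along the transcript from transcriptome-space alignments; aligned
#' intervals are treated as fully covered (deletions inside a read count as
#' covered, matching CIGAR `D` inclusion).
#'
#' @param reads data.frame of alignments to one transcript: columns `start`,
#'   `end` (0-based half-open transcript coordinates).
#' @param transcript_length Length of the transcript in bases.
#' @return Integer vector of depth, length `transcript_length`.
#' @export
transcript_coverage <- function(reads, transcript_length) {
  rd <- as.data.table(reads)
  if (nrow(rd) == 0L) return(integer(transcript_length))
  cov <- IRanges::coverage(IRanges::IRanges(start = rd$start + 1L,
                                            end = rd$end),
                           width = transcript_length)
  as.integer(cov)
}

#' 100-bin normalised coverage profile
#'
#' The transcript is divided into 100 equal bins (bin i covers positions
#' `[floor((i-1)L/100), floor(iL/100))`), the mean depth is taken per bin
#' and divided by the maximum bin mean. Transcripts shorter than 100 bases
#' or with zero coverage are undefined (returns NULL).
#'
#' @param depth Integer/numeric per-base depth vector (5' to 3').
#' @return Numeric vector of 100 values in [0,1] with max 1, or NULL when
#'   undefined.
#' @export
binned_profile <- function(depth) {
  L <- length(depth)
  if (L < 100L || sum(depth) == 0) return(NULL)
  edges <- (0:100) * L %/% 100L
  bin <- vapply(seq_len(100L), function(i)
    mean(depth[(edges[i] + 1L):edges[i + 1L]]), numeric(1L))
  bin / max(bin)
}

#' Average coverage profiles within groups
#'
#' Arithmetic per-bin mean of normalised profiles, grouped e.g. by sample
#' within protocol and cell line.
#'
#' @param profiles List of 100-bin profiles (NULL entries dropped).
#' @param groups Optional grouping factor of the same length; when given, a
#'   matrix with one mean curve per group is returned.
#' @return Numeric vector of 100 bin means, or a groups x 100 matrix.
#' @export
aggregate_profiles <- function(profiles, groups = NULL) {
  keep <- !vapply(profiles, is.null, logical(1L))
  profiles <- profiles[keep]
  if (!length(profiles)) stop("no defined profiles")
  m <- do.call(rbind, profiles)
  if (is.null(groups)) return(colMeans(m))
  groups <- droplevels(factor(groups[keep]))
  rowsum(m, groups) / as.vector(table(groups))
}

#' Transcript-diversity cumulative curve
#'
#' Genes are ranked (by expression, descending, or by gene length,
#' ascending) and the cumulative read fraction is computed per rank. Tied
#' ranking keys are linearly interpolated across the tied rank span, since
#' the ordering within a tie is arbitrary.
#'
#' @param counts Named per-gene read counts (>= 0, total > 0).
#' @param ranking `"expression_desc"` or `"length_asc"`.
#' @param lengths Named gene lengths, required for `"length_asc"`.
#' @return data.table(rank, gene_id, cumulative_fraction), non-decreasing
#'   with final value 1.
#' @export
diversity_curve <- function(counts, ranking = c("expression_desc",
                                                "length_asc"),
                            lengths = NULL) {
  ranking <- match.arg(ranking)
  if (all(counts == 0)) stop("all-zero counts")
  if (any(counts < 0)) stop("negative counts")
  dt <- data.table(gene_id = names(counts), count = as.numeric(counts))
  if (ranking == "expression_desc") {
    dt[, key_ := -count]
  } else {
    if (is.null(lengths)) stop("lengths required for length ranking")
    dt[, key_ := as.numeric(lengths[gene_id])]
  }
  setorder(dt, key_, gene_id)
  dt[, cumulative_fraction := cumsum(count) / sum(count)]
  dt[, rank := .I]
  # linear interpolation across tied ranking keys
  rle_key <- rle(dt$key_)
  ends <- cumsum(rle_key$lengths)
  starts <- ends - rle_key$lengths + 1L
  cf <- dt$cumulative_fraction
  for (b in seq_along(ends)) {
    if (rle_key$lengths[b] > 1L) {
      lo <- if (starts[b] == 1L) 0 else cf[starts[b] - 1L]
      hi <- cf[ends[b]]
      cf[starts[b]:ends[b]] <- lo + (hi - lo) *
        seq_len(rle_key$lengths[b]) / rle_key$lengths[b]
    }
  }
  dt[, cumulative_fraction := cf]
  dt[, .(rank, gene_id, cumulative_fraction)]
}

#' Median diversity curve across samples
#'
#' @param curves List of [diversity_curve()] outputs over the same gene
#'   universe.
#' @return data.table(rank, cumulative_fraction) with the per-rank median.
#' @export
median_diversity_curve <- function(curves) {
  m <- vapply(curves, function(x) x$cumulative_fraction,
              numeric(nrow(curves[[1L]])))
  data.table(rank = curves[[1L]]$rank,
             cumulative_fraction = apply(as.matrix(m), 1L, median))
}

#' Cumulative read fraction captured by the top k genes
#'
#' @param curve A [diversity_curve()] result.
#' @param k Rank cutoff (default 1000).
#' @return The cumulative fraction at rank `min(k, G)`.
#' @export
top_k_fraction <- function(curve, k = 1000L) {
  curve$cumulative_fraction[min(k, nrow(curve))]
}

#' Length-adjusted gene-coverage ratio
#'
#' For each gene, the ratio of the length-adjusted total read count to the
#' raw total: `sum(count_c * width_c / L_max) / sum(count_c)` over its read
#' classes, where `L_max` is the gene length (maximum isoform length) and
#' `width` the exonic span of the class. Equals 1 exactly when every class
#' spans the longest isoform.
#'
#' @param classes Output of [build_read_classes()] (classes with NA gene
#'   are skipped).
#' @param annotation A [tx_annotation()].
#' @param min_cpm Genes below this mean CPM (computed from class counts) are
#'   excluded; default 30.
#' @return data.table(gene_id, ratio, n_reads).
#' @export
gene_coverage_ratio <- function(classes, annotation, min_cpm = 30) {
  cl <- as.data.table(classes)[!is.na(gene_id)]
  if (nrow(cl) == 0L) stop("no gene-assignable classes")
  total <- sum(cl$count)
  gl <- setNames(annotation$genes$gene_length, annotation$genes$gene_id)
  out <- cl[, .(ratio = sum(count * pmin(1, width / gl[.BY[[1L]]])) /
                  sum(count),
                n_reads = sum(count)), by = gene_id]
  out[, cpm := n_reads / total * 1e6]
  out <- out[cpm >= min_cpm][, cpm := NULL]
  setorder(out, gene_id)
  out[]
}

#' Two-sided z-test on two coverage ratios
#'
#' Treats each ratio as a proportion with variance `r(1-r)/n` (unequal
#' variances, unpooled): `z = (r1 - r2) / sqrt(r1(1-r1)/n1 + r2(1-r2)/n2)`,
#' with the p-value from the standard normal. Degenerate variance on both
#' sides (both ratios 0 or 1) yields NA.
#'
#' @param r1,r2 Ratios in [0,1].
#' @param n1,n2 Total gene read counts per protocol (> 0).
#' @return list(z, p).
#' @export
ratio_ztest <- function(r1, n1, r2, n2) {
  if (n1 <= 0 || n2 <= 0) stop("n must be positive")
  v <- r1 * (1 - r1) / n1 + r2 * (1 - r2) / n2
  if (v == 0) {
    if (r1 == r2) return(list(z = 0, p = 1))
    return(list(z = NA_real_, p = NA_real_))
  }
  z <- (r1 - r2) / sqrt(v)
  list(z = z, p = 2 * pnorm(-abs(z)))
}

#' Per-gene coverage-ratio comparison between two protocols
#'
#' @param ratios1,ratios2 Outputs of [gene_coverage_ratio()] for the two
#'   protocols; only shared genes are tested.
#' @return data.table(gene_id, ratio1, ratio2, n1, n2, z, p, p_bonferroni).
#' @export
compare_coverage_ratios <- function(ratios1, ratios2) {
  m <- merge(as.data.table(ratios1), as.data.table(ratios2), by = "gene_id",
             suffixes = c("1", "2"))
  if (nrow(m) == 0L) stop("no shared genes")
  zp <- mapply(function(r1, n1, r2, n2) unlist(ratio_ztest(r1, n1, r2, n2)),
               m$ratio1, m$n_reads1, m$ratio2, m$n_reads2)
  m[, `:=`(z = zp[1L, ], p = zp[2L, ])]
  m[, p_bonferroni := pmin(1, p * .N)]
  setnames(m, c("n_reads1", "n_reads2"), c("n1", "n2"))
  m[]
}

utils::globalVariables(c("m", "tot", "lr_major", "sr_major", "agree",
                         "cumulative_fraction", "ratio", "n_reads", "p",
                         "p_bonferroni", "ratio1", "ratio2", "z"))
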