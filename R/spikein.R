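# Spike-in expected CPM and the quantification metric suite.

#' Expected CPM of spike-in transcripts
#'
#' Expected reads per spike transcript are the total library reads times the
#' spike-in fraction times the transcript's relative concentration; on the
#' CPM scale the library size cancels: `expected CPM = fraction * rel * 1e6`.
#'
#' @param mix data.frame with columns `transcript_id` and `concentration`
#'   (relative fractions summing to 1 within 1e-9).
#' @param spike_fraction Spike-in fraction of the library, in (0, 1].
#' @param total_reads Total library reads (> 0); only used for the expected
#'   read counts.
#' @return data.table(transcript_id, expected_reads, expected_cpm).
#' @export
expected_cpm <- function(mix, spike_fraction, total_reads) {
  mx <- as.data.table(mix)
  if (abs(sum(mx$concentration) - 1) > 1e-9)
    stop("relative concentrations must sum to 1")
  if (total_reads <= 0) stop("zero total reads")
  if (spike_fraction <= 0 || spike_fraction > 1)
    stop("spike_fraction must be in (0,1]")
  mx[, .(transcript_id,
         expected_reads = total_reads * spike_fraction * concentration,
         expected_cpm = spike_fraction * concentration * 1e6)]
}

#' Quantification accuracy metrics
#'
#' Computes, on paired (typically log2-scale) vectors of estimated vs
#' expected abundance: Spearman correlation, mean absolute error, mean
#' relative absolute difference, mean relative difference, root mean squared
#' error and the R-squared value (squared Pearson correlation). Relative
#' metrics divide by the expected value by default
#' (`rel_denominator = "expected"`); `"mean"` uses the pair mean instead.
#' Relative metrics are NA when any denominator is zero.
#'
#' @param estimated,expected Paired numeric vectors, length >= 3.
#' @param rel_denominator `"expected"` or `"mean"`.
#' @return list(spearman, mae, mrad, mrd, rmse, r_squared).
#' @export
quant_metrics <- function(estimated, expected,
                          rel_denominator = c("expected", "mean")) {
  rel_denominator <- match.arg(rel_denominator)
  if (length(estimated) != length(expected)) stop("length mismatch")
  if (length(estimated) < 3L) stop("need at least 3 pairs")
  d <- estimated - expected
  den <- if (rel_denominator == "expected") expected
  else (estimated + expected) / 2
  rel_ok <- all(den != 0)
  list(
    spearman = suppressWarnings(cor(estimated, expected,
                                    method = "spearman")),
    mae = mean(abs(d)),
    mrad = if (rel_ok) mean(abs(d) / abs(den)) else NA_real_,
    mrd = if (rel_ok) mean(d / den) else NA_real_,
    rmse = sqrt(mean(d^2)),
    r_squared = suppressWarnings(cor(estimated, expected))^2)
}

#' Metric table across protocols and spike-in mixes
#'
#' Evaluates each protocol's estimates against the expected log2 CPM of
#' each mix, at transcript level and at gene level (transcript CPM summed
#' by the mix's gene grouping).
#'
#' @param estimates Named list (by protocol) of named estimated-CPM vectors
#'   over spike-in transcripts.
#' @param mixes Named list (by mix) of mix sheets (columns `transcript_id`,
#'   `gene_id`, `concentration`).
#' @param spike_fraction Spike-in fraction used for the expected CPM.
#' @param pseudocount log2 pseudocount (default 1).
#' @return Long data.table: protocol, mix, level (gene/transcript), and the
#'   metric columns of [quant_metrics()].
#' @export
protocol_comparison <- function(estimates, mixes, spike_fraction,
                                pseudocount = 1) {
  if (is.null(names(estimates)) || is.null(names(mixes)))
    stop("estimates and mixes must be named lists")
  out <- list()
  for (pn in names(estimates)) {
    est <- estimates[[pn]]
    for (mn in names(mixes)) {
      mx <- as.data.table(mixes[[mn]])
      if (is.null(mx) || nrow(mx) == 0L) stop("missing mix sheet: ", mn)
      exp_tx <- expected_cpm(mx, spike_fraction, 1e6)
      for (level in c("transcript", "gene")) {
        if (level == "transcript") {
          e <- est[exp_tx$transcript_id]
          x <- exp_tx$expected_cpm
        } else {
          g <- mx$gene_id
          e <- as.vector(rowsum(est[mx$transcript_id], g))
          x <- as.vector(rowsum(exp_tx$expected_cpm, g))
        }
        e[is.na(e)] <- 0
        mt <- if (length(e) < 3L)
          list(spearman = NA_real_, mae = NA_real_, mrad = NA_real_,
               mrd = NA_real_, rmse = NA_real_, r_squared = NA_real_)
        else quant_metrics(log2_transform(e, pseudocount),
                           log2_transform(x, pseudocount))
        out[[length(out) + 1L]] <- data.table(
          protocol = pn, mix = mn, level = level, as.data.table(mt))
      }
    }
  }
  rbindlist(out)
}

#' Read / write a spike-in concentration sheet
#'
#' CSV with columns `transcript_id`, `gene_id`, `concentration`, `mix`.
#'
#' @param path CSV path.
#' @return data.table of the sheet.
#' @export
read_mix_sheet <- function(path) {
  sheet <- fread(path)
  req <- c("transcript_id", "concentration")
  if (!all(req %in% names(sheet)))
    stop("mix sheet needs columns: ", paste(req, collapse = ", "))
  sheet
}

#' @rdname read_mix_sheet
#' @param sheet The sheet to write.
#' @export
write_mix_sheet <- function(sheet, path) {
  fwrite(as.data.table(sheet), path)
  invisible(path)
}
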