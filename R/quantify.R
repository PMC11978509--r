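# Minimal transcript quantifier: unique counting plus EM over ambiguous
# read classes. The E-step splits each class's count across its compatible
# transcripts in proportion to the current count estimate, optionally divided
# by effective length (fragment mode, where class membership probability per
# molecule scales with the number of fragment start positions).

#' EM transcript quantification over read classes
#'
#' Expectation-maximisation on the class-compatibility structure. Classes
#' with a single compatible transcript pin that transcript's unique count;
#' ambiguous classes are split proportionally to the current estimates
#' (`weights = "count"`, long-read mode) or to estimates divided by
#' effective length (`weights = "molar"`, fragment mode; effective length =
#' transcript length − fragment length + 1, floored at 1). Initialisation is
#' uniform and deterministic; convergence when the relative L1 change drops
#' below `tol`.
#'
#' @param classes Output of [build_read_classes()]; unassigned classes (empty
#'   compatibility) are excluded and counted.
#' @param annotation A [tx_annotation()] providing the transcript universe
#'   and lengths.
#' @param weights `"count"` or `"molar"`.
#' @param fragment_length Fragment length used for effective lengths in
#'   molar mode.
#' @param max_iter,tol Convergence controls.
#' @return data.table `transcript_id`, `est_count` (summing to the assigned
#'   read total), `cpm`, and in molar mode `tpm` (length-normalised).
#'   Attributes: `converged`, `iterations`, `loglik` (per-iteration
#'   log-likelihood trace), `n_excluded` (classes without compatibility).
#' @export
em_quantify <- function(classes, annotation, weights = c("count", "molar"),
                        fragment_length = 150L, max_iter = 1000L,
                        tol = 1e-8) {
  weights <- match.arg(weights)
  tx <- annotation$transcripts
  cl <- as.data.table(classes)
  excl <- lengths(cl$compatible) == 0L
  n_excl <- sum(excl)
  cl <- cl[!excl]
  out <- data.table(transcript_id = tx$transcript_id, est_count = 0)
  if (nrow(cl) == 0L) {
    out[, cpm := 0]
    setattr(out, "converged", TRUE)
    setattr(out, "iterations", 0L)
    setattr(out, "loglik", numeric(0L))
    setattr(out, "n_excluded", n_excl)
    return(out[])
  }
  # long membership table
  mem <- cl[, .(transcript_id = compatible[[1L]]), by = .(class_id, count)]
  ids <- sort(unique(mem$transcript_id))
  ti <- match(mem$transcript_id, ids)
  ci <- match(mem$class_id, unique(mem$class_id))
  cls_count <- cl[match(unique(mem$class_id), class_id), count]
  n_cls <- length(cls_count)
  n_tx <- length(ids)
  efflen <- rep(1, n_tx)
  if (weights == "molar") {
    L <- tx[J(ids), length]
    efflen <- pmax(1, L - fragment_length + 1)
  }
  inv_el <- 1 / efflen

  a <- rep(sum(cls_count) / n_tx, n_tx)
  loglik <- numeric(0L)
  converged <- FALSE
  iter <- 0L
  total <- sum(cls_count)
  for (iter in seq_len(max_iter)) {
    w <- (a * inv_el)[ti]
    denom <- rowsum_fast(w, ci, n_cls)
    # log-likelihood of the multinomial class model at current estimates
    theta_cls <- rowsum_fast((a / total)[ti], ci, n_cls)
    loglik <- c(loglik, sum(cls_count * log(pmax(theta_cls, 1e-300))))
    share <- w / denom[ci]
    a_new <- rowsum_fast(share * cls_count[ci], ti, n_tx)
    delta <- sum(abs(a_new - a)) / total
    a <- a_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("EM did not converge in ", max_iter, " iterations")
  est <- setNames(a, ids)
  out[, est_count := fifelse(is.na(est[transcript_id]), 0,
                             est[transcript_id])]
  out[is.na(est_count), est_count := 0]
  out[, cpm := compute_cpm(est_count)]
  if (weights == "molar") {
    L <- tx[J(out$transcript_id), length]
    el <- pmax(1, L - fragment_length + 1)
    molar <- out$est_count / el
    out[, tpm := molar / sum(molar) * 1e6]
  }
  setattr(out, "converged", converged)
  setattr(out, "iterations", iter)
  setattr(out, "loglik", loglik)
  setattr(out, "n_excluded", n_excl)
  out[]
}

rowsum_fast <- function(x, g, n) {
  out <- numeric(n)
  s <- rowsum(x, g)
  out[as.integer(rownames(s))] <- s[, 1L]
  out
}

#' Counts per million
#'
#' @param counts Non-negative numeric vector (one sample).
#' @return `counts / sum(counts) * 1e6`.
#' @export
compute_cpm <- function(counts) {
  if (any(counts < 0)) stop("negative counts")
  total <- sum(counts)
  if (total <= 0) stop("zero total count")
  counts / total * 1e6
}

#' Transcripts per million
#'
#' Length-normalised abundance: counts are divided by effective length
#' before rescaling to one million.
#'
#' @param counts Non-negative numeric vector.
#' @param effective_length Positive lengths, same order as `counts`.
#' @return TPM vector summing to 1e6.
#' @export
compute_tpm <- function(counts, effective_length) {
  if (any(counts < 0)) stop("negative counts")
  if (any(effective_length <= 0)) stop("non-positive effective length")
  molar <- counts / effective_length
  if (sum(molar) <= 0) stop("zero total")
  molar / sum(molar) * 1e6
}

#' Aggregate a transcript matrix to gene level
#'
#' Gene expression is the sum of the expression of all its transcripts,
#' per sample.
#'
#' @param mat Numeric matrix, transcripts x samples, with transcript ids as
#'   rownames.
#' @param annotation A [tx_annotation()]; every transcript must resolve to a
#'   gene.
#' @return Numeric matrix, genes x samples.
#' @export
gene_expression <- function(mat, annotation) {
  mat <- as.matrix(mat)
  tx <- annotation$transcripts
  g <- tx[J(rownames(mat)), gene_id]
  if (anyNA(g)) stop("transcript(s) without a gene in the annotation")
  out <- rowsum(mat, g)
  out[order(rownames(out)), , drop = FALSE]
}

#' Log2 transform with pseudocount
#'
#' @param x Non-negative numeric vector or matrix.
#' @param pseudocount Added before taking log2 (default 1, so 0 maps to 0).
#' @return `log2(x + pseudocount)`.
#' @export
log2_transform <- function(x, pseudocount = 1) {
  if (any(x < 0)) stop("negative values")
  log2(x + pseudocount)
}
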