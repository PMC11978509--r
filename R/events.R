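# Pairwise structural comparison of transcripts: the splicing-event
# vocabulary, a 20-repeat simulated background null, and Bonferroni-corrected
# two-proportion z-tests.
#
# Event definitions (strand-aware; "first"/"last" in transcript orientation,
# decidable from exon coordinates and junction chains alone):
#  - internal_first/last_exon: the query's terminal exon shares its inner
#    junction boundary with a non-terminal exon of the subject.
#  - alternative_first/last_exon: the terminal exons do not overlap and
#    neither transcript's terminal exon matches an internal exon of the
#    other (that case is the internal-exon event above).
#  - exon_skipping: a subject internal exon lies inside a query intron whose
#    donor and acceptor both match subject junction boundaries.
#  - intron_retention: a query exon fully spans a subject junction plus at
#    least one base of each flanking exon.
#  - alt_5prime/alt_3prime_splice: a query junction absent from the subject
#    shares exactly one boundary with a subject junction; the named side is
#    the shifted one, mirrored on the minus strand.

.event_names <- c("internal_first_exon", "internal_last_exon",
                  "alternative_first_exon", "alternative_last_exon",
                  "exon_skipping", "intron_retention",
                  "alt_5prime_splice", "alt_3prime_splice")

#' Structural events between two isoforms of one gene
#'
#' @param annotation A [tx_annotation()].
#' @param query,subject Transcript ids of the same gene.
#' @return Named integer vector of event counts (all zero when the
#'   transcripts are identical in structure). Symmetric events (skipping,
#'   retention) are reported from the query's perspective: `exon_skipping`
#'   counts subject exons skipped by the query.
#' @export
compare_transcripts <- function(annotation, query, subject) {
  tx <- annotation$transcripts
  qi <- tx[J(query)]; si <- tx[J(subject)]
  if (anyNA(qi$gene_id) || anyNA(si$gene_id)) stop("unknown transcript id")
  if (qi$gene_id != si$gene_id)
    stop("transcripts belong to different genes")
  ev <- setNames(integer(length(.event_names)), .event_names)
  qe <- annotation$exons[J(query)][order(start)]
  se <- annotation$exons[J(subject)][order(start)]
  if (nrow(qe) == nrow(se) && all(qe$start == se$start) &&
      all(qe$end == se$end)) return(ev)
  strand <- qi$strand
  nq <- nrow(qe); ns <- nrow(se)

  term <- function(e, which) {
    # which = "first"/"last" in transcript orientation
    gfirst <- (which == "first") == (strand == "+")
    if (gfirst) e[1L] else e[nrow(e)]
  }
  inner_boundary <- function(e, which) {
    # junction-side boundary of a terminal exon; NA for single-exon
    if (nrow(e) == 1L) return(NA_integer_)
    gfirst <- (which == "first") == (strand == "+")
    if (gfirst) e$end[1L] else e$start[nrow(e)]
  }
  internal_match <- function(e_query, e_subject, which) {
    # query terminal exon's inner boundary hits a non-terminal subject exon
    if (nrow(e_subject) < 3L || nrow(e_query) < 2L) return(FALSE)
    b <- inner_boundary(e_query, which)
    mid <- e_subject[2:(nrow(e_subject) - 1L)]
    gfirst <- (which == "first") == (strand == "+")
    if (gfirst) any(mid$end == b) else any(mid$start == b)
  }
  overlaps <- function(a, b) a$start < b$end && b$start < a$end

  for (which in c("first", "last")) {
    key_int <- if (which == "first") "internal_first_exon" else
      "internal_last_exon"
    key_alt <- if (which == "first") "alternative_first_exon" else
      "alternative_last_exon"
    int_q <- internal_match(qe, se, which)
    int_s <- internal_match(se, qe, which)
    if (int_q) ev[key_int] <- 1L
    else if (!overlaps(term(qe, which), term(se, which)) && !int_s)
      ev[key_alt] <- 1L
  }

  qj <- if (nq > 1L) data.table(d = qe$end[-nq], a = qe$start[-1L]) else
    data.table(d = integer(), a = integer())
  sj <- if (ns > 1L) data.table(d = se$end[-ns], a = se$start[-1L]) else
    data.table(d = integer(), a = integer())

  # exon skipping: subject internal exon inside a query intron with matched
  # boundaries
  if (nrow(qj) && ns >= 3L) {
    mid <- se[2:(ns - 1L)]
    for (i in seq_len(nrow(qj))) {
      if (qj$d[i] %in% sj$d && qj$a[i] %in% sj$a &&
          !any(sj$d == qj$d[i] & sj$a == qj$a[i])) {
        ev["exon_skipping"] <- ev["exon_skipping"] +
          sum(mid$start >= qj$d[i] & mid$end <= qj$a[i])
      }
    }
  }
  # intron retention: query exon spans a subject junction + flanking bases
  if (nrow(sj)) {
    for (i in seq_len(nrow(sj))) {
      if (any(qe$start < sj$d[i] & qe$end > sj$a[i]))
        ev["intron_retention"] <- ev["intron_retention"] + 1L
    }
  }
  # alternative 5'/3' splice sites
  if (nrow(qj) && nrow(sj)) {
    for (i in seq_len(nrow(qj))) {
      if (any(sj$d == qj$d[i] & sj$a == qj$a[i])) next
      share_d <- any(sj$d == qj$d[i] & sj$a != qj$a[i])
      share_a <- any(sj$a == qj$a[i] & sj$d != qj$d[i])
      # exactly one shared boundary: both shared is a skipping-type junction,
      # handled above. Shifted side: genomic-right boundary when donors
      # match, genomic-left when acceptors match; right = 3' on plus strand,
      # 5' on minus
      if (share_d && !share_a) {
        key <- if (strand == "+") "alt_3prime_splice" else "alt_5prime_splice"
        ev[key] <- ev[key] + 1L
      }
      if (share_a && !share_d) {
        key <- if (strand == "+") "alt_5prime_splice" else "alt_3prime_splice"
        ev[key] <- ev[key] + 1L
      }
    }
  }
  ev
}

#' Observed event fractions over a set of isoform pairs
#'
#' @param annotation A [tx_annotation()].
#' @param pairs data.frame(gene_id, query, subject) of same-gene transcript
#'   pairs (e.g. LR-specific major vs SR-specific major per gene).
#' @return Named numeric vector: fraction of pairs showing each event at
#'   least once; attribute `n` = number of pairs.
#' @export
observed_event_fractions <- function(annotation, pairs) {
  pr <- as.data.table(pairs)
  if (nrow(pr) == 0L) stop("no pairs")
  flags <- vapply(seq_len(nrow(pr)), function(i)
    compare_transcripts(annotation, pr$query[i], pr$subject[i]) > 0L,
    logical(length(.event_names)))
  out <- rowMeans(flags)
  attr(out, "n") <- nrow(pr)
  out
}

#' Simulated background event distribution
#'
#' For each repetition, one isoform other than the target is drawn uniformly
#' per gene and compared against the target; the fraction of genes showing
#' each event is recorded, and the mean and s.d. over repetitions form the
#' background distribution. Genes with fewer than two annotated isoforms are
#' excluded and counted.
#'
#' @param annotation A [tx_annotation()].
#' @param targets data.frame(gene_id, target) giving the fixed comparison
#'   subject per gene (e.g. the SR-specific major isoform).
#' @param n_rep Number of repetitions (default 20).
#' @param seed Integer seed.
#' @return data.table(event, mean, sd, n_rep); attributes `n_genes` (used)
#'   and `n_excluded` (single-isoform genes).
#' @export
background_event_distribution <- function(annotation, targets, n_rep = 20L,
                                          seed) {
  if (missing(seed)) stop("seed is required")
  set.seed(seed)
  tg <- as.data.table(targets)
  tx <- annotation$transcripts
  alt <- lapply(seq_len(nrow(tg)), function(i)
    setdiff(tx[gene_id == tg$gene_id[i], transcript_id], tg$target[i]))
  usable <- lengths(alt) >= 1L
  n_excl <- sum(!usable)
  tg <- tg[usable]; alt <- alt[usable]
  if (nrow(tg) == 0L) stop("no genes with >= 2 isoforms")
  fracs <- matrix(NA_real_, n_rep, length(.event_names),
                  dimnames = list(NULL, .event_names))
  for (r in seq_len(n_rep)) {
    draws <- vapply(alt, function(a) a[sample.int(length(a), 1L)],
                    character(1L))
    flags <- vapply(seq_len(nrow(tg)), function(i)
      compare_transcripts(annotation, draws[i], tg$target[i]) > 0L,
      logical(length(.event_names)))
    fracs[r, ] <- rowMeans(flags)
  }
  out <- data.table(event = .event_names,
                    mean = colMeans(fracs),
                    sd = apply(fracs, 2L, sd),
                    n_rep = as.integer(n_rep))
  setattr(out, "n_genes", nrow(tg))
  setattr(out, "n_excluded", n_excl)
  out[]
}

#' Event enrichment z-test with Bonferroni correction
#'
#' Two-proportion z-test (unpooled variance) of an observed event fraction
#' against its simulated background fraction, Bonferroni-corrected over the
#' number of event categories tested.
#'
#' @param obs_frac,n_obs Observed fraction and number of pairs.
#' @param bg_frac,n_bg Background fraction and number of background pairs.
#' @param n_events Number of event categories tested (Bonferroni factor,
#'   default `length(.event_names)` = 8).
#' @return list(z, p, p_adjusted); NA when the variance is degenerate.
#' @export
event_enrichment_test <- function(obs_frac, n_obs, bg_frac, n_bg,
                                  n_events = length(.event_names)) {
  zt <- ratio_ztest(obs_frac, n_obs, bg_frac, n_bg)
  if (is.na(zt$z))
    return(list(z = NA_real_, p = NA_real_, p_adjusted = NA_real_))
  list(z = zt$z, p = zt$p, p_adjusted = min(1, zt$p * n_events))
}
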