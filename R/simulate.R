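# Seeded synthetic-data generator: annotations with subset-isoform gene
# families, log-normal/Dirichlet ground-truth expression, protocol-specific
# long reads (3'-anchored truncation, PCR concentration bias, short-transcript
# depletion), uniform short-read fragments, and spike-in mixes.
#
# Reads are emitted directly in transcriptome-space alignment form
# (read_id, transcript_id, start, end): the downstream analyses consume
# alignments, so no error model or aligner sits in the loop.

#' Simulation configuration
#'
#' Collects every tunable of the synthetic-data generator with defaults
#' representing a small but realistic transcriptome: ~40% multi-isoform
#' genes, exons of 100-300 bp, introns of 200-2,000 bp, log-normal gene
#' expression spanning ~3 orders of magnitude and moderately concentrated
#' isoform usage.
#'
#' @param n_genes Number of genes.
#' @param isoform_probs Probability vector over 1..K isoforms per gene.
#' @param exons_range Min/max scaffold exons per gene.
#' @param exon_length_range,intron_length_range Base ranges (uniform draws).
#' @param subset_isoform_fraction Probability that a multi-isoform gene
#'   carries a junction-subset isoform pair (one isoform's chain a strict
#'   consecutive sub-chain of another's, the internal-first-exon pattern).
#' @param subset_extension Bases by which the subset isoform's outer exon
#'   extends into the dropped intron.
#' @param gene_meanlog,gene_sdlog Log-normal parameters for gene expression.
#' @param usage_concentration Dirichlet concentration for isoform usage.
#' @param replicate_sdlog Log-normal replicate noise (0 = identical
#'   replicates).
#' @param n_reads Reads per simulated sample.
#' @param fragment_length Short-read fragment length.
#' @param seed Master seed (mandatory); per-stage streams are derived by
#'   fixed offsets.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 100L,
                       isoform_probs = c(0.6, 0.25, 0.15),
                       exons_range = c(3L, 8L),
                       exon_length_range = c(100L, 300L),
                       intron_length_range = c(200L, 2000L),
                       subset_isoform_fraction = 0.3,
                       subset_extension = 60L,
                       gene_meanlog = log(50),
                       gene_sdlog = 1.2,
                       usage_concentration = 1.5,
                       replicate_sdlog = 0.1,
                       n_reads = 20000L,
                       fragment_length = 150L,
                       seed = NULL) {
  if (is.null(seed)) stop("seed is mandatory")
  if (abs(sum(isoform_probs) - 1) > 1e-9) stop("isoform_probs must sum to 1")
  if (subset_isoform_fraction < 0 || subset_isoform_fraction > 1)
    stop("subset_isoform_fraction must be in [0,1]")
  if (exons_range[1L] < 1L || diff(exons_range) < 0) stop("bad exons_range")
  if (exon_length_range[1L] < 1L || intron_length_range[1L] < 1L)
    stop("infeasible length ranges")
  structure(as.list(environment()), class = "sim_config")
}

#' Protocol read-behaviour profiles
#'
#' Returns the per-protocol parameters used by [simulate_long_reads()]:
#' truncation probability with 3'-anchoring (direct-RNA-like degradation and
#' pore-release truncation), a PCR concentration-bias exponent (reads drawn
#' proportional to CPM^(1+eps)), and a logistic length weight suppressing
#' short transcripts (IsoSeq-like size selection, midpoint 1 kb).
#'
#' @param name One of `"dRNA-like"`, `"dcDNA-like"`, `"PCR-cDNA-like"`,
#'   `"IsoSeq-like"`.
#' @return list(name, p_truncation, three_prime_anchored, pcr_eps,
#'   length_midpoint, length_scale).
#' @export
protocol_profile <- function(name = c("dRNA-like", "dcDNA-like",
                                      "PCR-cDNA-like", "IsoSeq-like")) {
  name <- match.arg(name)
  switch(name,
    "dRNA-like" = list(name = name, p_truncation = 0.35,
                       three_prime_anchored = TRUE, pcr_eps = 0,
                       length_midpoint = NA_real_, length_scale = NA_real_),
    "dcDNA-like" = list(name = name, p_truncation = 0.25,
                        three_prime_anchored = TRUE, pcr_eps = 0,
                        length_midpoint = NA_real_, length_scale = NA_real_),
    "PCR-cDNA-like" = list(name = name, p_truncation = 0.2,
                           three_prime_anchored = TRUE, pcr_eps = 0.15,
                           length_midpoint = NA_real_,
                           length_scale = NA_real_),
    "IsoSeq-like" = list(name = name, p_truncation = 0.05,
                         three_prime_anchored = TRUE, pcr_eps = 0,
                         length_midpoint = 1000, length_scale = 200))
}

#' Generate a synthetic annotation and transcript sequences
#'
#' Genes are laid out non-overlapping on one synthetic chromosome. Each gene
#' has a scaffold of exons; isoform 1 uses all of them, and additional
#' isoforms are derived by dropping the outer exon (subset-isoform pair, with
#' a small extension of the new outer exon into the dropped intron), by
#' skipping an internal exon, or by shifting an internal donor site, always
#' keeping junction chains distinct within the gene. Strands are random;
#' sequences are random nucleotides extracted per exon (reverse-complemented
#' on the minus strand), so isoforms sharing exons share sequence.
#'
#' @param config A [sim_config()].
#' @return list(annotation = [tx_annotation()], sequences =
#'   `Biostrings::DNAStringSet` of transcript sequences, subset_genes =
#'   character vector of gene ids carrying a subset-isoform pair).
#' @export
generate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  n_iso_max <- length(config$isoform_probs)
  rows <- vector("list", config$n_genes)
  subset_genes <- character(0L)
  cursor <- 1000L
  for (g in seq_len(config$n_genes)) {
    gid <- sprintf("G%04d", g)
    n_iso <- sample.int(n_iso_max, 1L, prob = config$isoform_probs)
    n_ex <- sample(seq(config$exons_range[1L], config$exons_range[2L]), 1L)
    if (n_iso > 1L) n_ex <- max(n_ex, 3L)
    strand <- sample(c("+", "-"), 1L)
    ex_w <- sample(seq(config$exon_length_range[1L],
                       config$exon_length_range[2L]), n_ex, replace = TRUE)
    in_w <- sample(seq(config$intron_length_range[1L],
                       config$intron_length_range[2L]),
                   max(0L, n_ex - 1L), replace = TRUE)
    starts <- cursor + c(0L, cumsum(ex_w[-n_ex] + in_w))
    ends <- starts + ex_w
    iso <- list(seq_len(n_ex))                 # exon index sets, genomic order
    shift5 <- integer(1L)                      # extension of outer exon, per iso
    is_subset <- n_iso > 1L &&
      runif(1L) < config$subset_isoform_fraction && n_ex >= 3L
    if (is_subset) subset_genes <- c(subset_genes, gid)
    chains <- function(idx, s5) {
      if (length(idx) < 2L) return("")
      paste(ends[idx[-length(idx)]], starts[idx[-1L]], sep = "-",
            collapse = "|")
    }
    seen <- chains(iso[[1L]], 0L)
    k <- 1L
    guard <- 0L
    while (k < n_iso && guard < 50L) {
      guard <- guard + 1L
      cand <- NULL; c5 <- 0L
      if (is_subset && k == 1L) {
        # drop the genomic-first exon; extend the new outer exon 5'-ward
        cand <- 2:n_ex
        c5 <- min(config$subset_extension, in_w[1L] - 20L)
      } else {
        mode <- sample(c("skip", "shift"), 1L)
        if (mode == "skip" && n_ex >= 3L) {
          drop <- sample(2:(n_ex - 1L), 1L)
          cand <- setdiff(seq_len(n_ex), drop)
        } else {
          cand <- seq_len(n_ex)
          c5 <- -sample(10:40, 1L)   # negative = donor shift, handled below
        }
      }
      key <- if (c5 < 0L) paste0(chains(cand, 0L), "~", c5) else chains(cand, c5)
      key <- paste0(key, "@", c5)
      if (!key %in% seen) {
        seen <- c(seen, key)
        k <- k + 1L
        iso[[k]] <- cand
        shift5[k] <- c5
      }
    }
    n_iso <- length(iso)
    for (i in seq_len(n_iso)) {
      idx <- iso[[i]]
      s <- starts[idx]; e <- ends[idx]
      sh <- shift5[i]
      if (sh > 0L) s[1L] <- s[1L] - sh         # subset outer-exon extension
      if (sh < 0L) {                            # internal donor shift
        j <- max(1L, length(idx) %/% 2L)
        if (length(idx) >= 2L) e[j] <- e[j] + sh
      }
      rows[[length(rows) + 1L]] <- data.table(
        transcript_id = sprintf("%s.T%d", gid, i), gene_id = gid,
        chrom = "chrS", start = s, end = e, strand = strand,
        biotype = "protein_coding")
    }
    cursor <- max(ends) + sample(500:2000, 1L)
  }
  ex <- rbindlist(rows)
  ann <- tx_annotation(ex)
  # chromosome sequence and transcript extraction
  chrom_len <- max(ex$end) + 100L
  chrom_seq <- Biostrings::DNAString(paste(
    sample(c("A", "C", "G", "T"), chrom_len, replace = TRUE), collapse = ""))
  seqs <- extract_transcript_seqs(ann, chrom_seq)
  list(annotation = ann, sequences = seqs, subset_genes = subset_genes)
}

extract_transcript_seqs <- function(annotation, chrom_seq) {
  ex <- annotation$exons
  ids <- annotation$transcripts$transcript_id
  out <- Biostrings::DNAStringSet(vapply(ids, function(tid) {
    e <- ex[J(tid)]
    s <- paste(vapply(seq_len(nrow(e)), function(i)
      as.character(Biostrings::subseq(chrom_seq, e$start[i] + 1L, e$end[i])),
      character(1L)), collapse = "")
    if (e$strand[1L] == "-")
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    s
  }, character(1L)))
  names(out) <- ids
  out
}

#' Generate ground-truth expression
#'
#' Gene CPM is log-normal, isoform usage Dirichlet; per-sample replicate
#' noise is multiplicative log-normal; every sample is renormalised to one
#' million. The true major isoform per gene is the arg-max of the
#' noise-free transcript CPM.
#'
#' @param annotation A [tx_annotation()].
#' @param config A [sim_config()].
#' @param n_samples Number of replicate samples.
#' @return list(base_cpm = named noise-free transcript CPM, cpm = transcript
#'   x sample matrix (columns sum to 1e6), major = data.table(gene_id,
#'   major_tx), usage = named usage fractions).
#' @export
generate_expression <- function(annotation, config, n_samples = 2L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  tx <- annotation$transcripts
  gn <- annotation$genes
  gexp <- rlnorm(nrow(gn), config$gene_meanlog, config$gene_sdlog)
  names(gexp) <- gn$gene_id
  usage <- unlist(lapply(gn$gene_id, function(g) {
    k <- gn[J(g), n_tx]
    u <- rgamma(k, shape = config$usage_concentration, rate = 1)
    if (all(u == 0)) u <- rep(1, k)
    u <- u / sum(u)
    setNames(u, sort(tx[gene_id == g, transcript_id]))
  }))
  base <- gexp[tx[J(names(usage)), gene_id]] * usage
  base <- base / sum(base) * 1e6
  names(base) <- names(usage)
  base <- base[sort(names(base))]
  cpm <- vapply(seq_len(n_samples), function(s) {
    noisy <- base * rlnorm(length(base), 0, config$replicate_sdlog)
    noisy / sum(noisy) * 1e6
  }, numeric(length(base)))
  rownames(cpm) <- names(base)
  colnames(cpm) <- sprintf("S%d", seq_len(n_samples))
  major <- data.table(transcript_id = names(base), cpm = base,
                      gene_id = tx[J(names(base)), gene_id])
  major <- major[order(-cpm, transcript_id),
                 .(major_tx = transcript_id[1L]), by = gene_id]
  setorder(major, gene_id)
  list(base_cpm = base, cpm = cpm, major = major,
       usage = usage[sort(names(usage))])
}

#' Simulate long reads for one sample
#'
#' Transcripts are chosen multinomially proportional to CPM times the
#' protocol bias weight (CPM^(1+eps) for PCR-amplified libraries; a logistic
#' length weight for size-selected libraries). With the protocol's
#' truncation probability the read's 5' end is drawn uniformly inside the
#' transcript while the 3' end stays anchored at the transcript end;
#' otherwise the read is full-length.
#'
#' @param true_cpm Named transcript CPM vector for the sample.
#' @param annotation A [tx_annotation()].
#' @param profile A [protocol_profile()].
#' @param n_reads Number of reads (> 0).
#' @param seed Integer seed.
#' @return data.table(read_id, transcript_id, start, end) in transcript
#'   coordinates (0-based half-open; `end` = transcript length for
#'   3'-anchored or full-length reads).
#' @export
simulate_long_reads <- function(true_cpm, annotation, profile, n_reads,
                                seed) {
  if (n_reads <= 0L) stop("n_reads must be positive")
  set.seed(seed)
  tx <- annotation$transcripts
  ids <- names(true_cpm)
  len <- tx[J(ids), length]
  w <- true_cpm
  if (profile$pcr_eps > 0) w <- true_cpm^(1 + profile$pcr_eps)
  if (!is.na(profile$length_midpoint))
    w <- w / (1 + exp(-(len - profile$length_midpoint) / profile$length_scale))
  counts <- as.integer(rmultinom(1L, n_reads, w))
  tid <- rep(ids, counts)
  L <- rep(len, counts)
  trunc <- runif(length(tid)) < profile$p_truncation
  start <- integer(length(tid))
  end <- as.integer(L)
  # truncated: 5' start uniform in [0, L-1], 3' end fixed at transcript end
  start[trunc] <- as.integer(floor(runif(sum(trunc)) * (L[trunc] - 1L)))
  data.table(read_id = sprintf("LR%07d", seq_along(tid)),
             transcript_id = tid, start = start, end = end)
}

#' Simulate short-read fragments for one sample
#'
#' Transcripts shorter than the fragment length are excluded; selection is
#' multinomial proportional to CPM times the number of valid fragment start
#' positions (molar abundance times effective length, as in a uniform
#' fragmentation process), and the start is uniform over valid positions.
#'
#' @inheritParams simulate_long_reads
#' @param fragment_length Fragment length in bases.
#' @return data.table(read_id, transcript_id, start, end).
#' @export
simulate_short_reads <- function(true_cpm, annotation, fragment_length,
                                 n_reads, seed) {
  if (n_reads <= 0L) stop("n_reads must be positive")
  set.seed(seed)
  tx <- annotation$transcripts
  ids <- names(true_cpm)
  len <- tx[J(ids), length]
  ok <- len >= fragment_length
  eff <- pmax(0, len - fragment_length + 1)
  w <- true_cpm * eff * ok
  counts <- as.integer(rmultinom(1L, n_reads, w))
  tid <- rep(ids, counts)
  npos <- rep(eff, counts)
  start <- as.integer(floor(runif(length(tid)) * npos))
  data.table(read_id = sprintf("SR%07d", seq_along(tid)),
             transcript_id = tid, start = start,
             end = start + as.integer(fragment_length))
}

#' Generate a spike-in read population and concentration sheet
#'
#' @param mix data.frame with columns `transcript_id` and `concentration`
#'   (relative fractions summing to 1 within 1e-9), optionally `gene_id` and
#'   `mix` (mix name).
#' @param transcript_lengths Named lengths of the spike-in transcripts.
#' @param spike_fraction Fraction of the library that is spike-in.
#' @param n_total_reads Total library size.
#' @param seed Integer seed.
#' @return list(reads = data.table(read_id, transcript_id, start, end)
#'   full-length spike reads, sheet = the concentration sheet with expected
#'   read counts).
#' @export
generate_spikein <- function(mix, transcript_lengths, spike_fraction,
                             n_total_reads, seed) {
  mx <- as.data.table(mix)
  if (abs(sum(mx$concentration) - 1) > 1e-9)
    stop("relative concentrations must sum to 1")
  set.seed(seed)
  n_spike <- rbinom(1L, n_total_reads, spike_fraction)
  counts <- if (n_spike > 0L)
    as.integer(rmultinom(1L, n_spike, mx$concentration))
  else rep(0L, nrow(mx))
  tid <- rep(mx$transcript_id, counts)
  len <- transcript_lengths[tid]
  reads <- data.table(read_id = if (length(tid))
    sprintf("SP%07d", seq_along(tid)) else character(0L),
    transcript_id = tid, start = 0L, end = as.integer(len))
  sheet <- copy(mx)
  sheet[, expected_reads := n_total_reads * spike_fraction * concentration]
  list(reads = reads, sheet = sheet)
}

utils::globalVariables(c("pos", "cchain", "cstart", "cend", "exact", "fsm",
                         "compat_fsm", "compat_any", "first_token", "cand",
                         "tlen", "k", "g_lo", "g_hi", "row", "cse", "any_se",
                         "compat_se", "compat_me", "one", "all_present",
                         "hit", "concentration", "expected_reads", "major_tx",
                         "tpm"))
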