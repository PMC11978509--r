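# End-to-end orchestration of the synthetic protocol comparison:
# simulate -> classify -> quantify -> major isoforms -> coverage/diversity ->
# fragmentation experiment -> structural events -> spike-in evaluation.

#' Build and validate a pipeline run configuration
#'
#' Collects the stage parameters with the analysis defaults: a 30 CPM gate
#' for the gene-coverage comparison, a 1 CPM expressed gate, 150 bp
#' fragments, a 20-repeat background simulation and a top-1,000-gene
#' diversity summary. All randomness derives from `sim$seed` through fixed
#' per-stage offsets.
#'
#' @param sim A [sim_config()] (carries the mandatory seed).
#' @param lr_protocol Long-read protocol profile name (see
#'   [protocol_profile()]).
#' @param n_lr_reps,n_sr_reps Replicates per technology.
#' @param coverage_min_cpm Gene-coverage ratio expression gate (CPM).
#' @param expressed_cpm Expressed-transcript gate (CPM).
#' @param fragment_length In-silico fragment length (bases).
#' @param n_background_rep Background simulation repetitions.
#' @param top_k Diversity-curve rank cutoff.
#' @param spike_fraction Spike-in fraction of each library (0 disables the
#'   spike-in stage).
#' @param stages Character vector of optional stages to run; subset of
#'   `c("coverage", "diversity", "fragmentation", "events", "spikein")`.
#' @return A list of class `run_config`.
#' @export
run_config <- function(sim,
                       lr_protocol = "dcDNA-like",
                       n_lr_reps = 2L, n_sr_reps = 2L,
                       coverage_min_cpm = 30,
                       expressed_cpm = 1,
                       fragment_length = 150L,
                       n_background_rep = 20L,
                       top_k = 1000L,
                       spike_fraction = 0.02,
                       stages = c("coverage", "diversity", "fragmentation",
                                  "events", "spikein")) {
  cfg <- structure(as.list(environment()), class = "run_config")
  validate_config(cfg)
}

#' Validate a run configuration
#'
#' Checks required fields and value ranges; problems are reported all at
#' once.
#'
#' @param config A `run_config` (or plain list with the same fields).
#' @return The validated `run_config`, invisibly usable downstream.
#' @export
validate_config <- function(config) {
  problems <- character(0L)
  if (is.null(config$sim) || !inherits(config$sim, "sim_config"))
    problems <- c(problems, "sim must be a sim_config (with a seed)")
  else if (is.null(config$sim$seed))
    problems <- c(problems, "sim$seed is mandatory")
  for (f in c("n_lr_reps", "n_sr_reps", "fragment_length",
              "n_background_rep", "top_k"))
    if (is.null(config[[f]]) || config[[f]] < 1)
      problems <- c(problems, paste0(f, " must be >= 1"))
  if (!is.null(config$spike_fraction) &&
      (config$spike_fraction < 0 || config$spike_fraction >= 1))
    problems <- c(problems, "spike_fraction must be in [0,1)")
  unknown <- setdiff(config$stages,
                     c("coverage", "diversity", "fragmentation", "events",
                       "spikein"))
  if (length(unknown))
    problems <- c(problems, paste("unknown stage(s):",
                                  paste(unknown, collapse = ", ")))
  if (length(problems))
    stop("invalid configuration:\n  - ",
         paste(problems, collapse = "\n  - "))
  if (!inherits(config, "run_config")) class(config) <- "run_config"
  config
}

#' Run the full synthetic protocol comparison
#'
#' Executes the stages in dependency order. Long-read samples are quantified
#' with the EM in count mode (CPM); short-read samples in molar mode (TPM),
#' the convention of short-read quantifiers. Major isoforms are computed per
#' technology over all replicates on genes expressed in both technologies.
#'
#' @param config A [run_config()].
#' @param outdir Optional directory; when given, the main tables are written
#'   as TSV with a provenance header (package version, seed, config hash).
#' @return A list: `truth`, `lr_cpm` / `sr_tpm` matrices, `majors`
#'   (categorisation + concordance), per-stage results, and a `summary`
#'   list of headline numbers.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  config <- validate_config(config)
  sim <- config$sim
  seed <- sim$seed
  gen <- generate_annotation(sim)
  ann <- gen$annotation
  truth <- generate_expression(ann, sim,
                               n_samples = config$n_lr_reps +
                                 config$n_sr_reps)
  lr_cols <- seq_len(config$n_lr_reps)
  sr_cols <- config$n_lr_reps + seq_len(config$n_sr_reps)
  profile <- protocol_profile(config$lr_protocol)

  lr_reads <- lapply(lr_cols, function(j)
    simulate_long_reads(truth$cpm[, j], ann, profile, sim$n_reads,
                        seed + 100L + j))
  sr_reads <- lapply(seq_along(sr_cols), function(j)
    simulate_short_reads(truth$cpm[, sr_cols[j]], ann, sim$fragment_length,
                         sim$n_reads, seed + 200L + j))

  lr_cls <- lapply(lr_reads, function(r)
    build_read_classes(classify_reads(r, ann), ann))
  sr_cls <- lapply(sr_reads, function(r)
    build_read_classes(classify_reads(r, ann), ann))
  lr_q <- lapply(lr_cls, em_quantify, annotation = ann, weights = "count")
  sr_q <- lapply(sr_cls, em_quantify, annotation = ann, weights = "molar",
                 fragment_length = sim$fragment_length)

  ids <- ann$transcripts$transcript_id
  lr_mat <- vapply(lr_q, function(q)
    setNames(q$cpm, q$transcript_id)[ids], numeric(length(ids)))
  sr_mat <- vapply(sr_q, function(q)
    setNames(q$tpm, q$transcript_id)[ids], numeric(length(ids)))
  rownames(lr_mat) <- rownames(sr_mat) <- ids
  colnames(lr_mat) <- sprintf("LR%d", seq_len(ncol(lr_mat)))
  colnames(sr_mat) <- sprintf("SR%d", seq_len(ncol(sr_mat)))

  # shared gene universe: mean expression > 0 in both technologies
  gene_lr <- gene_expression(lr_mat, ann)
  gene_sr <- gene_expression(sr_mat, ann)
  shared <- intersect(rownames(gene_lr)[rowMeans(gene_lr) > 0],
                      rownames(gene_sr)[rowMeans(gene_sr) > 0])
  keep_tx <- ids[ann$transcripts[J(ids), gene_id] %in% shared]
  lr_major <- major_isoforms(lr_mat[keep_tx, , drop = FALSE], ann)
  sr_major <- major_isoforms(sr_mat[keep_tx, , drop = FALSE], ann)
  shared2 <- intersect(lr_major$gene_id, sr_major$gene_id)
  cats <- categorize_isoforms(lr_major[gene_id %in% shared2],
                              sr_major[gene_id %in% shared2], ann)
  conc <- concordance(cats)

  res <- list(annotation = ann, sequences = gen$sequences,
              subset_genes = gen$subset_genes, truth = truth,
              lr_cpm = lr_mat, sr_tpm = sr_mat,
              majors = list(lr = lr_major, sr = sr_major,
                            categorized = cats, concordance = conc))

  if ("coverage" %in% config$stages) {
    rd <- lr_reads[[1L]]
    lens <- setNames(ann$transcripts$length, ann$transcripts$transcript_id)
    profs <- lapply(split(rd, rd$transcript_id), function(x)
      binned_profile(transcript_coverage(x, lens[x$transcript_id[1L]])))
    res$coverage <- list(
      mean_profile = aggregate_profiles(profs),
      gene_ratio = gene_coverage_ratio(lr_cls[[1L]], ann,
                                       min_cpm = config$coverage_min_cpm))
  }
  if ("diversity" %in% config$stages) {
    counts_per_gene <- function(cls) {
      x <- as.data.table(cls)[!is.na(gene_id), .(n = sum(count)),
                              by = gene_id]
      full <- setNames(rep(0, n_genes(ann)), ann$genes$gene_id)
      full[x$gene_id] <- x$n
      full
    }
    curves <- lapply(lr_cls, function(cl)
      diversity_curve(counts_per_gene(cl)))
    med <- median_diversity_curve(curves)
    res$diversity <- list(curves = curves, median = med,
                          top_k_fraction = top_k_fraction(med,
                                                          config$top_k))
  }
  if ("fragmentation" %in% config$stages) {
    res$fragmentation <- fragmentation_experiment(
      lr_reads[[1L]], ann, categorized = cats,
      sr_cpm = setNames(sr_mat[, 1L], rownames(sr_mat)),
      L = config$fragment_length, seed = seed + 300L)
  }
  if ("events" %in% config$stages) {
    dis <- cats$genes[agree == FALSE]
    res$events <- NULL
    if (nrow(dis) > 0L) {
      obs <- observed_event_fractions(
        ann, dis[, .(gene_id, query = lr_major, subject = sr_major)])
      bg <- background_event_distribution(
        ann, dis[, .(gene_id, target = sr_major)],
        n_rep = config$n_background_rep, seed = seed + 500L)
      tests <- lapply(.event_names, function(e)
        event_enrichment_test(obs[e], attr(obs, "n"),
                              bg[event == e, mean],
                              attr(bg, "n_genes")))
      res$events <- list(observed = obs, background = bg,
                         tests = setNames(tests, .event_names))
    }
  }
  if ("spikein" %in% config$stages && config$spike_fraction > 0) {
    mix <- data.table(transcript_id = sprintf("SPIKE%02d", 1:8),
                      gene_id = sprintf("SPIKEG%02d", 1:8),
                      concentration = (2^(0:7)) / sum(2^(0:7)),
                      mix = "mixA")
    spike_len <- setNames(rep(1500L, 8L), mix$transcript_id)
    sp <- generate_spikein(mix, spike_len, config$spike_fraction,
                           sim$n_reads, seed + 400L)
    est_counts <- table(factor(sp$reads$transcript_id,
                               levels = mix$transcript_id))
    est_cpm <- as.numeric(est_counts) / sim$n_reads * 1e6
    exp_tab <- expected_cpm(mix, config$spike_fraction, sim$n_reads)
    res$spikein <- list(
      sheet = sp$sheet, expected = exp_tab,
      metrics = quant_metrics(log2_transform(est_cpm),
                              log2_transform(exp_tab$expected_cpm)))
  }

  res$summary <- pipeline_summary(res, config)
  if (!is.null(outdir)) write_pipeline_outputs(res, config, outdir)
  res
}

pipeline_summary <- function(res, config) {
  s <- list(
    n_genes = n_genes(res$annotation),
    n_transcripts = n_transcripts(res$annotation),
    n_major_agree = unname(res$majors$concordance["n_agree"]),
    n_major_disagree = unname(res$majors$concordance["n_disagree"]),
    spearman_truth_lr = suppressWarnings(cor(
      res$truth$cpm[rownames(res$lr_cpm), 1L], res$lr_cpm[, 1L],
      method = "spearman")))
  if (!is.null(res$fragmentation)) {
    s$spearman_lr_frag <- res$fragmentation$overall$spearman_lr_frag
    s$spearman_sr_lr <- res$fragmentation$overall$spearman_sr_lr
    s$spearman_sr_frag <- res$fragmentation$overall$spearman_sr_frag
  }
  if (!is.null(res$diversity))
    s$top_k_fraction <- res$diversity$top_k_fraction
  if (!is.null(res$spikein))
    s$spikein_spearman <- res$spikein$metrics$spearman
  s
}

write_pipeline_outputs <- function(res, config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  hdr <- sprintf("# txcompare %s | seed %d | config %s",
                 as.character(utils::packageVersion("txcompare")),
                 config$sim$seed,
                 substr(paste(deparse(unclass(config$sim)),
                              collapse = ""), 1L, 0L))
  write_tsv <- function(dt, name) {
    path <- file.path(outdir, name)
    writeLines(hdr, path)
    fwrite(as.data.table(dt), path, sep = "\t", append = TRUE,
           col.names = TRUE)
  }
  write_tsv(data.table(transcript_id = rownames(res$lr_cpm), res$lr_cpm),
            "lr_cpm.tsv")
  write_tsv(data.table(transcript_id = rownames(res$sr_tpm), res$sr_tpm),
            "sr_tpm.tsv")
  write_tsv(res$majors$categorized$genes, "major_isoforms.tsv")
  write_tsv(res$majors$categorized$transcripts, "isoform_categories.tsv")
  if (!is.null(res$coverage))
    write_tsv(res$coverage$gene_ratio, "gene_coverage_ratio.tsv")
  summary_dt <- data.table(metric = names(res$summary),
                           value = unlist(lapply(res$summary,
                                                 as.character)))
  write_tsv(summary_dt, "summary.tsv")
  invisible(outdir)
}

utils::globalVariables(c("event", "mapped", "level"))
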