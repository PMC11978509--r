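# txcompare

Transcript-level comparison of long- and short-read RNA-seq protocols.

Long-read protocols (Nanopore direct RNA, direct cDNA, PCR cDNA, PacBio
IsoSeq) and short-read Illumina RNA-seq frequently disagree about which
isoform of a gene is the most highly expressed. `txcompare` provides the
analytics to study that disagreement end to end: read-to-transcript
classification, transcript quantification, major-isoform concordance,
coverage and diversity profiling, in-silico read fragmentation, structural
isoform-event comparison against a simulated null, and spike-in
quantification benchmarking — together with a seeded synthetic-data
generator so every stage can be exercised with known ground truth, without
any external dataset.

It is aimed at method developers and analysts benchmarking RNA-seq
protocols or isoform quantifiers at transcript resolution.

## Core methods

**Read classification.** A read's splice-junction chain is the ordered list
of genomic (donor end, acceptor start) pairs it spans. A read is a
*full-splice-match* (FSM) when its chain exactly equals the complete chain
of an annotated transcript, *partial* when its chain is a non-empty
consecutive sub-chain of at least one transcript (or the read is
junction-free and contained in one exon), and *unassigned* otherwise. Reads
sharing a chain form a *read class* with a count, an exonic width and a
compatible-transcript set.

**Quantification.** An expectation-maximisation estimator over read
classes: the E-step splits each class count n_c across its compatible
transcripts proportionally to the current estimates a_t (long-read mode) or
to a_t / ℓ_t with ℓ_t the effective length (fragment mode, the convention
of short-read quantifiers); the M-step re-normalises. Abundances are
reported as CPM (counts per million) and, in fragment mode, TPM.

**Major isoforms.** Per gene and technology, the transcript with the
highest mean expression across replicates; transcripts are categorised as
major-shared, major-LR-specific, major-SR-specific or minor, and agreement
between technologies is measured per category (Spearman ρ, MAE).

**In-silico fragmentation.** Each long read of mapped length m ≥ 150 bp is
resampled into N = ⌊m/150⌋ fragments with start positions uniform on the
alignment interval, emulating short-read data from the same molecules.

**Coverage and diversity.** 100-bin normalised coverage profiles per
transcript; cumulative read-fraction curves over expression- or
length-ranked genes (ties linearly interpolated); and a length-adjusted
gene-coverage ratio Σ(n_c · w_c / L_max) / Σ n_c compared between protocols
with a two-sided unpooled z-test.

**Structural events.** Pairwise isoform comparison flags internal/
alternative first and last exons, exon skipping, intron retention and
alternative 5'/3' splice sites, with a background null built by repeatedly
substituting a random non-major isoform (20 repetitions) and Bonferroni-
corrected two-proportion z-tests.

**Spike-ins.** Expected CPM from a concentration sheet
(CPM_t = fraction × rel_t × 10⁶) and a metric suite on the log2 scale:
Spearman ρ, MAE, MRAD, MRD, RMSE, R².

## Worked example

```r
library(txcompare)

cfg   <- sim_config(n_genes = 50, seed = 7)
gen   <- generate_annotation(cfg)
truth <- generate_expression(gen$annotation, cfg, n_samples = 2)
reads <- simulate_long_reads(truth$cpm[, 1], gen$annotation,
                             protocol_profile("dRNA-like"), 20000, seed = 8)

cls <- classify_reads(reads, gen$annotation)
table(cls$label)
#> full_splice_match           partial
#>             14484              5516

classes <- build_read_classes(cls, gen$annotation)
fit <- em_quantify(classes, gen$annotation)
est <- setNames(fit$cpm, fit$transcript_id)
cor(truth$base_cpm[names(est)], est, method = "spearman")
#> 0.982

unique_assignment_stats(classes)$fraction_unique
#> 0.987

fx <- fragmentation_experiment(reads, gen$annotation, seed = 9)
fx$n_fragments                   #> 90182
fx$overall$spearman_lr_frag      #> 0.964
```

With direct-RNA-like truncation, roughly a quarter of the reads lose their
5'-most junctions and become partial; the EM still recovers the true
transcript CPM ranking almost perfectly (ρ = 0.98), and almost 99% of reads
are uniquely assignable. Fragmenting the same reads into 150-bp pieces and
re-quantifying in fragment mode shifts the estimates (ρ = 0.96 against the
originals) — the shift concentrates on genes whose isoforms are
junction-subsets of one another, which is the mechanism behind
technology-specific major isoforms. `run_pipeline(run_config(sim = cfg))`
chains all stages and returns a summary list.

## Package layout

- `R/annotation.R` — annotation model, GTF I/O, coordinate conversion
- `R/simulate.R` — synthetic genomes, expression, reads, spike-ins
- `R/classify.R` — FSM/partial classification and read classes
- `R/quantify.R` — EM quantifier, CPM/TPM, gene aggregation
- `R/isoform.R` — major isoforms, categories, concordance
- `R/coverage.R` — coverage profiles, diversity curves, coverage ratio
- `R/fragment.R` — in-silico fragmentation and the impact experiment
- `R/events.R` — structural event vocabulary and background null
- `R/spikein.R` — expected CPM and the metric suite
- `R/pipeline.R` — configuration and end-to-end orchestration

See `vignettes/protocol-comparison.Rmd` for the methods account.
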