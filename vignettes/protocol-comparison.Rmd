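---
title: "Comparing RNA-seq protocols at transcript resolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing RNA-seq protocols at transcript resolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(txcompare)
```

# The problem

Long-read RNA sequencing observes (most of) a transcript molecule in a
single read, so transcript-level quantification can lean on direct
evidence: a read whose splice-junction chain equals an annotated
transcript's chain identifies that transcript. Short-read data only ever
observe ~150-bp fragments, and fragments falling in regions shared between
isoforms are intrinsically ambiguous. When isoforms of a gene are
*junction subsets* of one another — one isoform's chain a strict
consecutive sub-chain of another's, as with an alternative promoter in an
internal exon — short fragments cannot distinguish the pair over most of
their length, and quantifiers must apportion them by model. The two
technologies consequently often disagree about a gene's *major isoform*
(its most highly expressed transcript).

`txcompare` implements the analytics to measure this disagreement and to
test its mechanism: if short-read ambiguity drives it, then fragmenting
long reads *in silico* and re-quantifying them with a short-read-style
estimator should reproduce the short-read behaviour from the very same
molecules. That is the package's central experiment.

# Data model and conventions

Coordinates are 0-based half-open internally; GTF I/O converts from/to the
1-based closed convention. A transcript is an ordered list of
non-overlapping exons on one strand; its *junction chain* is the list of
(donor end, acceptor start) pairs in ascending genomic order regardless of
strand, so junction identity is purely genomic — matching how junction
equality is evaluated from alignments. Junction comparison is exact
(0 bp tolerance): inputs are assumed junction-corrected upstream.
Gene length is the maximum isoform length. Transcript space runs 5'→3',
i.e. reversed relative to genomic order on the minus strand.

Annotation-side filters mirror a standard expression-comparison setup:
`match_annotations()` keeps only genes whose transcripts are all present in
the transcriptome catalogue (version-suffix stripping is explicit via
`strip_versions`, never silent, because id conventions differ between
releases), and `filter_biotypes()` keeps protein-coding genes, antisense
RNAs, lincRNAs, noncoding RNAs and macro lncRNAs by default.

# Read classification

A read is **full-splice-match** (FSM) iff its junction chain equals some
transcript's complete chain; the compatible set is then exactly the
equal-chain transcripts. It is **partial** iff its chain is a non-empty
consecutive sub-chain of at least one transcript chain (with the read span
contained in that transcript's extent) but equals none. Consecutive
sub-chain containment — not arbitrary subset — is used because a read with
junctions 1 and 3 but not 2 of a transcript is splice-incompatible with it.

Junction-free reads are not covered by the spliced definition, so the
package takes a decision: they are FSM to a single-exon transcript that
contains them and partial to multi-exon transcripts when contained within
one exon. A strict `spliced_only = TRUE` mode leaves all junction-free
reads unassigned instead. Reads aligned to an unknown chromosome are
unassigned with a warning, never an error.

One consequence worth spelling out: a 150-bp fragment that spans the single
junction of a short isoform has a chain *equal* to that isoform's complete
chain and is therefore FSM to it alone, even if the fragment also fits
inside a longer isoform containing that junction. This makes
junction-subset isoform pairs the dominant source of fragment
misassignment, which is precisely the phenomenon under study.

Both transcriptome-space alignments (the generator's native output) and
genome-space block lists share one code path: transcriptome alignments are
projected to genomic junction chains through the annotation.

# Quantification

`em_quantify()` runs EM on the class-compatibility structure. With class
counts $n_c$ and per-transcript estimates $a_t$, the E-step splits each
class $n_c \cdot w_t / \sum_{t' \in c} w_{t'}$ with $w_t = a_t$ in
**count mode** (long reads: one molecule, one read) or
$w_t = a_t / \ell_t$ with effective length $\ell_t = L_t - 150 + 1$ in
**molar mode** (fragments: a molecule yields fragments in proportion to its
length, so short-read quantifiers reason on molar abundance). Molar mode
systematically shifts shared fragments toward shorter isoforms — the
behaviour that inflates subset isoforms in short-read estimates. Estimates
start uniform (deterministic, no seed), stop when the relative L1 change
drops below 1e-8 or after 1,000 iterations (returning with a warning when
the cap is hit; classes with no unique evidence decay geometrically and can
legitimately reach the cap), and conserve the assigned read total exactly.
The per-iteration log-likelihood trace is kept as an attribute and is
asserted non-decreasing in the tests.

CPM is count / total × 10⁶; TPM additionally divides by effective length
before rescaling. Gene expression is the per-sample sum of the gene's
transcript values. The log2 transform uses pseudocount 1 throughout.

# Major isoforms and concordance

Majors are computed per technology over the mean of all replicates (never
per sample), on the gene universe expressed (> 0 mean) in both
technologies. Ties are broken by the lexicographically smallest transcript
id — the underlying convention is unstated in common practice, so a
deterministic rule is fixed here. Genes with all-zero expression carry no
major isoform and are excluded and counted. The four categories
(major-shared, major-LR-specific, major-SR-specific, minor) partition the
transcripts of the shared universe; per-category agreement uses Spearman ρ
or MAE on log2 matrices and is reported as missing below 3 members.

# Coverage, diversity, coverage ratio

Coverage counts every aligned base, with deletion gaps inside a read
treated as covered, so depth reflects the molecule, not the alignment
gaps. Bin $i$ of 100 covers positions $[\lfloor (i-1)L/100 \rfloor,
\lfloor iL/100 \rfloor)$ — deterministic integer binning; transcripts
shorter than 100 bases or with zero coverage are excluded and counted.
Profiles are normalised by the maximum bin and averaged arithmetically
within groups.

Diversity curves rank genes by expression (descending) or length
(ascending) and accumulate read fractions; tied ranking keys are linearly
interpolated across the tied span, since the order within a tie is
arbitrary — the linear rule equals the average over all tie orderings. The
per-protocol summary is the rank-wise median across samples, and
`top_k_fraction()` reads the curve at rank min(k, G), default k = 1000.

The gene-coverage ratio is $\sum_c n_c\, w_c / L_{max} \big/ \sum_c n_c$
over a gene's read classes, with $w_c$ the class's exonic span (the
summed-block alternative coincides for transcriptome-space input) and
$L_{max}$ the gene length; it is 1 exactly when every class spans the
longest isoform. Genes below 30 CPM are excluded. Two protocols are
compared per gene by a two-sided z-test treating the ratio as a proportion
with unpooled variance $r(1-r)/n$, $n$ the gene's read total per protocol;
per-gene p-values are reported raw and Bonferroni-corrected. The variance
is degenerate when both ratios are 0 or 1; equal ratios then give z = 0,
p = 1, and unequal ones are reported missing.

# In-silico fragmentation

Reads with mapped length (alignment span, not query length — start
positions are defined on the alignment interval) of at least 150 bp yield
$N = \lfloor m / 150 \rfloor$ fragments, each start drawn from the
discrete uniform on [aln_start, aln_end − 150] inclusive; shorter reads
are skipped and counted. Only the bound N ≤ m/150 is standard; this
package fixes the deterministic floor rule as canonical and offers
`n_rule = "uniform"` (N uniform on [1, ⌊m/150⌋]) for sensitivity analysis.
Fragment sequences are reference substrings — error-corrected by
construction — and fragments are single-end with no insert-size model,
since only start positions are resampled. `trim_reads()` provides the
companion 5'-anchored trimming series (150 → 50 bp).

The impact experiment quantifies a long-read sample in count mode,
fragments it, re-quantifies in molar mode, and reports per-category
agreement plus the correlation of an independent short-read sample with
the original versus the fragmented estimates.

# Structural events and the background null

The event vocabulary is decidable from exon coordinates and junction
chains alone, strand-aware ("first"/"last" in transcript orientation):
internal first/last exon (the query's terminal exon shares its inner
junction boundary with a non-terminal subject exon), alternative
first/last exon (terminal exons disjoint and *neither* matches an internal
exon of the other — the exclusion keeps the reciprocal of an internal-exon
event from being miscalled alternative), exon skipping (a subject internal
exon inside a query intron whose boundaries both match subject junctions),
intron retention (a query exon spanning a subject junction plus flanking
bases), and alternative 5'/3' splice sites (a query junction sharing
exactly one boundary with a subject junction; junctions sharing both
boundaries with different subject junctions are skipping-type and not
double-counted as shifts).

The background distribution substitutes, per gene and repetition, one
uniformly drawn isoform other than the target and records event fractions
across genes; 20 repetitions give the mean ± s.d. Genes with a single
isoform are excluded and counted; with exactly two isoforms the null is
degenerate (s.d. 0) by construction. Enrichment uses the same unpooled
two-proportion z-test, Bonferroni-corrected over the 8 event categories.

# Spike-ins

Expected reads are total × fraction × relative concentration; on the CPM
scale the total cancels. The metric suite (Spearman, MAE, MRAD, MRD, RMSE,
R²) is computed on log2 values with pseudocount 1. The relative metrics'
denominator is not standardised anywhere, so both conventions ship:
relative to the expected value (default — errors anchored to truth) or to
the pair mean (`rel_denominator = "mean"`). Gene-level evaluation sums
transcript CPM by the mix's gene grouping.

# The synthetic-data generator

The generator emulates, with one mandatory master seed and fixed per-stage
offsets:

- **Gene structure**: non-overlapping genes on one synthetic chromosome;
  per gene a scaffold of 3–8 exons (100–300 bp, introns 200–2,000 bp);
  isoform 1 uses the full scaffold and further isoforms arise by exon
  skipping or donor shifts. With probability `subset_isoform_fraction` a
  gene carries a junction-subset pair: the subset isoform drops the outer
  scaffold exon and extends its new outer exon slightly into the dropped
  intron (the internal-first-exon pattern).
- **Expression**: gene CPM log-normal (meanlog log 50, sdlog 1.2 — about
  three orders of magnitude), isoform usage Dirichlet (concentration 1.5 —
  usually one clearly dominant isoform), multiplicative log-normal
  replicate noise (sdlog 0.1), every sample renormalised to 10⁶.
- **Protocol behaviour**: 3'-anchored truncation (5' start uniform, 3' end
  fixed) with probability 0.35 / 0.25 / 0.2 / 0.05 for dRNA-, dcDNA-,
  PCR-cDNA- and IsoSeq-like profiles; PCR concentration bias CPM^1.15 for
  the PCR profile; a logistic length weight (midpoint 1 kb, scale 200 bp)
  depleting short transcripts for the IsoSeq profile. These values are the
  package's calibration of the qualitative protocol differences they
  emulate (3' coverage bias, top-gene concentration, short-transcript
  depletion).
- **Short reads**: transcripts drawn ∝ CPM × (L − 150 + 1) (uniform
  fragmentation of molecules), fragment starts uniform.
- **Spike-ins**: binomially sized spike population, multinomial across the
  mix's relative concentrations, full-length reads, sheet written alongside.

What it does **not** emulate: sequencing errors and quality scores,
alignment artefacts (reads are emitted as transcriptome-space alignments
directly — the analyses consume alignments and fragmentation is
error-corrected by construction), poly(A) tails, overlapping or
antisense gene pairs, and genome-space mapping ambiguity. Passing tests
therefore demonstrate correctness of the analytics and the *mechanistic*
reproduction of fragmentation effects on clean alignments, not robustness
to alignment noise on real data.

# Shipped experiment scales

The tests and the acceptance script run fixed problem sizes chosen so each
property is measured with adequate statistical power while staying quick:
parameter recovery uses 200 genes with 2–4 isoforms and 10⁵ unbiased
full-length reads; the fragmentation benchmark uses 20 seeds × 150 genes
(subset fraction 0.5) × 15,000 reads per technology — at substantially
fewer genes the per-seed category Spearman rests on under ten genes per
category and its ordering is dominated by noise, whereas 150 genes give
30–40 genes in each specific category; the background null uses the
standard 20 repetitions. The end-to-end pipeline example runs 100 genes ×
20,000 reads × 2 + 2 replicates.

# Limitations

- The EM quantifier is deliberately minimal: no GC or positional bias
  model, no bootstrap uncertainty. It stands in for external quantifiers
  so the analytics can be exercised hermetically.
- Junction-free read handling and the event definitions are fixed package
  decisions where the field's conventions vary; alternatives are exposed
  (`spliced_only`, `n_rule`, `rel_denominator`) rather than silently
  chosen.
- Real-data headline numbers from large published cohorts depend on their
  specific quantifiers and annotations and are out of scope; the package
  claims definition-level and mechanism-level reproduction, verified
  against ground truth and independent oracles in the test suite.
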