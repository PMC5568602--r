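---
title: "Selecting reference genes from RNA-seq count tables"
author: "rgselect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting reference genes from RNA-seq count tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rgselect)
```

## The problem

Relative qPCR quantification divides a target gene's signal by that of a
reference gene (RG) assumed constant across all conditions of the
experiment. The assumption routinely fails for classical housekeeping
genes, and the standard stability scores (geNorm, NormFinder, BestKeeper)
require qPCR measurements of candidate RGs — the very data the RG is needed
to produce. An RNA-seq experiment run on the same conditions breaks the
circle: every transcript's expression profile is already measured, so
stable, well-expressed genes can be screened genome-wide before a single
primer is ordered. That screen is what `rgselect` implements, for anything
from a handful of long-read libraries in a non-model plant to dozens of
matched tumor/normal human samples.

## Model and procedure

The input is a table of raw counts $c_{gs}$ for transcript $g$ in condition
(sample) $s$, plus the per-sample library sizes $L_s$ — the number of
transcriptome-mapped reads.

**Within-sample normalization.** Sequencing depth varies between libraries
(up to an order of magnitude in heterogeneous public datasets), so counts
are scaled to reads per mapped million:

$$\mathrm{RPMM}_{gs} = \frac{c_{gs}}{L_s} \times 10^6.$$

Unlike RPKM/FPKM/TPM there is no division by transcript length. The method
never compares two different genes' expression levels — only one gene with
itself across samples — and a gene's length divides every entry of its row
equally, so it cannot change the cross-sample profile. This matters in
organisms whose transcriptomes are fragmentary: reliable lengths may simply
not exist.

**Stability statistic.** Per transcript, the coefficient of variation of
the RPMM profile across all conditions, as a percentage:

$$\mathrm{CV}_g = 100 \cdot \frac{\sigma_g}{\mu_g}, \qquad
\sigma_g^2 = \frac{1}{n}\sum_s (\mathrm{RPMM}_{gs} - \mu_g)^2.$$

The standard deviation is the **population** form (divisor $n$): the
conditions studied are the complete universe the RG must be stable over,
not a sample from a larger population. The package ships two published
per-sample RPMM tables as anchors (`published_rpmm()`); recomputing their
CV columns reproduces every printed value at 2 decimals with the divisor-n
form and none of them with divisor $n-1$ (the first olive row gives 10.72
vs 11.74), which pins the convention. A transcript with an all-zero profile
has an undefined CV (`NA`), not zero — it can never be a candidate anyway,
since it fails any expression filter.

**Dual-threshold selection.** A transcript is a candidate when

* $\mathrm{CV}_g \le \mathrm{cv_{max}}$ — expression as invariant as
  possible; and
* $c_{gs} \ge$ `min_reads` in **every** condition — enough molecules
  everywhere for the PCR to amplify reliably.

Both comparisons are inclusive and made on full-precision values; rounding
is display-only. Inclusive CV comparison is deliberate: published candidate
lists contain transcripts whose printed CV sits exactly on the cutoff, so a
strict inequality would contradict them. `min_reads` applies per condition
by default (a transcript silent in one tissue is useless as an RG there,
whatever its total); a `total` mode exists for exploratory use.
`suggest_min_reads()` provides the recommended starting threshold,
$0.00003 \times \min_s L_s$, which scales the expression floor with the
shallowest library: roughly 10 reads for a 3×10^5-read 454 library and
roughly 266 for a 9-million-read Illumina one.

**Ortholog collapsing.** Assembled transcriptomes often carry several
transcripts (fragments, isoforms, contig splits) of one gene. Given an
annotation table mapping transcripts to ortholog IDs, each candidate group
sharing an ortholog keeps only its member with the highest **mean** RPMM —
the best-expressed representative. "Highest RPMM" is interpreted as highest
mean across samples (no single sample is privileged); exact ties break to
the lexicographically smallest transcript ID so results are reproducible
bit for bit. Unannotated candidates pass through untouched.

**Sweeps and Venn summaries.** `run_sweep()` evaluates the full cross
product of CV cutoffs and read thresholds in one call, collapses each cell,
ranks each report by ascending CV (ties: descending mean RPMM, then ID),
and, per CV cutoff, partitions the union of candidate sets across read
thresholds into Venn regions. The region counts show at a glance how robust
the candidate list is to the expression threshold. Membership is compared
at ortholog level when an annotation is available — the biologically
meaningful unit — and at transcript level otherwise. For a fixed CV cutoff
the sets are nested (raising `min_reads` only removes candidates), so the
Venn collapses to a chain; across CV cutoffs it need not.

## The counting stage

When alignments rather than a count table are at hand, `count_sam_files()`
builds the table. The contracts:

* **Paired-end**: a record counts for its reference iff it is flagged
  properly paired (0x2) and mapped (0x4 clear) — both ends concordant on
  the same transcript, the record-level semantics of `samtools view -f2`.
  Each mate's record adds 1; a `fragment` unit (pair adds 1) is available.
* **Single-end**: every mapped record adds 1.
* Multi-mapping: when the aligner reported all alignments (report-all
  mode), each alignment record counts, including secondary records
  (0x100). `primary_only = TRUE` restricts to primary alignments.
* **Library size**: the number of *distinct* mapped read units (read name ×
  mate), each counted once however many transcripts it hit. The numerator
  of RPMM may be multi-map inflated, the denominator is not. When only a
  count table exists the true denominator is unrecoverable and column sums
  stand in; with report-all multi-mapping column sums overstate the
  denominator, which shrinks all RPMM values of a sample by a common factor
  — CVs are unaffected unless the multi-mapping rate differs strongly
  between samples, which is why explicit `--library-sizes` are preferred.

The SAM reader is intentionally minimal (QNAME, FLAG, RNAME of the text
format): counting is per-reference, so positions, CIGAR strings and
qualities are irrelevant. A record flagged properly-paired but without a
reference is rejected as malformed. Whether both mates truly landed on the
same transcript is taken from flag 0x2 as set by the aligner; the record
format carries no mate-reference field with which to double-check it.

## What the simulator emulates

`simulate_counts()` plants ground truth for validation. Invariant gene $g$
has a fixed relative abundance $p_g$; its count in sample $s$ is drawn with
mean $p_g L_s$, so its expected RPMM, $10^6 p_g$, is identical in every
sample regardless of depth heterogeneity. Variable genes receive an
additional independent per-sample fold factor drawn uniformly from
`fold_change_range`. Noise is negative binomial with
$\mathrm{Var} = \mu + \phi\mu^2$ — the standard RNA-seq count model —
approaching Poisson as $\phi \to 0$; at exactly $\phi = 0$ counts are the
deterministic $\mathrm{round}(\mu)$, giving (up to rounding) exactly
proportional rows and CV 0.

Default settings, chosen once as a realistic desk-scale screen: 20
invariant + 480 variable genes, 6 conditions, library sizes uniform in
[10^5, 3×10^5] (a threefold spread, within the range seen across public
datasets), abundances log-uniform in [0.005, 0.05] so planted genes sit at
roughly 500–5000 counts where Poisson noise contributes only 1.5–4.5% CV,
dispersion 0.001 (adding ~3% CV), and folds in [1, 4] (variable-gene RPMM
CV around 35%). Under these conditions the default thresholds (CV ≤ 10%,
≥ 10 reads per condition) recover the planted set with sensitivity and
specificity above 0.95, which the test suite and acceptance script verify
over 20 seeds. An olive-scale table is one call away
(`simulate_counts(157, 9000, 6)` — and is exercised by the round-trip
test). All randomness flows through the single `seed` argument; there is no
hidden state.

What the simulator does **not** emulate: correlated expression between
genes, sample-specific GC or length biases, batch effects, or compositional
coupling (abundances are drawn independently, not as a simplex). Passing
the planted-recovery test therefore shows the selection machinery is
correct and well-calibrated for its noise model, not that any particular
real dataset will yield equally clean candidates — on real data the CV
cutoff and read threshold usually need loosening, which is exactly what the
sweep is for.

## Numerical and design choices

* No value is rounded before filtering, ranking or collapsing; reports
  print CV and per-sample RPMM to 2 decimals and mean RPMM to 1, matching
  the precision conventions of published candidate tables.
* Number formatting in artifacts is locale-independent; identical inputs
  and flags give byte-identical outputs, and each run writes a
  `manifest.json` sufficient to re-run it.
* Missing cells in a count table are rejected, not imputed as zero: a
  silently imputed zero would both disqualify a transcript (min-reads) and
  distort its CV, so the user must decide.
* Counts must be integral; `"3.0"`-style exporter output is coerced with a
  warning, fractional values are errors.
* Transcript IDs are opaque strings; suffix conventions like `_split_1`
  are never parsed — such fragments stay distinct unless the annotation
  maps them together.
* An empty candidate set is a result (published analyses report such
  cases), not an error: reports are written header-only and the exit
  status is 0.
* More than 5 Venn sets cannot be drawn as a diagram and are refused
  unless counts-only mode is requested explicitly.

## Worked example

```{r example}
sim  <- simulate_counts(seed = 1)
expr <- summarize_expression(sim$counts, sim$lib_sizes)
sw   <- run_sweep(expr, sim$counts, NULL,
                  cv_list = c(10, 20), min_reads_list = c(10, 50, 100))
sw
head(sw$grid[[1]]$report[, c("transcript_id", "cv_percent", "mean_rpmm")])
sum(names(sim$truth)[sim$truth == "invariant"] %in%
      sw$grid[[1]]$candidates)
```

## Limitations

* Stability is scored marginally per gene; no multi-gene normalization
  factor (geNorm-style pairwise variation) is computed — the output is a
  shortlist for experimental validation, not a final normalizer.
* The CV of a two-condition experiment is driven by a single difference;
  candidates from $n = 2$ designs deserve extra scrutiny (the published
  two-accession anchors illustrate how small such CVs can look).
* Counting interprets flags only; it trusts the aligner's proper-pair
  definition and performs no coordinate-level checks.
* Candidate lists are screening evidence. Final RGs still require qPCR
  validation in the actual experimental material.
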