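---
title: "Methods: somatic alteration calling and multi-assay integration in collecting duct carcinoma cohorts"
author: "cdclossmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: somatic alteration calling and multi-assay integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdclossmap)
```

# Scope

Collecting duct carcinoma (CDC) is a rare, aggressive renal cell carcinoma
subtype in which loss of the *CDKN2A*/p16 tumor-suppressor locus on 9p is
the recurrent headline alteration, and in which solute-carrier (SLC)
transporter dysregulation — notably the cystine transporter xCT
(*SLC7A11*), a cisplatin-resistance marker — is of direct therapeutic
interest.  `cdclossmap` implements the downstream analysis layer for such
cohorts: it consumes variant candidate tables, copy-number segments,
per-cell FISH probe counts, differential-expression tables and IHC scores,
and produces filtered somatic calls, gene-level loss calls, FISH
classifications, an integrated per-sample gene status with cohort
frequencies, and gene-family expression summaries.

Upstream primary analysis (read alignment, initial variant calling,
segmentation, differential-expression testing) is deliberately out of
scope: those steps have mature dedicated tools, and this package picks up
at their outputs.

# Somatic filter chain

Candidates arrive as tumor/normal stranded allele counts
$(r^{+}, r^{-}, a^{+}, a^{-})$ with a reference context string.  Five
filters are applied; a candidate is somatic iff all applicable filters
pass.

1. **Normal absence.** Total normal alt reads
   $a_N \le$ `max_normal_alt_reads` (default 0).  The default demands
   strict absence; a small tolerance is configurable because real matched
   normals contain contamination and sequencing error.
2. **Fisher enrichment.** One-sided Fisher exact test on
   $[(a_T, r_T), (a_N, r_N)]$, i.e. the upper hypergeometric tail
   $P(X \ge a_T)$ with $X \sim \mathrm{Hypergeom}(N, K, n_T)$, where $K$
   is the total alt count and $n_T$ the tumor depth.  Pass iff
   $p <$ `fisher_alpha` (default 0.05).  Strand-collapsed counts are used;
   the alternative (per-strand tables) would conflate this criterion with
   the orientation filter.  Zero depth in either sample is a domain error,
   not a NaN.
3. **Orientation.** At least `min_alt_per_strand` (default 1) alt reads on
   each strand.  Single-strand pile-ups are a classic sequencing-artifact
   signature.
4. **Homopolymer context.** A maximal single-base run of length $\ge$
   `homopolymer_min_run` (default 5) that touches, or lies within
   `homopolymer_max_dist` (default 1) bases of, the variant position fails
   the candidate.  Polymerase slippage concentrates errors in and
   immediately next to such runs, which motivates including the adjacent
   position rather than only runs covering the variant itself.
5. **Indel realignment.** For indels, every read at the site (tumor and
   normal) is scored ungapped against the reference window and against the
   mutant template obtained by substituting the alternative allele for the
   reference allele; on the mutant template, offsets of reads starting
   right of the indel are shifted by the net indel length.  A read
   supports the mutant iff its mismatch count to the mutant template is
   *strictly* lower — ties count as non-supporting, a conservative
   tie-break.  Pass iff tumor support $\ge$ `indel_min_tumor_support`
   (default 2) and normal support $\le$ `indel_max_normal_support`
   (default 0).  An ungapped mismatch comparison (rather than a full
   aligner) is sufficient because both hypotheses are fixed-length
   templates anchored at known offsets; it is cheap and deterministic.

All thresholds live in `filter_params()`.  The criteria themselves are
standard for tumor/normal post-caller filtering; the numeric defaults are
this package's choices and are exposed precisely because they are
conventions, not laws.

The Fisher p-value is computed by `stats::phyper()` (exact hypergeometric
tail).  The test suite checks it against an independent brute-force
enumeration of every $2\times2$ table with the observed margins, built
from exact binomial coefficients, exhaustively over all tables with total
depth $\le 120$ (about $8.7\times10^6$ tables), with agreement required to
$10^{-9}$, and additionally against `stats::fisher.test()` on spot cases.

# Copy-number loss calling

Segments carry a sample, 1-based inclusive coordinates, a logR and an LOH
flag.  For a gene $g$ and sample $s$, the call uses the **minimum** logR
over all segments overlapping $g$:

* $\min \mathrm{logR} <$ `homo_logR` (default $-1.0$): homozygous loss;
* `homo_logR` $\le \min \mathrm{logR} <$ `loss_logR` (default $-0.4$):
  heterozygous loss;
* otherwise no loss.  LOH is reported if any overlapping segment carries
  the flag.

The $-0.4$ loss threshold is the conventional segment-overlap rule for
calling a gene lost from array segmentation; it is applied with strict
inequality ("less than").  The homozygous/heterozygous split at $-1.0$ is
this package's addition: in a pure diploid tumor a single-copy loss
expects $\mathrm{logR} \approx \log_2(1/2) = -1$, so values well below
that indicate loss of both copies.  Both thresholds are configurable
(`cn_thresholds()`).  Taking the minimum over overlapping segments (rather
than a weighted mean) ensures a focal deletion nested inside a broad
copy-neutral segment is not averaged away.

Coordinates are 1-based inclusive throughout; BED input (0-based
half-open) is converted on read via `rtracklayer`.  A gene with no
overlapping segment is reported as `no_loss` with a missing logR and a
logged message rather than an error, so partially covered cohorts remain
processable.  Overlap queries use `GenomicRanges`.

# FISH ratio classification

For each case the ratio is $\bar{t}/\bar{c}$: the mean number of target
(*CDKN2A*) probe signals per nucleus divided by the mean number of
reference (CEP9 centromeric) signals, conventionally over 200 evaluated
nuclei.  Bins: ratio $> 0.75$ no loss; $0.5 \le$ ratio $\le 0.75$
heterozygous loss; ratio $< 0.5$ biallelic loss.  The published bin
descriptions leave the two boundary values ambiguous; this package fixes
both 0.75 and 0.5 to classify as heterozygous loss (configurable bin
edges), and applies no rounding to the ratio before binning.  Cases with
fewer than `min_cells` (default 200) nuclei are computed but flagged
sub-threshold rather than rejected, keeping the tool usable on partial
data.

# Multi-assay integration

Array status, FISH status and sequencing evidence (truncating SNV plus
LOH at the locus) are merged by a maximum over the severity scale
`no_loss < het_loss < homo_loss`: *the assay reporting the deeper loss
wins*, and a truncating mutation under LOH counts as biallelic
inactivation.  This rule is induced from how such cohorts are tabulated
in practice: a FISH-detected homozygous loss missed by the array is a
homozygous loss, and a nonsense mutation with LOH over the locus is
counted with the biallelic events.  Discordance in the opposite direction
(one assay deep loss, another explicit no-loss) also resolves to the
deeper loss but is annotated in `evidence_note` for manual review, since
it more likely reflects assay failure than biology.  Cohort percentages
are rounded half-up to one decimal (`round_half_up()`), matching how such
frequencies are conventionally printed; base R's round-half-even would
print e.g. 62.45 as 62.4.

`cdkn2a_evidence()` ships the per-sample evidence for the published
16-case CDC cohort (3 array biallelic deletions, 1 FISH-only biallelic
loss, 1 FISH heterozygous loss, 1 nonsense mutation under copy-neutral
LOH, 9 FFPE cases resolved by FISH alone); its integration yields 8/16
homozygous (50.0%), 2/16 heterozygous (12.5%), 62.5% any loss.

# Expression profiling

`family_alteration_summary()` counts family genes with adjusted
$p <$ `padj_cutoff` (default 0.05) and positive/negative log2 fold change;
no fold-change magnitude cutoff is applied by default (configurable),
because the upstream DE tool has already performed the significance test
and multiple-testing correction.  Family genes absent from the DE table
count as unaltered.  With 41 up- and 95 down-regulated members of a
300-gene family this gives 136 altered, 45.3%.

Per-sample marker up-regulation (`per_sample_up_fraction()`) counts
samples with log2 fold change strictly above `min_log2fc` (default 0; no
per-sample significance threshold is defined upstream, so the sign is the
defensible default).  IHC scores are binned as negative ($<2\%$ positive
cells), low (2–20%), intermediate ($>20\%$ and $<80\%$) and high
(80–100%): the conventional low/high ranges leave 0–2% and 20–80%
unclassified, so explicit `negative` and `intermediate` bins complete the
partition of $[0, 100]$.

# The synthetic cohort generator

No public raw data accompanies this analysis setting, so the package
treats the generator as a first-class module: every downstream stage is
exercised against data with known truth labels.  The distributions are
the simplest models matching each assay's described behaviour:

* **Variants.** Site depths are fixed at their configured means (depth
  variation adds nothing to what the filters test).  Somatic sites draw
  tumor alt counts $\sim \mathrm{Bin}(d_T, \mathrm{VAF})$ (default depth
  100, VAF 0.3) split binomially across strands; normals are clean unless
  `seq_error_rate` $> 0$.  Germline sites are heterozygous in both
  samples.  Artifacts are single-strand (all alt reads on one strand) or
  homopolymer-context (a run of `homopolymer_len`, default 6, embedded
  under the variant) with probability `strand_bias_prob` for the former —
  each artifact class violates exactly one filter.  Clean contexts are
  generated with runs capped at 3 bases so they can never trip the
  homopolymer filter.  Default site counts (200 somatic, 200 germline,
  100 artifact) define the reference recovery conditions.  Only SNV
  candidates are emitted in bulk; the indel path is exercised by
  `simulate_indel_reads()`, which builds read sets as verbatim template
  substrings with per-read provenance labels.
* **Segments.** Per assayed sample and gene, a focal segment (gene
  $\pm$ 50 kb) draws logR $\sim N(\mu_{\mathrm{state}}, \sigma)$ with
  centres $0 / -0.7 / -2.0$ for no/het/homo loss and $\sigma =$ `cn_sd`
  (default 0.1), nested in a copy-neutral whole-chromosome background
  segment — which also exercises the minimum-logR aggregation.  LOH flags
  copy the truth table, so copy-neutral LOH is representable.  The
  centres sit $\ge 3\sigma$ from both thresholds at the default noise,
  and at $\sigma = 0$ recovery is exact.
* **FISH.** Neoplastic nuclei carry base counts $(2,2) / (1,2) / (0,2)$
  for no/het/homo loss; each evaluated nucleus is instead a diploid
  non-neoplastic cell with probability `fish_normal_fraction` (default
  0.2); each count is then misread by $\pm1$ with probability
  `fish_noise`, floored at zero.  The admixture term deserves emphasis:
  tissue sections genuinely contain stromal and entrapped normal nuclei,
  and without admixture a pure heterozygous-loss population has expected
  ratio exactly $1/2\cdot\bar{c}/\bar{c} = 0.5$ — *on* the het/biallelic
  bin boundary — so any unbiased counting noise would turn the het call
  into a coin flip.  The 0.5–0.75 heterozygous bin presupposes admixed
  material.  With the default 20% admixture the expected ratios are 1.0,
  0.6 and 0.2, all interior to their bins by $\ge 5$ standard errors at
  200 cells and noise 0.1.  Setting `fish_normal_fraction = 0` recovers
  the pure base states (ratio exactly 0.5 for het loss at zero noise).
* **Expression/IHC.** The DE generator plants exactly the configured
  up/down family counts (default 41/95 of 300) with adjusted $p < 0.05$,
  plus filler genes whose default up/down split (2838/1856) makes the
  overall table resemble a tumor-vs-normal comparison with ~4800
  significant genes.  IHC draws `ihc_high` scores in 80–100 and `ihc_low`
  in 2–20 (default 12/3); the marker generator gives `marker_up` of
  `marker_total` samples positive fold changes (default 4/5).

Each generator draws from its own substream derived from the master seed
(`derive_seed()`), so enlarging one table never shifts another's values,
and all generators restore the caller's RNG state.  What the generator
does *not* model — and what passing recovery tests therefore do not
demonstrate about real data — includes: depth variation and mapping
artifacts, tumor purity and subclonality in the sequencing data,
base-quality structure, correlated FISH counting error between probes,
and segmentation error in the copy-number input.

# Demo cohort and problem sizes

The default configuration encodes a 16-sample cohort whose per-sample
truth reproduces the published evidence pattern (see
`demo_cn_truth()`, `demo_fish_truth()`, `demo_snv_truth()`), so the demo
pipeline's integrated output is 8 homozygous + 2 heterozygous + 6 no-loss
= 62.5% any loss.  The test suite uses: 500-site filter recovery runs,
1,000 seeded FISH replicates per state at noise 0.1, the exhaustive
Fisher grid to total depth 120, and full pipeline runs on the 16-sample
demo; these sizes give stable statistics while keeping a full check run
in minutes on one CPU.

```{r demo, eval = FALSE}
res <- run_pipeline(outdir = "demo_out", seed = 1)
res$cohort_summary
#>   n_samples n_homo n_het n_no_loss pct_homo pct_het pct_no_loss pct_any_loss
#> 1        16      8     2         6       50    12.5        37.5         62.5
```

# Reproducibility and numerical conventions

* Identical configuration + seed gives byte-identical pipeline outputs;
  the run manifest records package version, seed, every configurable
  parameter and MD5 checksums of all files, and deliberately contains no
  timestamps or absolute paths.
* Percentages: half-up rounding to one decimal, applied only at reporting
  boundaries — classification always uses unrounded values.
* Boundary conventions collected in one place: loss calls use strict
  `<` at both logR thresholds; FISH bin edges 0.5 and 0.75 classify as
  heterozygous loss; IHC edges 2 and 20 belong to `low`, 80 to `high`;
  the normal-absence and orientation count thresholds are inclusive;
  realignment mismatch ties are non-supporting.

# Known limitations

* The filters operate on candidate tables, not raw alignments; systematic
  caller biases upstream are invisible to them.
* No purity/ploidy correction: logR thresholds assume a reasonably pure
  diploid background, and heavily admixed or aneuploid samples would need
  recalibrated thresholds.
* The integration rule trusts the deepest-loss assay; it has no model of
  assay-specific error rates and flags rather than resolves opposite-
  direction discordance.
* Real gene symbols are not validated against an annotation source; the
  expression module treats symbols as opaque identifiers.
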