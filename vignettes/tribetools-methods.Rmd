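---
title: "Methods: differential-editing target calling and downstream scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential-editing target calling and downstream scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tribetools)
```

## The experiment this package models

HyperTRIBE-style experiments identify the mRNA targets of an RNA-binding
protein (RBP) by fusing the RBP to the catalytic domain of the RNA-editing
enzyme ADAR. Wherever the fusion protein binds, nearby adenosines are
deaminated to inosine, which sequencers read as guanosine. Comparing the
A-to-G editing frequency between cells expressing the fusion (`S_ADAR`) and
cells carrying an empty vector (`EV`) therefore marks direct binding targets
without immunoprecipitation, at the low input amounts typical of sorted stem
and progenitor cells.

The pipeline starts at the per-site count table (alternate and reference
reads per sample at each candidate site); alignment and per-read variant
calling are upstream and out of scope. Downstream of target calling it
covers three further analyses that commonly accompany such experiments:
k-mer motif discovery around edit sites, integration of the target list with
transcriptome and label-free-proteomics fold-change tables, and scoring of
asymmetric cell division and cell polarity from paired immunofluorescence
intensities.

## Differential-editing model

The editing frequency of site $i$ in sample $j$ is $f_{ij} = a_{ij} /
(a_{ij} + r_{ij})$, the alternate-read fraction. Condition means are
unweighted across samples with nonzero depth: a depth-weighted mean would
let a single deep replicate dominate, and the replicate—not the read—is the
unit of biological variation here. The calling statistic is the
differential editing frequency

$$\Delta f_i = \bar f_i^{\,\mathrm{S\_ADAR}} - \bar f_i^{\,\mathrm{EV}}.$$

Two per-site tests are offered:

* **`fisher_pooled`** (default): reads are pooled within condition and the
  2×2 table of summed (alt, ref) counts is tested with the two-sided
  conditional exact (Fisher) test. Pooling sacrifices replicate-level
  dispersion information but is robust at the shallow depths common at
  candidate sites.
* **`betabinom_lrt`**: a replicate-aware likelihood-ratio test. Counts are
  beta-binomial with mean $p$ and intra-class correlation $\rho$ (shared
  across conditions); the null fits one mean, the alternative one mean per
  condition, and $2\Delta\ell$ is referred to $\chi^2_1$. This is the
  better-calibrated choice when replicates are overdispersed, at roughly
  100× the computational cost.

A site is **called** when its Benjamini–Hochberg adjusted p-value satisfies
$q < 0.05$ and $\Delta f > 0.1$, both strict, the package's default calling
standard. BH is applied once per dataset (e.g. per cell type), so q-values
are comparable within but not across datasets. Sites need at least
`min_depth = 10` summed reads in *each* condition to be tested: at depths of
1–2 reads the frequency estimate is degenerate (0, ½ or 1), and admitting
such sites would only dilute the BH correction. The depth floor is a package
design choice, exposed as a parameter.

Genic location is annotated by interval overlap against transcript models
(0-based half-open internally; 1-based only on VCF write). When isoforms
disagree, the fixed priority 3'UTR > CDS > 5'UTR applies — RBP binding
reported by this assay class concentrates in 3'UTRs, so ambiguity resolves
toward the more probable annotation; the rule is deterministic, which
matters more than its direction. Output ordering ties are broken by site id
so that runs are byte-reproducible.

## Motif enrichment and distance profiles

Motif discovery is deliberately simple: exact k-mers (k = 4–7) scored by
*presence/absence* across sequence windows of ±250 bases around called
sites, against windows drawn at random positions of transcripts that carry
no called site. Presence counting (rather than occurrence counting) removes
sequence-length bias; the window size matches how far this assay class
displaces edits from the actual binding site. The test is the one-sided
binomial tail $P(X \ge c_{fg} \mid n_{fg}, \hat p_{bg})$ with BH correction
across all k-mers. The background presence rate is floored at half a count
(a Haldane-style correction): without it any k-mer absent from the finite
background sample would get p = 0 and outrank genuinely enriched motifs.
The background construction is a package choice — matched random windows
from non-target transcripts — and is the main lever a user may want to
change on real data. No PWM refinement is attempted; the motifs this assay
class reports are short exact strings, and an iterative optimizer would add
variance without adding interpretability.

Nearest-motif distances are signed (motif start minus site position, in
window coordinates, negative = upstream), nearest by absolute value with
ties resolved upstream, overlapping occurrences included (regex lookahead).
Sites without an occurrence within the window are excluded and counted.
The summary density is a Gaussian KDE with Silverman's bandwidth on a
501-point grid over ±window, renormalized to unit mass on the grid so the
reported curve is a proper (truncated) density even when distances sit near
the window edge. Motif specs accept IUPAC codes and a leading `X/Y`
alternative (`G/AGUAAG` ≡ `[GA]GUAAG`).

## Multi-omics integration

Protein intensities are normalized by equalizing column totals to the mean
input total, which preserves within-sample proportions. Per-gene
$\log_2$ fold change uses group means with a pseudo-count of half the
smallest nonzero intensity in the matrix (configurable); means rather than
medians because 3-sample groups give medians no robustness advantage.
Significance is a one-sided Wilcoxon rank-sum test oriented by the sign of
the observed fold change — the orientation convention is a package decision
and is tested against full enumeration of rank assignments for 3v3 and 4v4
designs. Note the floor this implies: a 3v3 one-sided exact rank test
cannot go below p = 1/20, so genome-wide FDR-controlled discovery from the
matrix alone needs either more replicates or an externally computed
fold-change table; the integration layer accepts both.

Threshold filters mirror the conventions of printed differential-expression
cutoffs: fold-change boundaries are inclusive (FC ≥ 2 keeps
$|\log_2\mathrm{FC}| \ge 1$) while FDR boundaries are strict. Venn region
counting works on deduplicated exact-string gene identifiers (after no
alias resolution — mapping identifiers is upstream curation, not statistics)
and satisfies the partition identity $|A| = \sum_{\text{regions} \ni A}$ by
construction, which the tests assert on random sets. Edit-burden versus
expression association uses Spearman rank correlation, the natural choice
for a count against a fold change.

## Division and polarity scoring

Paired daughter cells are classified from two intensities per pair:

* **2-fold rule** (NUMB): ratio ≥ 2 (inclusive) → asymmetric; otherwise the
  pair mean against a per-replicate high/low threshold splits symmetric
  commitment from symmetric renewal.
* **log2FC rule** (LAMP1, TMI): $|\log_2(i_1/i_2)| \ge 0.6$ (inclusive) →
  asymmetric; the symmetric remainder splits into high/low by the same mean
  rule.
* **Polarity** (TUBULIN): a cell is polar when the two half-cell sums differ
  by $|\log_2| > 0.6$, *strict* — mirroring the different operator
  conventions the two rules are stated with.

Ratio-based decisions are scale invariant and symmetric in daughter labels;
both properties are tested. The inclusive/strict boundaries carry a 1e-9
guard on the log2 scale so that an intensity pair constructed exactly at a
boundary classifies the same way on every platform. The high/low threshold
is set per experimental replicate; the default rule (median of pair means
within the replicate) is a package choice, prominently overridable, because
staining intensity is only comparable within a replicate. Genotype
summaries aggregate per-replicate category fractions (the animal is the
experimental unit) and compare genotypes with two-tailed t-tests on those
fractions; with a single replicate only fractions are reported.

Co-segregation of two markers is the 3×3 contingency of their classes; among
doubly-asymmetric pairs, concordance is the fraction where the same daughter
is high for both markers, with a Fisher exact test on the asymmetric/not
2×2 collapse.

## What the synthetic generator emulates — and what it does not

The generator produces every input the pipeline consumes, with known truth:

* **Editing counts**: beta-binomial alternate reads at negative-binomial
  depths (floored at one read), background editing 0.005, effect size
  +0.3 at true sites in `S_ADAR` samples only, $\rho = 0.02$, 3v3
  replicates, ~100× coverage. Background editing in empty-vector controls
  is not reported by the assay literature at per-site resolution; 0.005 is
  a realistic stand-in for residual ADAR activity plus sequencing error and
  is exposed in the configuration. Setting the effect size to zero produces
  a pure null with no true targets.
* **Transcripts/sequences**: single-isoform plus-strand genes (200 nt
  5'UTR / 900 nt CDS / 600 nt 3'UTR), one contig per gene, candidate sites
  placed 3'UTR-heavy (60/30/10), an A forced at every site, and the binding
  motif planted near each true site at a Normal(0, 50) offset clamped to
  ±200 so every true site has its motif within the ±250 search window.
  Minus-strand handling is exercised by hand-built fixtures instead.
* **Expression tables**: planted down-regulated sets receive
  $\log_2\mathrm{FC} \le -1$ with FDR below the layer cutoff, everything
  else above it, so threshold filters recover planted sets exactly; the
  mRNA-down targets are drawn from within the protein-down targets
  (co-regulated direct targets), giving a controllable triple intersection.
* **Daughter pairs / polarity cells**: asymmetric pairs at ratio ≥ 4,
  symmetric at ratio < 1.5, polar cells above the 0.6 boundary — all well
  clear of the decision boundaries — with multiplicative log-normal noise.

Real data differ in ways the generator does not model: editing frequencies
correlate along transcripts, depth tracks expression, motif background is
compositionally biased rather than uniform, proteomics intensities are
missing not-at-random, and staining intensities drift within a replicate.
Passing tests therefore demonstrate that the *statistics and bookkeeping*
are correct under the declared model, not that the thresholds are optimal
for any particular dataset.

All randomness flows from one master seed through fixed per-stage offsets,
so every table is byte-reproducible; identical configuration and seed give
identical files.

## Problem sizes and numerical choices

The test suite and the acceptance script run the null and recovery checks at
~10,000 sites (5 seeds for the null), motif recovery over 20 generator seeds
at the 200-gene default, and mixture recovery at 10,000 pairs — sizes chosen
so the full battery reproduces on a laptop in about a minute while keeping
Monte-Carlo error well inside the asserted tolerances (≤ 0.02 on
frequencies, ≤ 0.01 on null call fractions). Exact-test agreement is checked
exhaustively for all 2×2 tables with margins ≤ 30 against an independent
log-factorial enumeration oracle. Degenerate inputs have defined behaviour
throughout: zero-depth samples drop out of means, zero-depth conditions are
flagged untestable, empty call tables return empty results rather than
errors, all-zero protein rows are dropped and counted, and constant vectors
make correlations report "undefined" rather than NaN.

## Known limitations

* The pooled Fisher test ignores replicate structure; with strongly
  overdispersed replicates prefer `betabinom_lrt`.
* Presence/absence k-mer enrichment cannot separate motifs that co-occur in
  the same windows; it ranks, it does not deconvolve.
* The background-window construction assumes non-target transcripts are a
  fair compositional background, which a GC- or region-matched background
  would improve on real data.
* Gene identifiers are matched as exact strings (case-normalized); no
  ortholog or alias resolution.
* Image-level processing (segmentation, half-cell splitting, z-stacks) is
  out of scope; the division module starts at per-object intensity sums.
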