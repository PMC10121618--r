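# tribetools

Identify the mRNA targets of an RNA-binding protein (RBP) from
HyperTRIBE-style editing experiments, and carry the target list through the
downstream analyses that typically accompany them.

In a HyperTRIBE experiment the RBP is fused to the catalytic domain of the
RNA-editing enzyme ADAR; transcripts the RBP binds acquire A-to-I edits,
which sequencing reads as A→G. Comparing per-site editing frequencies
between fusion-expressing cells (`S_ADAR`) and empty-vector controls (`EV`)
marks direct targets without immunoprecipitation — well suited to rare
populations such as sorted hematopoietic stem and progenitor cells.

The package covers, end to end and on a single count-table input:

1. **Edit calling** — per-site editing frequency
   *f* = alt/(ref+alt); differential frequency
   Δ*f* = mean *f*(S_ADAR) − mean *f*(EV); two-sided pooled Fisher exact
   test (or a replicate-aware beta-binomial likelihood-ratio test);
   Benjamini–Hochberg FDR; calling standard **q < 0.05 and Δf > 0.1** with
   a per-condition depth floor; genic annotation (5'UTR/CDS/3'UTR) and
   gene-level target summaries.
2. **Motif analysis** — presence/absence k-mer enrichment (k = 4–7,
   one-sided binomial vs a background of non-target transcript windows,
   BH-corrected) and signed nearest-motif distance profiles with kernel
   density estimates, within ±250 bases of edit sites.
3. **Multi-omics integration** — total-intensity normalization of
   label-free proteomics, per-gene log2 fold changes with one-sided
   Wilcoxon rank tests, threshold filters (inclusive fold-change, strict
   FDR boundaries), and exact Venn region counting across
   target/transcriptome/proteome gene sets.
4. **Division scoring** — paired daughter-cell classifiers (NUMB 2-fold
   rule; LAMP1/TMI |log2FC| ≥ 0.6 rule), TUBULIN polarity scoring
   (|log2FC| > 0.6, strict), marker co-segregation contingency analysis,
   and replicate-aware genotype summaries.
5. **Synthetic data** — a generator for every input above with known
   ground truth (beta-binomial counts, planted motifs, planted
   expression/proteome intersections, intensity-pair mixtures), so the
   whole pipeline is testable without any external download.

## Worked example

```r
library(tribetools)

cfg   <- edit_sim_config(n_genes = 300, effect_delta = 0.3, seed = 42)
sim   <- simulate_edit_dataset(cfg)
calls <- call_edits(sim$counts, transcripts = sim$transcripts)
calls
#> Differential editing calls: 135 of 454 tested sites (of 454 total)
#>   standard: q < 0.05 and delta_f > 0.1; min depth 10/condition; test fisher_pooled
#>       site_id      gene     chrom  pos strand    f_adar        f_ev   delta_f ...
#> 1  site000436 gene00293 gene00293 1151      + 0.3733460 0.002789400 0.3705566
#> 2  site000439 gene00295 gene00295 1491      + 0.3898778 0.000000000 0.3898778
#> ...
```

135 sites pass the calling standard; each row reports the mean editing
frequency in fusion and control samples, their difference, the exact-test
p-value, its BH-adjusted q and the genic region (mostly 3'UTR, where the
generator plants most true sites). Motif enrichment around those sites
recovers the planted binding motif:

```r
fg <- extract_context_sequences(calls, sim$transcripts, sim$sequences)
bg <- background_windows(setdiff(unique(sim$counts$gene), calls$gene),
                         sim$transcripts, sim$sequences, n = 150, seed = 7)
rank_kmers(fg$seq, bg$seq, k_range = c(4, 7))
#> k-mer enrichment ranking: 21248 k-mers tested
#>     kmer k fg_count fg_total bg_count bg_total enrichment       p_value
#> 1 ACUUAG 6      135      135       19      150   7.894737 7.234627e-122
#> 2  CUUAG 5      135      135       56      150   2.678571  1.710266e-58
```

`ACUUAG` is present in 135/135 site windows versus 19/150 background
windows (7.9-fold presence enrichment). Its nearest-occurrence distance
profile is centred on the edit sites:

```r
nearest_motif_distances(fg, "ACUUAG")[["ACUUAG"]]$all
#> distance profile for ACUUAG: 135 sites retained, 0 excluded (window +/-250)
#>   median distance -15, IQR [-42.5, 28.5]
```

Against the generator's truth table this run has sensitivity 1.000 and
precision 1.000. A full orchestrated run (simulation → calling → motif →
integration → division scoring, with all files written and a JSON run
report) is one call:

```r
report <- run_pipeline(load_config(NULL), out_dir = "demo_run")
```

A thin command-line wrapper with subcommands (`simulate`, `call-edits`,
`motif`, `integrate`, `score-division`, `run-all`) is installed at
`inst/scripts/tribetools.R`.

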