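# smoopr

Integrative analysis of condensation-prone RNAs in R.

Some RNAs concentrate into ribonucleoprotein assemblies and biomolecular
condensates. Two biochemical assays flag them transcriptome-wide:
*semi-extractability* (RNAs under-recovered by standard extraction unless
heated and sheared) and *OOPS* (orthogonal organic phase separation, which
recovers UV-crosslinked, protein-bound RNA at the organic/aqueous
interphase). Genes enriched in **both** assays — "smOOPs" — are candidate
condensation-prone RNAs. smoopr implements the full downstream analysis for
researchers studying RNA condensation:

* **Dual-assay calling** — smOOPs are genes with `padj < 0.01` and
  `LFC > 1` in both assays (controls: `padj > 0.01`, `|LFC| < 1.4`
  everywhere), plus one-sided hypergeometric granule-overlap tests.
* **Proximity-network null model** — RNA–RNA interaction graphs from
  proximity-ligation hybrid reads; focal-set connectivity (edge density,
  largest component, clustering coefficient, mean path length) is tested
  against degree-matched random node sets (±1 degree, 10,000 iterations in
  the full protocol) with the add-one permutation p
  `(1 + #{null ≥ obs}) / (1 + n_iter)`.
* **Feature encoding** — per-nucleotide tracks (crosslinks, m6A, duplex
  contacts, predicted pairedness, binary RBP peaks) projected onto
  exon-concatenated transcript coordinates, TPM-normalised, one-hot
  sequence, −1 padding, stratified 70:15:15 splits with oversampling.
* **Classifier** — the fixed convolutional-recurrent architecture: four
  dilated conv blocks (108/144/192/256 filters, kernel 9, dilations
  1/4/16/64, layer norm, ReLU, dropout 0.34, max-pool 4), a bidirectional
  GRU (128 units/direction, reset-after biasing), dense 64/32, softmax 2,
  L1L2 λ = 1.2e−5, Adam 1e−4 — between 1,149,986 and 1,203,446 trainable
  parameters depending on input width. Implemented natively in R (BLAS +
  small C++ kernels), with gradients verified against finite differences.
* **Powerset attribution** — one model per non-empty subset of the data
  layers (127 for seven layers), best of replicates, per-layer AUROC
  improvement deltas with one-sample t-tests, pairwise overlap analysis.
* **Integrated gradients** — per-nucleotide attribution of the
  positive-class output with a zeros baseline, 100-bin importance profiles,
  two-cluster agglomerative grouping on correlation distance, triplet and
  per-RBP importance, region-masking validation.
* **Validation statistics** — binned nucleotide/triplet composition
  differences (10/50/50 region bins), bootstrap CIs on binned track
  medians, region-resolved contact counts (Welch), global occupancy
  (one-sided Wilcoxon), amino-acid enrichment, disorder-fraction and mass
  comparisons for encoded proteins.
* **Synthetic cohorts** — a seeded generator planting all of the above
  signals (C-rich CDS, 3'UTR crosslink enrichment, a dense proximity
  community, dual-assay fold changes, codon-driven amino-acid shifts) so
  the whole pipeline is testable end to end without sequencing data.

## Worked example

```r
library(smoopr)

cfg <- sim_config(seed = 42, n_genes = 150)
tx  <- generate_transcripts(cfg)
enr <- generate_enrichment_table(tx, cfg)

smoops   <- call_smoops(enr, stage = "nPSC")
controls <- call_common_controls(enr)
length(smoops)    # 52
length(controls)  # 40

focal <- smoops[1:20]
net <- build_rri_network(generate_hybrids(tx, focal, cfg))
permutation_test(net, focal, n_iter = 999, seed = 7)
#> Degree-matched permutation test (20 focal nodes, 999 iterations, +/-1 degrees)
#>   edge_density       observed 0.2684   p = 0.001
#>   lcc_size           observed 20   p = 0.04
#>   global_clustering  observed 0.2459   p = 0.593
#>   avg_path_length    observed 3.158   p = 0.926

build_model(n_channels = 1)
#> Convolutional-recurrent classifier: 1 input channel(s), 1,149,986 trainable parameters
```

The permutation test flags the planted community: its observed edge density
(0.268) exceeds every degree-matched null draw (null mean 0.163), giving the
smallest attainable p at 999 iterations. The 20 focal genes were simulated
with a within-community edge probability of 0.25 against a 0.02 background,
so this is the expected planted-signal recovery. The model print shows the
parameter accounting at the narrowest input: a single-channel model has
exactly 1,149,986 trainable weights.

The full pipeline — simulation, calling, network test, encoding, powerset
training, integrated-gradients deconvolution, composition and protein
validation — runs as one seeded call:

```r
report <- run_demo(demo_config(seed = 1))
report$powerset$best_auroc
report$powerset$improvements
write_demo_report(report, "demo_report.json")
```

`autoplot()` methods cover permutation tests, training histories and
profile clusterings; `tidy()`/`glance()` give broom-style summaries.

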