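---
title: "Models and methods behind smoopr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind smoopr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

smoopr implements an integrative analysis of condensation-prone RNAs: RNAs
that are jointly enriched by a semi-extractability assay and by orthogonal
organic phase separation (OOPS), here called smOOPs. The pipeline has five
statistical components — dual-assay threshold calling, a degree-matched
permutation test of RNA-RNA proximity subnetworks, a convolutional-recurrent
classifier trained over every feature-subset combination, integrated-gradients
deconvolution of the learned features, and direct composition/protein-level
validation — plus a seeded synthetic-data generator that makes all of them
testable without sequencing data. This vignette explains each model, its
assumptions, the tunable parameters, and the numerical choices made where the
design was genuinely open.

## Dual-assay calling

A gene is called a smOOPs gene at a developmental stage when it satisfies
`padj < 0.01` and `LFC > 1` in **both** the semi-extractability and the OOPS
enrichment contrasts at that stage; the unified control set contains genes
with `padj > 0.01` and `|LFC| < 1.4` in **every** stage-assay combination.
All inequalities are strict, so boundary values fail. Genes missing a
contrast are conservatively excluded from both sets. A relaxed mode
(`lfc_min = 0`) supports replication batches with smaller effect sizes.
Granule-overlap testing uses the one-sided (upper tail) hypergeometric
distribution computed exactly (`phyper`), restricted to granule sets with at
least ten smOOPs exclusive to that granule.

The enrichment tables consumed by the caller normally come from a
differential-expression tool. The synthetic generator produces a deliberately
simple stand-in instead: replicate-level Gaussian log-intensities, a per-gene
Welch test and Benjamini-Hochberg correction across genes. This is documented
as a stand-in — it exists so the calling contract is testable, not as a
differential-expression method.

## The proximity-network null model

Intermolecular hybrid (proximity-ligation) records define an undirected,
weighted gene graph; degree is the number of distinct neighbours and all
connectivity metrics — edge density, largest-connected-component size, global
clustering (transitivity) and mean shortest path within the largest component
— are computed on the unweighted topology via igraph. High-degree nodes
connect more by chance, so focal-set connectivity is compared against random
node sets with a matched degree sequence: one node per focal degree, each
within ±1 of its target, drawn uniformly among eligible unused nodes (greedy
in random order, with restarts; an unmatchable degree raises an error rather
than silently widening the tolerance). The permutation p value uses the
add-one estimator `(1 + #{null >= observed}) / (1 + n_iter)`, which can never
be zero. The comparison is one-sided for greater connectivity; since a
*smaller* mean path length means tighter connectivity, the complementary tail
for that metric is available via `alternative = "less"`. Degree-preserving
edge rewiring was deliberately not used as a null: with high-degree focal
nodes it preserves exactly the connectivity pattern being tested.

## Feature encoding

Per-nucleotide signals are projected from genomic intervals onto
exon-concatenated transcript coordinates (intronic signal is dropped), count
tracks (crosslinks, methylation, intra-/intermolecular duplex counts) are
divided by the transcript's TPM, and binary tracks (predicted pairedness,
per-RBP peaks) are left untouched. Sequence is one-hot encoded in the fixed
channel order A, C, G, T; N becomes an all-zero column; U and T are synonyms
throughout. Channels stack in a canonical order — sequence (4), crosslinks,
methylation, intra- and intermolecular duplexes, pairedness, then one channel
per panel RBP plus one summed panel channel — and every example is padded
with −1 to the cohort's longest transcript. With all seven data layers and
the full 46-RBP panel this yields 56 channels; the summed panel channel is
included because only that width reproduces the architecture's documented
maximum parameter count (1,203,446), and the panel sum is itself an object of
interpretation downstream. Transcripts longer than 20 kb are excluded before
encoding. Splits are stratified 70:15:15 with largest-remainder
apportionment, and the minority class is oversampled with replacement within
each subset.

## The classifier

The architecture is fixed: four 1-D convolution blocks (108, 144, 192, 256
filters; kernel 9; dilations 1, 4, 16, 64; each block conv → layer
normalisation → ReLU → dropout 0.34 → max-pool 4), a bidirectional gated
recurrent layer with 128 units per direction, layer normalisation and
dropout, dense layers of 64 and 32 units (each with layer normalisation and
dropout, no additional activation — the block description lists none), and a
2-unit softmax. Convolutional, recurrent and dense kernels carry an L1+L2
penalty with λ = 1.2e−5. The recurrent parameterisation uses the reset-after
convention with separate input and recurrent bias vectors (3uc + 3u² + 6u
parameters per direction); this choice is load-bearing — it is the unique
convention under which the single-channel model has exactly 1,149,986
trainable parameters and the 56-channel model 1,203,446, the documented
extremes. Layer normalisation acts across channels at each position with
ε = 1e−3. No masking layer hides the −1 padding; the pad value flows through
the convolutions, which also means every model implicitly sees transcript
length.

The network is implemented natively in R: patch extraction (im2col), its
adjoint, max pooling and layer normalisation are small C++ kernels, matrix
products go through BLAS, and the optimizer is Adam (learning rate 1e−4,
β₁ = 0.9, β₂ = 0.999, ε = 1e−7) on a flattened parameter vector with
categorical cross-entropy. Every gradient path — all parameter blocks and
the input gradient — is verified against central finite differences in the
test suite. Training uses early stopping on validation AUROC with 20-epoch
patience and best-weights restore; `max_epochs` caps the otherwise unlimited
schedule. Batch size defaults to 32 and may be set anywhere in 8–64 (the
demo uses 8, trading per-epoch wall time for more optimizer steps). Model
performance is reported as rank-statistic AUROC on the combined validation
and test examples, which the training never saw for weight selection beyond
early stopping on validation alone.

## Powerset attribution

One model is trained per non-empty subset of the data layers (127 subsets
for seven layers), in replicates (8 in the full protocol), and the best
replicate per subset by evaluation AUROC is kept. The contribution of layer
*d* is the set of paired deltas `AUROC(S ∪ d) − AUROC(S)` over all non-empty
base subsets S not containing *d*, summarised by a two-sided one-sample
t-test against zero (the figure-level description calls this a Welch test;
for one sample the two coincide). Pairwise informational overlap compares
`AUROC(T ∪ d1 ∪ d2)` with the better of the two single additions over every
subset T of the remaining layers, including the empty set. Replicate seeds
derive deterministically from the base seed, subset index and replicate
number.

With three data layers each contribution t-test has only three paired
deltas, so its power is limited: a single under-trained model among the
seven subsets moves one delta by more than the planted effect. This is a
real property of the desk-scale protocol, discussed with the demo below.

## Integrated gradients

Attributions target the positive-class softmax output, integrated along the
straight path from an all-zeros baseline. The integral is approximated by a
Riemann sum with `steps` points (default 64; the completeness checks use
256). The quadrature is graded towards the baseline (substituting α = u² and
taking midpoints in u): layer normalisation divides by `sqrt(var + ε)`, so
when the scaled input α·x is near zero the normalised activations — and with
them the class probability — change extremely fast; measured on toy models,
more than half of the path's total variation can sit below α = 0.005, which
a uniform grid aliases. The graded grid concentrates points exactly there,
remains a Riemann approximation of the same integral, and is exact for
linear maps for any number of steps. Completeness (attributions summing to
`f(x) − f(0)`) is reported with every profile and holds within 1% at 256
steps for confidently trained models; for barely-trained models whose
near-baseline behaviour is dominated by initialisation noise the integrand
is chaotic in that window and no practical fixed grid integrates it — a
caveat inherent to attribution through normalisation layers, not a property
of the data.

Per-nucleotide importance is the channel sum (per-channel scores are kept
for the RBP-panel analysis). Profiles are standardised into 100 proportional
bins per model and stacked in fixed model order. Clustering into two groups
is agglomerative (Ward) on the correlation distance between binned profiles;
the accompanying 2-D embedding is a principal-coordinates projection of the
same distance, used for visualisation. The R environment used here has no
UMAP implementation, and clustering on the profiles' own correlation
distance (rather than on a 2-D compression of it) is the more direct reading
of "correlation as the distance metric"; a planted two-family recovery test
(≥95% agreement across five seeds) guards the choice. Constant profiles,
whose correlation is undefined, fall back to nearest-centroid assignment
with a warning.

## Composition and protein-level validation

Sequence validation bins coding transcripts into 10/50/50 proportional bins
over 5'UTR/CDS/3'UTR (or 100 bins over the whole transcript) and subtracts
the control group's mean per-bin nucleotide frequency from the target
group's; differences sum to zero within each bin by construction. Bins are
proportional (`position → floor(p·n/L)`); regions shorter than their bin
count take nearest-position values so no bin is empty. Triplet composition
uses overlapping 3-mers (stride 1, L−2 windows). Binned track medians carry
percentile-bootstrap 95% CIs over transcripts (1000 resamples by default).
Structure-contact counts per region are normalised by region length in kb
and by TPM and compared by two-sided Welch tests; global occupancy
(counts-per-million per kb of exonic length, divided by TPM) is compared by
a one-sided Wilcoxon rank-sum test — each test as used in the original
figure-level analyses.

Proteins are translated with the standard genetic code (internal stops
truncate with a warning), mass is computed from monoisotopic residue masses
plus water, and per-residue usage is each protein's relative amino-acid
frequency, so a Welch test across proteins is well-defined. Disorder
annotations are merged before computing the disordered fraction; disorder
fractions are compared by Wilcoxon, mass and optional precomputed
condensate-propensity scores by Welch. The amino-acid grouping
(charged/polar/hydrophobic/special) follows the IUPAC-conventional classes.

## The synthetic cohort

The generator emulates, at desk scale, the statistical structure the
pipeline is designed to detect. Defaults (all in `sim_config()`):

* 400 genes, 35% positive (condensation-prone), 10% non-coding
  (lncRNA/TEC biotypes).
* Region lengths are log-normal with medians 35 nt (5'UTR), 150 nt (CDS,
  rounded to codons) and 100 nt (3'UTR), truncated at their 97.5th
  percentiles so rare extreme draws do not dominate the padded tensor
  length. These are roughly a fifth of mammalian medians: the package's
  chosen working scale, keeping full powerset training runnable on a
  single CPU while leaving every planted contrast detectable. Positive-class
  CDS and 3'UTR medians are multiplied by 1.25 and 1.15 — a deliberately
  moderate planted length effect. Because the −1 padding makes length
  visible to every model, a strong length effect would let the
  noise layer's model ride on length alone and would compress the
  informative layers' AUROC headroom; the moderate effect keeps positional
  signal, not length, as the main discriminant.
* Sequence composition: the positive-class CDS is C-rich (A/C/G/T
  probabilities 0.18/0.40/0.20/0.22 versus 0.27/0.23/0.22/0.28 background),
  with milder C-enrichment in the 5'UTR. CDSs start with ATG, contain no
  internal stop and end with a stop codon, so translation is clean and the
  codon bias induces the planted amino-acid shifts (proline/serine/alanine
  up in the positive class).
* Tracks: crosslink counts are Poisson with rate proportional to TPM, with
  a 2× 3'UTR enrichment in the positive class; intramolecular duplex counts
  have a 2× CDS enrichment; the pairedness track is Bernoulli(0.5) noise —
  it carries no class signal by design and acts as the negative control
  layer in the powerset analysis. The RBP peak panel is binary, with one
  designated informative RBP whose peak rate triples in the positive class.
* The enrichment table draws LFC from N(2, 0.3) for positive and N(0, 0.3)
  for negative genes in both assays at all three stages; adjusted p values
  come from the Welch stand-in with 4 simulated replicates at noise SD 0.15,
  which makes dual-assay calling operate at ~100% sensitivity and near-100%
  specificity. Negatives whose drawn LFC happens to be non-trivial receive
  small p values and drop out of the control set — mirroring how fixed
  cutoffs exclude genes with intermediate behaviour.
* Hybrid records connect background pairs with probability 0.02 and planted
  community pairs with 0.25; counts are 1 + Poisson(1); a configurable
  fraction of records is intramolecular.

What the generator does **not** emulate: realistic secondary structure,
positional autocorrelation of crosslinking, isoform structure, expression-
degree confounding, or raw reads. Passing tests therefore demonstrate that
the statistical machinery recovers planted structure of the stated kinds at
the stated sizes — not that the pipeline's biological conclusions transfer
to any particular real dataset.

## The demo protocol and its known limits

`run_demo()` wires everything at a fixed scale: 400 genes, three data layers
(sequence, crosslinks, pairedness-noise), the 7-subset powerset with 2
replicates, batch size 8 and an 8-epoch cap, a 1999-iteration permutation
test, and 8-step integrated gradients on the two strongest single-layer
models. On one CPU this completes in roughly a quarter of an hour, with
powerset training dominating.

Two desk-scale caveats are worth stating plainly. First, at an 8-epoch cap
and learning rate 1e−4 the models retain replicate variance in AUROC of
several hundredths; best-of-2 selection absorbs only part of it. Second —
and more fundamentally — with three data layers the per-layer contribution
t-test has exactly three paired deltas, so it can only reach p < 0.05 when
all three deltas are nearly identical (|t| > 4.3 at 2 degrees of freedom).
Two effects preclude that reliably: subsets containing the noise layer
converge worse than their noise-free counterparts (extra input noise
genuinely hurts under-trained models — the same qualitative behaviour the
source analyses report for in-silico structure predictions), inflating one
delta; and once the informative layers converge, AUROC saturation compresses
the info-over-info deltas towards zero, deflating another. The demo
therefore demonstrates planted-signal recovery through the best-model AUROC
and the direct composition statistics, while its per-layer contribution
p values for the informative layers typically remain above 0.05; the
noise layer's contribution stays non-positive throughout. The full-scale
protocol (7 layers, 8 replicates, unlimited epochs, 31-63 deltas per
t-test) does not share this power limitation; the demo documents it rather
than hiding it.

## Reproducibility

Every stochastic routine takes an explicit integer seed; stage seeds derive
from the master seed by a fixed hash, so a serialized config fully
determines every output, including training trajectories (pure-R RNG,
deterministic BLAS ops). The test suite regenerates all fixtures from code;
no binary data ships with the package.
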