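---
title: "Classifying phage lifestyle from metagenomic fragments: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying phage lifestyle from metagenomic fragments: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phagelife)
```

## The problem

Bacteriophages fall into two lifestyles. Virulent phages replicate only
lytically, killing the host on infection; temperate phages can additionally
integrate into the host chromosome as prophages and replicate passively
until induced. The balance between the two shapes microbial communities,
and shifts in that balance — prophage induction in particular — have been
linked to dysbiosis in the human gut. Metavirome sequencing recovers huge
numbers of phage contigs, but most have no homolog in reference databases,
carry few or no recognizable marker genes, and are far too short for
proteome-scale classifiers. The question this package answers is therefore
posed per fragment: *given one DNA contig or read, does it derive from a
virulent or a temperate phage?*

The signal that makes this answerable is compositional. Temperate phages
spend long residence times inside host chromosomes and ameliorate toward
host sequence signatures, while virulent phages do not; the two classes
therefore differ in local k-mer statistics even at sub-gene scales. A
convolutional network over the raw one-hot encoded sequence can exploit
these local signatures — each convolution kernel is in effect a learned
position-weight matrix — without requiring assembled genomes, gene calls or
database hits.

## Sequence representation

A sequence of length $L$ becomes an $L \times 4$ indicator matrix $X$ with
column order T, G, C, A: A = $(0,0,0,1)$, C = $(0,0,1,0)$, G = $(0,1,0,0)$,
T = $(1,0,0,0)$ (`one_hot_encode()`). Two conventions are ours, because the
representation must be total:

* **Ambiguity codes** (N and the other IUPAC letters) encode as all-zero
  rows. An all-zero row contributes nothing to any kernel response, which
  is the natural reading of one-hot encoding as a 1-mer indicator; no base
  is imputed.
* **Padding** to the group input length is all-zero rows appended on the
  3′ (right) end, so coordinate 0 stays aligned with the sequence start
  for motif detection. Padding rows are indistinguishable from ambiguity
  rows by design: both mean "no evidence here".

Sequences are scored on the given strand; forward and reverse-complement
scores are not averaged. Nothing in the architecture enforces strand
symmetry, and averaging would silently halve the resolution of any
strand-biased signal, so the choice is left to the caller.

The ablation front end uses k-mer frequency vectors
(`kmer_frequencies()`): all overlapping windows of length $k$ consisting
only of A/C/G/T, counted and normalized by the number of counted windows.
Windows containing ambiguity codes are skipped, not imputed, so the vector
stays a proper frequency distribution over observed words.

## The network

One model per fragment-length group, four groups in total, with input
lengths $L \in \{400, 800, 1200, 1800\}$. Each model is the eight-layer
stack

$$\mathrm{Conv1D} \to \mathrm{Maxpool} \to \mathrm{BN_1} \to
  \mathrm{Dropout} \to \mathrm{GlobalAvgPool} \to \mathrm{Dense_1} \to
  \mathrm{BN_2} \to \mathrm{Dense_2}$$

with, for kernel $f$ at position $l$:

$$Y^{C}_{l,f} = \mathrm{ReLU}\Big(\sum_{m=0}^{M-1}\sum_{n=0}^{3}
  W^{f}_{m,n}\, X_{l+m,n} + b^{C}_f\Big), \qquad l = 0,\dots,L-1$$

followed by max pooling with window $S_1$ and stride $S_2$, batch
normalization, dropout with proportion $P$, global average pooling to one
value per channel, a ReLU dense layer with $R$ units, a second batch
normalization, and a single sigmoid output unit producing the score
$y^{D2} \in (0,1)$. Virulent is the positive class: scores near 1 mean
virulent, near 0 temperate.

Defaults are $F = 64$ kernels of width $M = 6$, $S_1 = S_2 = 3$,
$P = 0.3$, $R = 64$.

### Numerical conventions the equations leave open

* **Convolution padding.** The index range $l = 0,\dots,L-1$ with terms
  $X_{l+m}$ requires values beyond the sequence end; we zero-pad on the
  right so the output length stays exactly $L$.
* **Pooling remainder.** None of the four input lengths is such that all
  pooling windows fit for arbitrary $S_1$; a trailing window that would
  overrun the end is dropped, giving pooled length
  $L' = \lfloor (L-S_1)/S_2 \rfloor + 1$, which equals
  $\lfloor L/S_2 \rfloor$ when $S_1 = S_2$.
* **Dropout** uses the inverted convention: kept activations are rescaled
  by $1/(1-P)$ at training time, so inference is exactly the identity.
  What matters for prediction is the inference contract; the rescaling
  preserves expected activation magnitude during training.
* **Batch normalization** at inference uses running moments accumulated
  during training with momentum 0.99 and variance floor
  $\epsilon = 10^{-3}$ (both configurable in `network_config()`); training
  batches are normalized with their own biased statistics.
* **Initialization** is Glorot-uniform, seeded.

Every one of these choices is covered by tests that compare the production
(compiled) forward pass against a plain nested-loop oracle written
directly from the formulas above; the two must agree to $10^{-5}$ at all
four input lengths.

### Ablation variants

`network_config(variant = ...)` builds five reduced architectures used to
attribute performance: `kmer4` (4-mer vector straight into the dense
stack, no convolution), `no_maxpool`, `no_dropout`, `no_globalpool`
(flattening instead of averaging, which multiplies the dense input
dimension by $L'$), and `no_bn` (both normalization layers removed).
`run_ablation()` trains all requested variants on an identical benchmark
with identical seeds.

## Training

`train_model()` fits with Adam (learning rate $10^{-4}$), binary
cross-entropy and batch size 32. Epoch budget and stopping are not part of
the published settings and are ours: at most `max_epochs` (default 100)
with early stopping after `patience` (default 10) epochs without
validation-loss improvement, returning the weights of the best epoch.

The validation split is drawn at the *genome* level — 10% of training
genomes per class, never fragments — for the same reason the test folds
are: fragments of one genome are highly correlated, and a fragment-level
split would leak. Class balance is handled where the corpus is built
(balanced fragment sampling in `build_benchmark()`), not by loss
weighting, so the loss stays the plain published objective.

All randomness (initialization, validation split, epoch shuffles, dropout
masks) derives from R's RNG seeded by `train_spec()$seed`; under the
single-threaded contract a rerun reproduces the training log and weights
bit for bit.

## Prediction routing and the uncertainty cut-off

`route_and_score()` maps arbitrary input lengths onto the four models:

* 100–1,800 bp: padded and scored by the model of its group. Group
  boundaries are half-open — $[100,400)$, $[400,800)$, $[800,1200)$,
  $[1200,1800]$ — because the printed ranges touch at their endpoints and
  every length must map to exactly one group; the top endpoint is closed
  so a 1,800 bp sequence is scored directly rather than split.
* under 100 bp: scored by the group A model.
* over 1,800 bp: split into non-overlapping 1,800 bp pieces plus a
  remainder (`split_long_sequence()`); each piece is scored by its own
  length's model (a remainder under 100 bp again falls to group A) and the
  sequence score is the length-weighted mean of piece scores
  (`combine_scores()`).

`classify()` labels a score virulent above $0.5 + t/2$, temperate below
$0.5 - t/2$, and `"uncertain"` inside the open band, with cut-off $t = 0$
by default (report everything) and $t = 0.5$ — ignore scores in
$(0.25, 0.75)$ — recommended when precision matters more than yield. A
score of exactly 0.5 is labelled uncertain at every $t$, including 0: the
decision rule is defined by strict inequalities and we refuse to coerce
the undefined case.

## Evaluation

With virulent as positive: $Sn = TP/(TP+FN)$, $Sp = TN/(TN+FP)$,
$Acc = (TP+TN)/(TP+TN+FP+FN)$. Uncertain predictions are excluded from the
counts and reported separately; default evaluation uses $t = 0$ so nothing
is excluded. AUC is computed as the normalized Mann–Whitney $U$ statistic
with ties counting one half — exact and checkable by pairwise enumeration,
with no threshold grid.

`make_cv_folds()` partitions curated genomes into folds stratified by
lifestyle (the published description fixes only the genome-level rule;
stratification is ours, to avoid degenerate folds under class imbalance).
Auto-labelled genomes, whose annotations are bioinformatic rather than
curated, never enter a test fold. `run_cross_validation()` re-audits every
fold for genome disjointness at run time.

## The synthetic benchmark: what it emulates and what it does not

Real training corpora for this problem require hundreds of annotated phage
genomes. To make the package testable end to end without downloads,
`synthetic_benchmark()` generates two genome classes from order-1 Markov
chains (`generate_synthetic_genomes()`):

* the **virulent** class has every transition row
  $(A,C,G,T) = (0.30, 0.20, 0.20, 0.30)$ — AT-rich at GC 0.40, typical of
  virulent phage genomes;
* each **temperate** row is the virulent row mixed 85:15 with the
  GC-biased row $(0.05, 0.45, 0.45, 0.05)$, emulating amelioration toward
  a GC-richer host chromosome.

The default corpus is 20 genomes of 50 kb per class. The mixture emulates
exactly one property of real data — a diffuse, genome-wide compositional
difference between classes, the same property the k-mer feasibility
analysis of real phage genomes rests on. It does **not** emulate gene-scale
motif structure, mosaicism from recombination, sequencing error (fragments
are exact substrings; the extraction step reproduces MetaSim's uniform
fragment sampling, not its error models), the 77:148 class imbalance of
the curated corpus, or inter-genome diversity within a class. Passing the
built-in benchmark therefore demonstrates that the full pipeline —
simulation, leakage-free splitting, training, routing, evaluation —
recovers a planted compositional signal; it does not certify accuracy on
real viromes, for which the published full-scale corpus remains necessary.

Problem sizes used by the packaged experiments (tests and
`scripts/acceptance.R`): the headline parameter-recovery run uses two-fold
genome-level cross-validation on group D with 4,000 training and 1,000
test fragments per fold and at most 8 epochs — the signal is strong enough
that validation loss plateaus within a handful of epochs, so a longer
schedule buys nothing; the group A trend runs use 1,200/400 fragments and
6 epochs. Default corpus sizes in `build_benchmark()` are 8,000/2,000 per
group, one tenth of the published 80,000/20,000 design, and are parameters
throughout because the published counts are not fully explicit about
per-group versus total accounting.

## Cohort analysis

`summarize_sample()` reduces one sample's prediction report to its
temperate proportion $n_t/(n_t+n_v)$, uncertain calls excluded. Whether
published proportions of this kind are contig-count or base-pair weighted
is ambiguous; we default to per-contig counts — the estimand is "what
fraction of distinct phage sequences are temperate", robust to assembly
fragmentation — and expose `length_weighted = TRUE` for the base-pair
reading. `compare_groups()` performs the two-sided Wilcoxon rank-sum test
with the Hodges–Lehmann location-shift estimate and confidence interval,
exact for group sizes up to 12 per side without ties (verified against
exhaustive permutation enumeration) and normal-approximated with
continuity correction otherwise.

## Limitations

The classifier assumes its input *is* phage; it does not screen out
bacterial, eukaryotic-viral or host contigs, and upstream phage
identification is the caller's responsibility. Scores on sequences shorter
than ~100 bp lean on the group A model outside its training range and
should be treated as weak evidence. The compiled trainer is single-threaded
by design (determinism over speed); full-scale corpora are hours, not
minutes. And because the built-in generator plants a purely compositional
signal, ablation results on synthetic data can rank variants differently
than real data would — the `kmer4` variant in particular is handicapped far
less by a Markov-chain benchmark than by real phage sequence.
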