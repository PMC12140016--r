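---
title: "Identifying transcriptional-infidelity regions from DNA context: models and methods"
author: "ttiri package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying transcriptional-infidelity regions from DNA context}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Transcriptional infidelity denotes RNA-DNA sequence differences beyond
classical RNA editing: genomic positions where the transcribed RNA deviates
from its DNA template. In hybrid polyploid lineages these events occur orders
of magnitude more often than the usual transcriptional error rate, and the
question this package addresses is whether the *local DNA context* predicts
where they happen — and, if it does, which sequence motifs carry that signal.

`ttiri` implements a two-layer classifier over 200 nt genomic windows: a
sequence-level head that decides whether a window contains any infidelity
site, and a subregion-level head that localizes the signal to groups of
adjacent tokens. An attribution stack then quantifies which hexamers,
transcription-factor binding motifs, and TF families/classes drive the
predictions at each position around a site.

## Data model and datasets

Candidate positive windows are extracted by sliding a 200 nt window with a
10 nt step across the whole genome and keeping windows containing at least
one infidelity site. Candidate negatives use the same sliding scheme but are
restricted to coding intervals and to windows containing no site. The
asymmetry is deliberate: many coding intervals are shorter than the window,
and sites inside them would be lost if positives were also restricted to
coding regions — so the package replicates it even on synthetic data.
Windows containing undetermined bases ('N') are removed, 10,000 windows per
class are sampled uniformly without replacement, and the balanced set is
split 8:1:1 into train/validation/test, stratified by label.

For interpretation, a separate dataset centers each sequence on a site:
100 nt of flank on each side, 201 nt total, with the site at 0-based offset
100. Sites closer than one flank to a contig edge are excluded rather than
padded, because the perturbation arithmetic below assumes every position
holds real sequence. Negatives are site-free coding windows of the same
width. The model used for attribution is retrained on this set at the
sequence level only; the two-layer checkpoint is not reused.

### Subregion ground truth

The training data defines subregion labels by token-span overlap: subregion
$t$ merges $m$ adjacent tokens (CLS excluded), its label is 1 exactly when
the union of its tokens' character spans overlaps a site, and it is *valid*
(enters the loss) only when at least one merged token is a real sequence
token rather than SEP/PAD. This is the only definition consistent with
identifying infidelity regions at nucleotide resolution, and it guarantees
the invariant — tested for many $m$ — that the sequence label equals the OR
of the valid subregion labels.

## Tokenization

Sequences are tokenized with byte-pair encoding learned from the corpus
itself: starting from the single-character alphabet, the most frequent
adjacent token pair is merged repeatedly until the vocabulary holds 4096
tokens or no pair occurs twice. Two policies are fixed for determinism:
frequency ties merge the lexicographically smallest concatenated string, and
encoding applies merges greedily in learned order. On uniform DNA a
4096-token vocabulary yields a mean token length near 5 nt, so a 200 nt
window compresses to about 40 effective tokens — the statistic the
acceptance script recomputes. The model input is CLS + tokens + SEP, padded
with PAD to a fixed $n_t = 60$; sequences that tokenize longer raise an
error rather than being truncated, since truncation would silently drop
labeled nucleotides. The 4096 target counts non-special tokens; if an
external vocabulary counts its specials inside the budget, the two differ by
four tokens (the plain-text loader lets such a vocabulary be substituted).

## Model

Each token id is embedded into $d_h$ dimensions and passed through a stack
of post-norm transformer encoder blocks (multi-head self-attention, then a
GELU feed-forward of width $4 d_h$, each with residual connection and layer
normalization). Position is injected through ALiBi: head $i$ of $h$ adds the
bias $B_i[q,k] = -2^{-8i/h}\,\lvert q-k\rvert$ to its attention logits.
Because the encoder is bidirectional, the distance penalty is symmetric
(non-causal); this is the conventional encoder form of ALiBi. PAD positions
are masked out of the attention keys.

Two heads read the final hidden states. The sequence head applies a linear
layer and sigmoid to the CLS state. The subregion head first merges the
non-CLS token states in non-overlapping windows of $m$ tokens:
$$M^m = \mathrm{Concat}(\mathrm{Mean}(M^t, m), \mathrm{Max}(M^t, m))\,W^C,$$
with a partial final window kept, then scores each merged row with a linear
layer and sigmoid. Pooling excludes PAD rows (a window of $m$ tokens may mix
real tokens with padding): this keeps every valid subregion's probability —
and the sequence probability — exactly invariant to PAD token content, a
property the tests check bitwise. SEP participates in pooling (its embedding
is constant) but never makes a subregion valid.

### Losses

The sequence level uses plain binary cross-entropy. The subregion level is
heavily imbalanced, so valid positive subregions are up-weighted by the
batch ratio $w$ of valid negatives to valid positives (or, in an
all-negative batch, by the count of valid negatives):
$$\ell_{token} = \frac{-\sum_{i,t} V_{i,t}\,\big(w\,y_{i,t}\log p_{i,t} +
(1-y_{i,t})\log(1-p_{i,t})\big)}{\sum_{i,t} V_{i,t}}$$
The training objective is the convex mix
$\mathcal{L} = \lambda\,\ell_{sequence} + (1-\lambda)\,\ell_{token}$ with
$\lambda = 0.2$ by default: the subregion task is the harder one and gets
the larger share. Probabilities are clamped to $[10^{-7}, 1-10^{-7}]$
inside every logarithm and logit, so losses and attribution scores stay
finite even for saturated predictions. $\lambda = 1$ is accepted as an
internal override that trains the sequence head only (used for the
interpretation model); the exported combined loss enforces
$\lambda \in (0,1)$.

### Architecture parameters

| parameter | full scale | tiny preset | meaning |
|---|---|---|---|
| $d_h$ | 768 | 64 | hidden size |
| layers | 12 | 2 | encoder blocks |
| $h$ | 12 | 4 | attention heads ($d_k = d_h/h$) |
| $n_t$ | 60 | 60 | tokens per sequence |
| $m$ | 20 | 20 | tokens per subregion |
| $\lambda$ | 0.2 | 0.2 | loss mix |

With $n_t = 60$ and $m = 20$, a sequence has
$\lceil (n_t - 1)/m \rceil = 3$ subregions, of which typically two are valid
(about 40 real tokens): a 200 nt window splits into roughly two ~100 nt
subregions. The tiny preset trains from scratch in minutes on one CPU and is
used throughout the tests; nothing in the code depends on the preset.

### Training recipe

The paper-lineage models are pretrained; this package trains from scratch,
so the recipe is its own design: AdamW ($\beta = 0.9/0.999$, decoupled decay
0.01 on weight matrices), linear warmup over the first 5% of steps followed
by linear decay, batch size 32, peak learning rate $3\times10^{-4}$ for the
tiny preset ($10^{-4}$ recommended at full scale), early stopping on
validation sequence-level AUROC with the best checkpoint kept. The whole
loop — forward, analytic backward, optimizer — is implemented in
RcppArmadillo; its gradients are verified against central finite differences
and its losses against the exported R definitions, which are in turn tested
against scalar-loop oracles.

Numerical details: layer-norm $\varepsilon = 10^{-5}$; the GELU is the
sigmoid-weighted form $x\,\sigma(1.702x)$; max-pool gradients follow the
first maximal row on ties; all randomness (shuffling, dropout, replacement
draws) flows from explicit integer seeds, so two runs with one seed produce
identical histories.

## Evaluation

Sequence-level performance is AUROC in its Mann-Whitney form (ties count
one half) — appropriate because the dataset is balanced. Subregion-level
performance is the area under the precision-recall curve computed as
step-interpolated average precision over unique thresholds — appropriate
because subregion labels are imbalanced, and conservative relative to
trapezoidal interpolation. Subregion scores are pooled over all valid
subregions of all test sequences (per-sequence macro-averaging is available
behind a flag). Both metrics are tested against quadratic-time brute force.

## The synthetic benchmark

No real infidelity data ship with the package, so every claim is exercised
on simulated genomes. The simulator draws i.i.d. bases at a configurable GC
content, places sites as independent Bernoulli draws per position, lays
down disjoint coding intervals (alternating exponential interval and gap
lengths tuned to the coding fraction, intervals clipped to 60-5000 nt,
mean 600 nt — so a realistic share of coding intervals is shorter than one
window), and optionally writes a planted motif at a uniform offset from
each selected site. The default site density, 2 per kb, is the genome-wide
rate implied by millions of sites over a gigabase-scale genome.

The planted-motif benchmark (`plantedMotifBenchmark()`) uses 10 contigs of
200 kb, CACCTG planted with probability 0.8 at offsets within ±10 nt of a
site, and site density 6 per kb. The density is deliberately above the
default, for an identifiability reason that can be computed before any
training: in this simulation the *only* signal separating positive from
negative windows is the planted motif. With window rate
$\lambda_w = 200 \times$ density, a positive window carries at least one
site and each site plants a motif with probability 0.8, so at 2 per kb the
probability that a positive window shows the motif is about 0.81 while a
negative window shows a chance CACCTG with probability about 0.047 — a classifier reading exact-motif counts tops out
near AUROC 0.88. At 6 per kb the same calculation gives roughly 0.93 (a
trained model can sit slightly above it by exploiting partial-motif
context that the count statistic ignores), high enough that a sound
implementation clears 0.90 with margin while negatives (site-free coding
windows) remain abundant. The benchmark therefore tests the implementation,
not the luck of the draw.

What the simulator does *not* emulate — and what passing tests therefore do
not show about real genomes: sequence composition is i.i.d. (no repeats,
no isochores, no codon structure), sites are placed uniformly with no
clustering and no substitution-type identity, the planted motif is a single
exact string rather than a binding-energy landscape, and homeologous
subgenomes are absent. Results on this benchmark validate the machinery;
biological conclusions require real site calls.

## Attribution stack

For a 201 nt site-centered sequence $S$ with model probability $P(S)$, the
hexamer at each position $j \in [1, 196]$ is replaced $C = 100$ times by
hexamers drawn uniformly from the 4095 alternatives, and
$$IS^{hexamer}_j = V \cdot \mathrm{median}_k\,\big(\mathrm{logit}(P(S)) -
\mathrm{logit}(P(S^{(k)}_j))\big),$$
where $V = 1$ only if the sequence is correctly predicted positive
($P(S) \ge 0.5$); incorrectly predicted sequences contribute all-zero
tracks. The median over 100 draws makes the score robust to the occasional
replacement that recreates the disrupted signal. Drawing from the 4095
non-identical hexamers (rather than all 4096) guarantees a genuine
perturbation; draws are seeded per sequence.

TF-level importance averages the hexamer scores whose 6 nt windows fit
inside a motif footprint of length $L_n$ starting at $j$:
$IS^{TF}_{j} = \frac{1}{L_n-5}\sum_{k=0}^{L_n-6} IS^{hexamer}_{j+k}$
(motifs shorter than 6 nt are skipped — the window mean is undefined).
Binding sites come from PWM scanning: JASPAR count matrices are normalized
with pseudocount $\alpha = 0.5$ against the uniform background 0.25,
log-odds scores are summed over the footprint, standardized with a sigmoid,
and kept when the standardized score reaches 0.999. That cutoff is
algebraically a raw-score threshold of $\ln 999 \approx 6.91$ *independent
of motif length*, which favors long motifs; the package implements the rule
literally and flags the bias here. Only the forward strand is scanned by
default (site calls are strand-resolved upstream in real pipelines).

Family- and class-level tracks are binding-count-weighted means over all
valid sequences and member TFs per position; positions never bound are
reported as missing, not zero. For display, tracks are smoothed with a
centered triangular kernel of half-width $\lfloor\mathrm{window}/2\rfloor$
(window 10 by default), renormalized at the edges, with missing values
excluded from numerator and weight sum. The three report filters rank
groups by best single position (max), cumulative importance (sum), and
everywhere-positive binding (min > 0). A k-mer composition report
(mono/di/tri-nucleotide proportions and signed rank changes between
sequence sets, overlapping counts) provides the model-free cross-check.

## Problem sizes used by the test suite

The suite trains the tiny preset on the planted-motif benchmark at the full
balanced size (10,000 windows per class, 2 epochs), retrains the
sequence-level interpretation model on 10,000 + 10,000 centered sequences,
runs the perturbation analysis on 6 correctly predicted motif-bearing
sequences (about 1,100 background positions), ranks the planted motif
against 24 decoys, and reproduces the direction of the window-length and
$\lambda$ sweeps at 1,500 windows per class and 2 epochs per point. The
tokenizer statistic is checked on a 1 Mb corpus and 2,000 windows in the
suite, and on the full 5 Mb / 10,000-window setting by
`scripts/acceptance.R`. These sizes are the package's choice of a
desk-scale replica: large enough that every qualitative claim is exercised
with stable statistics, small enough to run routinely.

## Known limitations

* Subregion resolution is bounded by $m$ tokens (~100 nt at the defaults);
  single-nucleotide attribution comes only from the perturbation stack.
* Overlapping training windows (step 10 < window 200) share sites between
  candidate windows; the balanced sample keeps all candidates before
  sampling, so a site can inform both train and test windows. The split is
  honest at the window level but not leakage-free at the site level — at
  benchmark scale this is immaterial, for real use a site-level split would
  be the safer design.
* The vocabulary is retrained per corpus rather than imported, so token
  boundaries — and thus subregion boundaries — are corpus-dependent.
* Reverse-strand motif hits are off by default; enable a
  reverse-complement pass by scanning the reverse complement explicitly if
  strand-ambiguous calls are expected.
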