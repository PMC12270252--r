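---
title: "Modelling template-free CRISPR-Cas9 repair outcome profiles"
author: "crisprOutcomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling template-free CRISPR-Cas9 repair outcome profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crisprOutcomes)
```

## The problem

When Cas9 cuts DNA without a donor template, the cell repairs the blunt
double-strand break by non-homologous end joining (NHEJ) or
microhomology-mediated end joining (MMEJ). The repair products — small
deletions and insertions at the cut — are stochastic but strongly
sequence-dependent, so the frequency distribution over repair outcomes
("repair outcome profile") of a given target can be predicted from its
sequence. Accurate profiles help choose guide RNAs that favour a desired
edit, most prominently frameshifts for gene knockouts.

`crisprOutcomes` models this with three cooperating submodels over an
explicitly enumerated outcome space, adapts trained models to new cellular
domains with transfer learning, and explains individual predictions with
exact Shapley attributions.

## The outcome space

All coordinates are cut-relative, 0-based and half-open: position 0 is the
first base downstream of the blunt cut, which falls 3 bp upstream of the
NGG PAM (between positions 17 and 18 of the 20-nt protospacer). Every
target is standardized to a 60 bp window with the cut after base 30.

**Deletions.** We enumerate every interval $[s, e)$ with
$-30 \le s \le 0 \le e \le 30$ and $1 \le e - s \le 30$ — all deletions up
to 30 bp that overlap the cut or touch it from either side; on a 60 bp
window this gives 495 candidate intervals. Two intervals produce the same
repair product exactly when the deleted segments are shifts across a
flanking microhomology (MH), so intervals are grouped by product-string
identity. Each group is one *deletion outcome*; its canonical alignment is
the leftmost (PAM-distal) interval, and the MH length is

$$M = (\text{number of equivalent alignments}) - 1,$$

which ties the MH annotation to the grouping by construction rather than
by a separate seed-and-extend scan. The five features of an outcome with
canonical interval $[s, e)$ and deletion length $D = e - s$ are:

| feature | definition | MH-less value |
|---|---|---|
| $M$ (MH length, bp) | alignments $- 1$ | 0 |
| $F$ (MH GC fraction) | GC fraction of the MH copy | 0 |
| $G$ (gap, bp) | $D - M$ | $D$ |
| $L$ (left edge, bp) | $s + M$ | $s$ |
| $R$ (right edge, bp) | $e$ | $e$ |

Integer features are used as-is — no one-hot binning — which is what makes
per-feature attributions meaningful.

Design points that the definitions leave open, and the choices made here:

* *Perfect tandem repeats.* A full-repeat deletion (e.g. any deletion in a
  homopolymer) has $M = D$ and therefore $G = 0$, below the nominal
  $G \ge 1$ range of MH-based deletions. We keep $G = D - M$ unclamped;
  the poly-A window (one outcome per deletion length, $G = 0$) is part of
  the test suite.
* *MH spanning the cut.* $L$ and $R$ are not clamped into
  $[-30, 0]$/$[0, 30]$; values outside the nominal range are kept.
* *Eligibility.* $s \le 0 \le e$ admits deletions that merely touch the
  cut from either side, the broadest reading of "overlapping or adjacent".

**Insertions.** A fixed catalogue of 21 outcomes: the 4 single-nucleotide
and 16 dinucleotide insertions plus one category for insertions of
$\ge 3$ bp, in canonical order (A, C, G, T; AA..TT; `3+`).

## The prediction model

Three submodels compose the predicted profile:

1. **Deletion model** — a fully connected network $5 \to 16 \to 16 \to 1$
   with sigmoid activation at every layer scores each deletion outcome
   independently from $(M, F, G, L, R)$; per-target sum-normalization of
   the scores gives the deletion-conditional distribution $q_i = s_i / S$.
2. **Insertion model** — softmax regression over the 21 insertion outcomes
   from the one-hot mono- plus dinucleotide encoding of the 6 nt directly
   upstream of the PAM ($4\cdot6 + 16\cdot5 = 104$ binary features).
3. **Deletion–insertion model** — a 2-class softmax regression from the
   encoded 20-nt protospacer ($4\cdot20 + 16\cdot19 = 384$ features)
   predicting the overall deletion:insertion split.

The full profile scales the first two by the third and concatenates; it is
a valid distribution for arbitrary finite parameters (a uniform fallback
guards the degenerate case where all scores underflow an
$\varepsilon = 10^{-12}$ floor, the same floor used inside log terms).

## Training

Adam with $\beta_1 = 0.99$, $\beta_2 = 0.999$, batch size 200 targets,
per-epoch exponential learning-rate decay $\gamma = 0.999$, and L2
regularisation. Two deletion-model variants:

* **KLD** (learning rate 0.05): Kullback–Leibler divergence between the
  observed deletion-conditional frequencies and the normalized predicted
  distribution, with gradients flowing through the normalization.
* **MSE** (learning rate 0.01): each outcome's raw sigmoid score
  regresses the observed conditional frequency *max-normalized per
  target*, $p_i / \max_t p$. Two numerical facts force this formulation.
  First, the sum-normalization is scale-invariant, so an MSE loss applied
  after it leaves the overall score scale as a loss-null direction;
  adaptive-step optimisers drift along it into sigmoid saturation and
  never leave the uniform plateau. Second, raw conditional frequencies on
  300–500-outcome targets are all $\sim 10^{-3}$, pinning a raw-frequency
  regression in the sigmoid's flat tail. The max-normalized target spans
  $(0, 1]$, keeps gradients healthy, and recovers exactly the same
  predicted distribution after normalization, since
  $q \propto p / \max p$. Fresh MSE training additionally initializes the
  output bias at the base rate (logit of the mean target), avoiding large
  early updates that can saturate the hidden layers; weight matrices use
  seeded Gaussian initialization with $\mathrm{sd} = 1/\sqrt{\text{fan-in}}$.

The deletion net trains against deletion-conditional frequencies
(renormalized over deletion outcomes); composition with the ratio model
reconstructs the full profile. The linear submodels train on MSE with a
200-epoch cap and early stopping at patience 2 on a 10% seeded validation
split; the deletion net keeps the best-validation-epoch parameters within
its epoch budget (default 100). `crossValidate()` selects hyperparameters
(default grid: `l2_lambda` in {0, 1e-5, 1e-4, 1e-3}) by lowest mean loss
over 5 target-disjoint folds, ties broken by grid order.

The MSE variant converges more slowly than KLD (its gradient signal is
weaker once the base rate is fitted), so the package's synthetic
benchmarks give it 200 epochs against KLD's 60.

## Transfer learning

`adaptModel()` implements six strategies relative to a source-trained
bundle: SO (use the source model unchanged), TO (train from random
initialization on target samples only), FT (fine-tune all weights at a low
rate, default retrain rate / 10), and PF0–PF2 (retrain with 0, 1 or 2
frozen hidden layers, then fine-tune; frozen layers stay frozen in both
phases and are bitwise unchanged afterwards). Freezing refers to the
deletion net's hidden layers in forward order; the output layer is never
frozen. The linear submodels have no hidden layers, so every strategy
reduces to continued training for them. Target sample sets follow a nested
schedule (each size is a prefix of one seeded permutation), with
$n \in \{2, 5, 10, 20, 50, 200, 500\}$ as the standard grid.

## Evaluation

* **JSD** — the Jensen–Shannon *distance*: square root of the divergence
  with base-2 logarithms against the midpoint, symmetric and bounded in
  $[0, 1]$ so values are comparable across targets with different outcome
  counts. `jsd((1,0), (0.5,0.5)) = 0.5579`.
* **Pearson r and MSE** per target over the frequency vectors (Pearson is
  reported for completeness despite the sum-to-one dependence between
  outcome frequencies).
* **Precision-X%** for $X \in \{20, \dots, 70\}$: a target is positive
  when its modal outcome frequency is $\ge X\%$; predicted labels
  threshold the raw predicted maximum. Precision, recall and MCC come from
  the resulting confusion matrix; zero-denominator ratios are reported as
  `NaN` with a count rather than silently dropped.
* **Six aggregate tasks** — deletion, 1 bp insertion, 1 bp deletion,
  1 bp frameshift, 2 bp frameshift, and total frameshift frequency. The
  frameshift class of an outcome is its net length change mod 3
  ($+$length for insertions, $-D$ for deletions, so a 1 bp deletion is a
  2-frameshift); the `3+` insertion category contributes a representative
  length of 3 (in-frame) by default. The alternative reading of "1 bp
  frameshift" (frameshifts caused by 1 bp events) is not used.

## Explanations

For the deletion net the 5-feature space makes exact Shapley values
affordable: all $2^5$ coalitions are enumerated, with absent features
marginalized by averaging the network's raw score over background rows
(default 10,000 sampled deletions at full scale; far fewer in tests).
Efficiency — attributions summing to the instance score minus the mean
background score — holds to machine precision. The linear submodels get
closed-form attributions on the class logit scale,
$w_{j,c}(x_j - \bar b_j)$. Per-position nucleotide and dinucleotide values
are recovered by summing the attributions of all 4 (or 16) encoding bits
at the position; the per-target renormalization layer is outside
attribution scope.

## The synthetic screen generator

Real screens are unavailable offline, so `simulateScreen()` generates
fully synthetic ones whose statistical structure matches what the model
assumes: deletion outcome propensity is log-linear in the five features
($\log \varphi = a M + e F - b G - c |L| - d R$ plus an MH-less offset),
single-base insertions preferentially re-insert the base immediately
upstream of the cut, and reads are multinomial at a configurable depth
(default 2,000 per target, comfortably above the 100-mutated-read filter;
a depth-50 mode exercises the filter). Reads of an MH-based outcome are
scattered uniformly over its equivalent alignments, so profile building
must traverse the grouping logic. Domain shifts (`mh_boost`,
`long_del_shift`, `insertion_suppress`) perturb the law in the directions
repair-pathway mutants are known to move (MH-favouring, 10–16 bp-favouring,
insertion-poor); magnitude 0 is the identity. Default weights
($a = 0.35$, $e = 0.15$, $b = 0.10$, $c = d = 0.12$, offset $-1.0$,
deletion balance 0.8) give realistic-looking profiles: mass concentrated
near the cut, ~330–480 deletion outcomes per target, modal MH-based
outcomes.

What passing on synthetic screens shows — and what it does not: the
log-linear law is exactly representable by the deletion net, so synthetic
recovery demonstrates that enumeration, featurization, optimisation,
composition and evaluation are correct, not that the architecture
captures real repair biology; real screens carry sequence biases,
overdispersion and artefacts the generator deliberately omits.

## Benchmark problem sizes

The package's standard synthetic benchmark (used by the acceptance script
and the heavier tests) simulates 650 targets at depth 2,000, trains on
500 and tests on 150; the transfer benchmark adapts to an `mh_boost`
(magnitude 1) domain with $n = 50$ target samples over 5 seeds, evaluated
on ~60 held-out targets per seed. Typical results: mean test JSD ~0.24
(KLD) and ~0.27 (MSE) against ~0.70 for the uniform baseline; PF0
adaptation ~0.21 versus ~0.28 for target-only training.

## Known limitations

* The deletion model sees only the five outcome features; sequence
  context outside MH composition and position is invisible to it.
* Events must already be called (target id, interval or inserted
  sequence, count); read processing and indel calling are out of scope,
  as are deletions longer than 30 bp and compound indels.
* Near-duplicate screening across train/test splits uses Hamming distance
  on standardized windows, not full alignment.
* The MSE variant, while stable under the max-normalized formulation,
  remains slower to converge and slightly weaker than KLD on concentrated
  profiles.
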