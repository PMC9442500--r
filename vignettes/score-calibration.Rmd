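---
title: "Alignment-free k-mer comparison and score calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Alignment-free k-mer comparison and score calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kmerscore)
```

## The problem

An alignment-free comparison of two sequences reduces them to k-mer count
vectors and returns a single number. Unlike an alignment, that number
carries no biological context on its own: a score of 0.7 is neither good
nor bad until it is placed inside a distribution of scores from a concrete
search, and labelled by an *objective function* — an external predicate
that says which sequence pairs are truly related (an ortholog table, a
taxonomy). `kmerscore` implements both halves: the scoring engine, and the
calibration machinery that turns scores into cut-offs and probabilities of
correct prediction.

## Counting model

A sequence of length $n$ over an alphabet $A$ yields one k-mer window per
start position, $n - k + 1$ in total. Ambiguity symbols (N for DNA; X, B,
Z, ... for protein) are tolerated on input but never counted: any window
covering one is skipped entirely. This deliberate tolerance reflects a
practical failure mode of brittle parsers — rejecting a whole genome over
one IUPAC code. With spaced k-mers, a binary mask such as `1010101` slides
with the window and only the `1` positions contribute letters to the
emitted word; several masks may run simultaneously provided they select
the same number of positions, accumulating into one shared word space of
size $|A|^m$.

Frequencies divide each count by the *realised* total of counted windows,
not by $n - k$ or $n - k + 1$. The three denominators differ only by
$O(1/n)$, but the realised total is the one that guarantees frequencies
sum to exactly 1 when ambiguous windows have been skipped — an invariant
the metrics and the histogram machinery rely on.

No reverse-complement canonicalisation is performed: counting is
forward-strand only. This is a known limitation for applications where
query and reference may come from opposite strands.

## The metrics

The raw D2 statistic is the inner product of the two count vectors,
$D2 = \sum_w C_r(w)\,C_q(w)$. Its value grows with sequence length, so
the engine exposes it mainly for diagnostics and works instead with
distances in fixed ranges (lower = more similar):

| metric | input | formula sketch | range |
|---|---|---|---|
| `d2` | counts | $0.5\,(1 - \cos(C_r, C_q))$ | $[0,1]$ |
| `euclid` | freqs | $\sqrt{\sum (x-y)^2}$ | $[0,\sqrt2]$ |
| `manh` | freqs | $\sum\lvert x-y\rvert$ | $[0,2]$ |
| `cheby` | freqs | $\max\lvert x-y\rvert$ | $[0,1]$ |
| `ncanb` | freqs | mean of $\lvert x-y\rvert/(x+y)$ over supported words | $[0,1]$ |
| `bc` | counts | $1 - 2\sum_w \min(C_r,C_q)/(S_r+S_q)$ | $[0,1]$ |
| `ngd` | counts | $(\max S - C)/(S_r + S_q - \min S)$ | $[0,1]$ |
| `d2star`, `d2s` | counts + background | background-centred D2 correlations | $[0,1]$ |

Three choices here were genuinely open and are worth recording:

* **`d2` mapping.** A cosine lies in $[-1, 1]$; the standard affine map
  $0.5(1-\cos)$ takes it to $[0,1]$. With non-negative counts the cosine
  cannot go below 0, so the realised range is $[0, 0.5]$ — orthogonal
  count vectors score exactly 0.5.
* **Canberra normaliser.** The per-word terms
  $\lvert x-y\rvert/(x+y)$ are averaged over the words with non-zero
  denominator, giving a score in $[0,1]$ with 1 exactly on disjoint
  supports.
* **Counts vs frequencies.** Bray–Curtis and NGD are defined on raw
  counts (their $S_i$ are total counts), the Minkowski family on
  frequencies. This matters: the count-based pair inherits a hard lower
  bound $\mathrm{NGD} \ge (S_{long}-S_{short})/S_{long}$, so when a short
  query meets a long reference the score is forced towards 1 no matter
  how related the sequences are. The unequal-length benchmark in the
  acceptance script demonstrates exactly this failure mode.

### Markov-background statistics

`d2star` and `d2s` centre each count by its expectation under an order-0
Markov background fitted to the same sequence: letter probabilities
$p(a)$ give word probabilities $p_w = \prod_i p(w_i)$ and centred counts
$\tilde X_w = C(w) - n\,p_w$. The statistics are the correlation-like
normalised sums described on the help pages, mapped to distances by
$0.5(1-\rho)$; unrelated sequences centre near 0.5, identical ones at 0.
Two numerical notes:

* At $k = 1$ the background reproduces the counts exactly, every
  $\tilde X_w = 0$, and both statistics are undefined; the functions
  raise an informative error rather than return 0/0.
* Floating cancellation can produce values like $-10^{-16}$ on
  self-comparisons; results are clamped to $[0,1]$.
* Words with zero background probability on both sides are skipped; a
  *observed* word with zero probability is impossible by construction
  (the background comes from the same sequence) and raises an error.

There is no protein background: amino-acid sequences are short, the
alphabet is large, and selection acts directly on the residues, so the
Markov metrics reject `aa` input.

## Search semantics

`compare_sets()` scores every query against every reference, sorts each
query's scores ascending, breaks ties by reference input order (the only
way to make top-hit evaluation reproducible), applies the optional
cut-off (*inclusive*: scores equal to the printed cut-off are retained),
then truncates to `top_n`. The bookkeeping attributes always satisfy
retained + length-filtered + cutoff-filtered + truncated = |Q|·|R|, and a
`dry_run` mode audits pair counts for large designs without scoring.
Reference vectors are computed once and cached across queries. The
length-ratio filter `fp` keeps a pair only when
$\min(\ell_a,\ell_b)/\max(\ell_a,\ell_b) \ge fp$.

## Calibration

The central procedure takes two score histograms — *all-scores* (every
comparison, dominated by negatives) and *positive-only* (truth-set pairs,
reduced to one-to-one mappings) — with identical binning: 100 equal bins
over the metric's range, left-closed, last bin closed.

* The **overlapping index** $\eta = \sum_s \min(f_A, f_B)$ summarises in
  one number how separable the two distributions are: $\eta$ near 0
  predicts high accuracy, near 1 predicts failure.
* The **cumulative difference** $\mathrm{cum\_pos} - \mathrm{cum\_all}$
  rises while positive mass accumulates faster than total mass and falls
  back to 0; the upper edge of the first bin attaining its maximum is the
  selected **cut-off score**. (Read literally, one could subtract in the
  other order; that curve is non-positive everywhere with no informative
  maximum, so the positives-minus-all orientation is used.)
* The **calibration curve** evaluates, on a grid of candidate cut-offs
  $s$, the fraction of retained top hits that are true — this is the
  probability a prediction at that score level is correct — and the
  fraction of true hits the cut-off discards. Scores map to
  probabilities by step lookup at the covering grid point; no
  interpolation or extrapolation is attempted. The grid point where
  nothing is retained reports 0 by convention.
* The range is partitioned into **high** (fraction correct ≥ 0.95, the
  conventional "highly likely" threshold), **low** (scores beyond the
  point where ≥ 99% of true hits already lie below — predictions out
  there are allocated probability ≈ 0), and **variable** in between;
  both thresholds are arguments. A grid point qualifying as both keeps
  the `high` label.

## Evaluation

Objective functions come in two kinds: an unordered pair table, and a
seven-rank taxonomy (strain … phylum) matched at a configurable rank with
missing values never matching. Both are total predicates — unknown ids
label as `FALSE` with a warning, so every scored pair can be evaluated.
Top-hit accuracy counts queries whose rank-1 reference is true; note the
structural ceiling: queries with no true partner in the reference set
still count as failures. ROC AUC is the Mann–Whitney rank statistic
oriented for distances (positives should score *low*), with ties at half
credit; it is checked against an independent ROC library in the tests.
Length–score dependence uses the Spearman rank correlation of score with
the mean length of each pair.

## What the synthetic generators emulate — and what they do not

All tests run without external data, on two generators whose defaults
were fixed once to values a practitioner would call realistic, and which
define the package's study conditions:

* **Signature genomes** (`simulate_signature_genomes`): each genome is an
  order-1 Markov chain whose transition rows are drawn around a shared
  base composition (A/T 0.3, C/G 0.2) with a log-normal perturbation
  (default sd 0.5). This emulates the compositional "genome signature"
  that lets fragments of one genome be recognised without alignment. It
  does **not** emulate repeats, horizontal transfer, GC gradients, or
  phylogenetic structure between genomes; a perturbation of 0 is the
  exact no-signal null (AUC ≈ 0.5).
* **Fragment extraction** (`make_fragments`): ten equal intervals per
  genome (remainder dropped), the first $L$ bases of the odd intervals
  becoming queries and of the even intervals references, so the two sets
  never overlap and sample the whole genome; $L$ doubles from 100 bp to
  102.4 kb in the full sweep. The unequal-length variant fixes the
  reference at the genome's first 250 kb.
* **Ortholog pairs** (`simulate_ortholog_proteins`): ancestor proteins
  drawn from natural amino-acid abundances with gamma-distributed lengths
  (mean 450, the scale of real proteomes), partners derived by i.i.d.
  substitutions (default rate 0.3) plus rare geometric indels, and
  unrelated decoys added to the reference side. Real ortholog divergence
  is not i.i.d. — no rate heterogeneity, domain structure, or codon
  model — so these fixtures support *directional* claims (metric A beats
  metric B here; scores anti-correlate with length) rather than absolute
  accuracy claims about real proteomes.

Passing tests on these generators therefore shows the machinery is
correct and the qualitative effects are real; it does not certify
accuracy figures on any particular biological data set.

## Problem sizes and reproducibility

The test suite and the acceptance script keep simulations at desk scale
by choice: 10–12 genomes of 260 kb, fragment lengths 0.1/1.6/25.6 kb,
120–150 protein pairs, and a 10,000-draw mixture for the calibration
recovery check — sizes at which every quantity of interest is stable
under the fixed seeds used. Large published designs (tens of millions of
pairs) are audited through the engine's dry-run pair planner rather than
scored. All generators take explicit seeds and are bit-reproducible;
`scripts/acceptance.R --seed N --out f.json` recomputes every reported
quantity from scratch.

## A worked example

```{r example}
sim <- simulate_signature_genomes(6, 50000, perturbation = 0.5, seed = 42)
bench <- fragment_benchmark(sim, 1600)
spec <- kmer_spec("dna", 4)
res <- compare_sets(bench$queries, bench$references, spec, "d2")
top_hit_accuracy(top_hits(res), bench$truth)

all_h <- build_histogram(res$score, "d2")
lab <- is_positive(bench$truth, res$query_id, res$ref_id)
pos_h <- build_histogram(res$score[lab], "d2")
overlapping_index(all_h, pos_h)
cumulative_difference(all_h, pos_h)$cutoff_score
```

## Known limitations

* Forward-strand counting only; no reverse-complement collapsing.
* Backgrounds are order-0 only; higher Markov orders are out of scope.
* The S2/dAI statistic is not implemented (no published closed form in
  the sources this package follows).
* Scoring is sequential; the per-query structure is embarrassingly
  parallel but no threading primitive is bundled (the CLI accepts `-c`
  for interface compatibility and ignores it).
* Protein word spaces are held sparsely; dense enumeration
  (`enumerate_words`) is guarded and intended for DNA-sized spaces.
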