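---
title: "Indirect association measures for literature-based discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Indirect association measures for literature-based discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lbdassoc)
library(dplyr)
```

## The problem

Literature-based discovery (LBD) generates hypotheses of the form "A may be
related to C" for term pairs that have never appeared together in any
document — a drug and a disease, say, connected only through intermediate
terms B that co-occur with both. This is the ABC model: the start term A
co-occurs with linking terms, the linking terms co-occur with the target
term C, and the strength of that indirect chain is evidence for the
hypothesis. The practical task is *ranking*: given one start term and
thousands of candidate targets, put the genuinely related pairs at the top.

Classical association statistics (chi-squared, Dice, log-likelihood) score a
pair from a 2x2 contingency table of its co-occurrence counts. For an LBD
pair the joint cell is zero by definition, so the direct statistic carries no
signal. This package implements a family of *indirect* association measures
that keep the statistical machinery but repopulate the contingency table from
the linking structure, together with the baselines and the evaluation
machinery needed to compare them.

## From a corpus to a matrix

`count_cooccurrences()` slides a forward window over each tokenised document:
a token at position $p$ is paired with every token at positions
$p+1,\dots,p+w$ in the same document, incrementing the *directed* count
$w_{ij}$ ("$i$ precedes $j$"). The default window is $w = 8$, the setting
commonly used when collecting concept co-occurrences from biomedical
abstracts; sentence boundaries are deliberately ignored while document
boundaries are always respected (pairs across unrelated documents would be
pure noise; if a corpus should be treated as one stream, concatenate it into
one document). A repeated term contributes one count per position pair, and
self-pairs $w_{ii}$ are kept — they never enter linking sets, because query
terms are excluded from those by construction.

`apply_threshold()` removes counts at or below a cut (default 1), the usual
noise filter: singleton co-occurrences in a large corpus are mostly
artefacts, and removing them greatly sparsifies the matrix. After
thresholding, the vocabulary is recomputed from the surviving cells — a term
whose every count fell below the cut is no longer in $V$, which matters
because linking term association uses $|V|$ as its grand total. The
pre-threshold vocabulary can be kept (`keep_vocabulary = TRUE`), and the
`vocab_size` argument of `assoc_table()` lets a caller fix $|V|$ externally.

## Contingency tables and association equations

Every measure reduces a query to four primitive numbers — joint frequency
$n_{11}$, marginals $n_{1p}$ and $n_{p1}$, grand total $n_{pp}$ — from which
`contingency_table()` derives all remaining cells and the expected values
$m_{ij}$ under independence. Three association equations are registered:

* `x2` — Pearson's chi-squared, $\sum_{ij} (n_{ij}-m_{ij})^2/m_{ij}$, the
  package default (it performs well for relatedness estimation and is the
  standard choice for these measures). No continuity correction is applied,
  and the statistic is unsigned by default; a signed variant
  (`chi_squared(..., signed = TRUE)`) negates it when $n_{11} < m_{11}$.
* `dice` — $2 n_{11} / (n_{1p} + n_{p1})$, bounded in $[0, 1]$.
* `ll` — the log-likelihood ratio $2\sum_{ij} n_{ij}\ln(n_{ij}/m_{ij})$
  with $0 \ln 0 \equiv 0$.

Degenerate inputs do not raise errors: a zero expected cell, a zero
marginal, or an empty proxy set yields an *undefined* score — an `NA`
carrying a machine-readable reason (`is_undefined()`, `undefined_reason()`).
This mirrors how such pairs are handled downstream: intrinsic evaluation
drops them and reports a reduced $n$; extrinsic ranking places them in a
final tie group rather than silently discarding them, because dropping
unscorable pairs would inflate precision.

## The measures

With $B_A$ the out-neighbours of $A$, $B_C$ the in-neighbours of $C$ (query
terms excluded from both — a linking term connects two *other* terms), and
$S = B_A \cap B_C$ the shared linking set:

| measure | $n_{11}$ | $n_{1p}$ | $n_{p1}$ | $n_{pp}$ |
|---|---|---|---|---|
| `direct` | $\sum w_{ac}$ | $\sum_j w_{aj}$ | $\sum_j w_{jc}$ | $\sum w_{ij}$ |
| `mwa` | $\sum_{b \in S} \min(w_{Ab}, w_{bC})$ | as direct | as direct | as direct |
| `lta` | $|S|$ | $|B_A|$ | $|B_C|$ | $|V|$ |
| `sbc` | $\sum_{b \in S} w_{bC}$ | $\sum_{b \in S, j} w_{bj}$ | as direct | as direct |
| `lsa` | $\sum_{i \in B_A, j \in B_C} w_{ij}$ | $\sum_{i \in B_A, j} w_{ij}$ | $\sum_{j \in B_C, i} w_{ij}$ | as direct |

plus `ltc`, the linking term count $|S|$ reported raw, with no equation.

The minimum in MWA is what keeps its table valid: each A–B–C path can carry
no more than its weakest edge, so $n_{11} \le \min(n_{1p}, n_{p1})$ always
holds, where sums or maxima over paths could violate it. LTA is MWA viewed
on the unweighted graph — the package's tests check cell-for-cell agreement
on binarised matrices. SBC and LSA are set associations: SBC substitutes the
shared linking set for A as a composite first-position term and keeps C
itself; LSA substitutes neighbour sets for both sides. The package
instantiates both as direct-association tables with the proxy set occupying
the corresponding position; the proxy substitution affects set membership
only — edges into A or out of C are not removed. SBC is undefined when
$S = \varnothing$, LSA when either proxy set is empty. All measures accept
set-valued A and C; npp for the set measures is always the full matrix
total.

A worked nine-edge example is built into the package:

```{r}
g <- fig2_graph()
g
glance(assoc_table(g, "A", "C", measure = "mwa"))
score_pairs(g, tibble::tibble(term1 = "A", term2 = "C"), measure = "lta")
```

Two cosine baselines complement the contingency measures: `direct_cosine()`
compares co-occurrence context vectors (symmetrised by default — in a
directed matrix a term that only ever appears in second position has an
empty out-row, which would make the directed cosine vacuously undefined;
`directed_rows = TRUE` restores pure out-row behaviour), and
`embedding_cosine()` compares externally trained embedding vectors read from
word2vec text format. All scores are oriented so that higher means more
related.

## Evaluation

**Intrinsic.** `spearman_eval()` correlates machine scores with human
relatedness judgements (UMNSRS/MiniMayoSRS-style pair files read by
`read_gold()`). Undefined or out-of-vocabulary pairs are dropped and `n`
reduced, so measures are compared on the pairs they can score; Spearman's
rho uses the exact $1 - 6\sum d^2 / (n(n^2-1))$ form on tie-free ranks and
average-rank Pearson correlation otherwise. `fisher_r_to_z()` compares two
correlations from independent samples.

**Extrinsic.** Time-slicing turns link prediction into a labelled task:
`timeslice_labels()` takes pre- and post-cutoff matrices, removes start/
target pairs already present before the cutoff (known knowledge), labels
post-cutoff pairs true and the rest false. Occurrence is direction-blind by
default (`directed = TRUE` requires the start-to-target orientation), since
a windowed count of a genuinely co-occurring pair almost always populates
both directions. Scores from the pre-cutoff matrix then rank the pairs.

`rank_with_tie_penalty()` sorts by descending score and, within every tied
group, places all false pairs before all true ones — the worst ordering the
method could have produced, so methods emitting many ties get no credit for
luck. The package's tests verify exhaustively (up to 8 tied pairs) that no
within-tie permutation yields a lower area. Undefined scores form the final
tie group.

`pr_curve()` thresholds at every rank and integrates precision over recall
with the rectangular step convention, anchored at recall 0:
$\mathrm{AUC} = \sum \Delta r_k \, p_k$ over ranks where recall increases.
Step integration was chosen over linear interpolation because interpolating
between PR points is known to overstate performance; for severely
imbalanced LBD data that bias is large. `roc_curve()`/`roc_auc()` use the
standard trapezoid over (FPR, TPR) anchored at (0, 0), which on tie-free
rankings equals the Mann–Whitney statistic divided by $P \cdot N$; the same
upstream tie penalty applies. Both curve objects support `tidy()`,
`glance()`, and `autoplot()`.

```{r, fig.width = 5, fig.height = 3.5}
ranked <- rank_with_tie_penalty(tibble::tibble(
  score = c(4, 3, 2, 1),
  label = c(TRUE, FALSE, TRUE, FALSE)
))
glance(pr_curve(ranked))
autoplot(pr_curve(ranked))
```

## Synthetic data

The package is fully testable without any corpus download. `fig2_graph()`
is the deterministic worked example above. `random_lbd_graph()` generalises
its topology — white terms co-occur with A only, black with C only, shared
terms with both, gray terms are isolated vocabulary members — with uniform
integer weights (default 1–9, spanning the worked example's range) drawn
from an explicit seed. `random_streams()` produces uniform token streams
for exercising the windowed counter against a brute-force position-pair
oracle. Every generator takes its seed as an argument; none touches global
RNG state.

What the generators emulate is the *combinatorial structure* of LBD data:
linking-set topology, directionality, weight asymmetry, isolated vocabulary.
What they do not emulate is the statistics of a real MetaMapped corpus —
Zipfian term frequencies, vocabulary sizes in the hundreds of thousands,
co-occurrence matrices with billions of pair tokens, or the semantic
coherence of actual UMLS concepts. Passing tests therefore establish that
the measures compute exactly what their definitions say on any directed
weighted graph, not that any particular measure will rank real biomedical
hypotheses well; the latter is an empirical question about corpora, not
about this implementation.

## Numerical and design choices

* Counting and all contingency cells are integer-valued sums held as
  doubles; no floating-point tolerance is needed anywhere in the measure
  layer, and the test suite asserts exact equality against brute-force
  oracles on hundreds of seeded random graphs (up to 30 nodes) and streams
  (up to 200 tokens) — sizes at which the quadratic oracles are still
  instant but the combinatorics are non-trivial.
* Undefined-score propagation is by `NA` plus reason rather than exceptions,
  so vectorised pipelines (`score_pairs()`) always return one row per input
  pair.
* `contingency_table()` rejects inputs violating
  $n_{11} \le \min(n_{1p}, n_{p1})$, $\max(n_{1p}, n_{p1}) \le n_{pp}$, or
  $n_{22} \ge 0$ with an error naming the inequality; the measures
  themselves can never produce such inputs for never-co-occurring query
  pairs, which is the intended domain.
* Ties in ranking are broken only by the label penalty; the sort is
  otherwise stable, and every AUC is invariant to within-group order beyond
  the penalty.
* The triplet TSV matrix format cannot represent isolated vocabulary terms
  (it stores only nonzero cells); the MatrixMarket format with its
  vocabulary sidecar round-trips them. Pipelines that care about exact
  $|V|$ (LTA's total) should use the latter or pass `vocab_size`.

## Limitations

Corpus acquisition and concept mapping are out of scope: the package
consumes tokenised concept streams, prebuilt matrices, and pretrained
embedding vectors, and does not train embeddings or extract predications.
The measure layer stores matrices as sparse triplet tibbles, which is
comfortable up to millions of nonzero cells but is not engineered for a
full MEDLINE-scale matrix in memory; the windowed counter processes
documents in R and is sized for experimentation, not corpus-scale
ingestion.
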