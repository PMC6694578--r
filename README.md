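# lbdassoc

Indirect association measures for literature-based discovery (LBD) in R.

LBD generates hypotheses of the form "start term A may be related to target
term C" for pairs that never co-occur in any document — classically, a drug
and a disease connected only through intermediate *linking terms* B that
co-occur with both (the ABC model). Because the pair's joint frequency is
zero by construction, ordinary collocation statistics are blind to it. This
package scores such pairs by repopulating the 2×2 contingency table from the
linking structure of a directed co-occurrence graph, then applying a
standard association equation.

For a query pair (A, C) over directed counts w_ij, with B_A the
out-neighbours of A, B_C the in-neighbours of C, and S = B_A ∩ B_C the
shared linking terms, the implemented measures set the joint cell n11 to:

| measure | n11 | intuition |
|---|---|---|
| `ltc` | \|S\| (raw count, no equation) | classic linking term count |
| `direct` | Σ w_AC | ordinary direct association (zero for LBD pairs) |
| `mwa` | Σ_{b∈S} min(w_Ab, w_bC) | minimum-capacity flow along each A–B–C path |
| `lta` | \|S\|, with marginals \|B_A\|, \|B_C\| and total \|V\| | linking term count with statistical weighting |
| `sbc` | Σ_{b∈S} w_bC | the shared set stands proxy for A against C |
| `lsa` | Σ_{i∈B_A, j∈B_C} w_ij | neighbour sets stand proxy for both terms |

The remaining cells follow from the marginals; the table feeds Pearson's
chi-squared (default), Dice, or log-likelihood. Cosine baselines over
co-occurrence context vectors and pretrained embeddings are included, as is
the evaluation machinery: Spearman correlation against human relatedness
gold standards with Fisher r-to-z comparison, and time-slicing link
prediction with tie-penalised precision–recall and ROC curves.

## Worked example

The package ships the nine-edge reference graph in which A co-occurs with
four terms (weights 1, 2, 8, 3), C is preceded by three (weights 4, 5, 7),
and b3, b4 are the shared linking terms:

```r
library(lbdassoc)
library(dplyr)

g <- fig2_graph()
g
#> <cooc_matrix> 8 terms, 7 directed nonzero cells, total weight 30

glance(assoc_table(g, "A", "C", measure = "mwa"))
#> # A tibble: 1 × 7
#>     n11   n1p   np1   npp    x2  dice    ll
#>   <dbl> <dbl> <dbl> <dbl> <dbl> <dbl> <dbl>
#> 1     7    14    16    30 0.117 0.467 0.117
```

MWA's joint cell is min(8,4) + min(3,5) = 7: each A–B–C path carries no more
than its weakest edge. The marginals are A's total out-weight (1+2+8+3 = 14)
and C's total in-weight (4+5+7 = 16) against the grand total 30; the
chi-squared, Dice, and log-likelihood columns score that table. Scoring is
pipe-friendly over data frames of pairs:

```r
pairs <- tibble(term1 = "A", term2 = "C")
bind_rows(
  score_pairs(g, pairs, measure = "ltc"),
  score_pairs(g, pairs, measure = "mwa"),
  score_pairs(g, pairs, measure = "lta"),
  score_pairs(g, pairs, measure = "sbc")
)
#> # A tibble: 4 × 6
#>   term1 term2 measure equation  score reason
#>   <chr> <chr> <chr>   <chr>     <dbl> <chr>
#> 1 A     C     ltc     <NA>      2     <NA>
#> 2 A     C     mwa     x2        0.117 <NA>
#> 3 A     C     lta     x2        0.533 <NA>
#> 4 A     C     sbc     x2       11.2   <NA>
```

Even though A and C never co-occur (the direct n11 is 0), every indirect
measure assigns a positive score; a pair with no shared linking terms would
instead come back as `NA` with a reason (e.g. `"empty shared set"`), and
undefined pairs rank last in evaluation. The methods vignette
(`vignettes/indirect-association.Rmd`) documents the model, the tie-penalised
curve conventions, and the design choices in full; a command-line wrapper
(`inst/cli/lbdassoc`) exposes counting, scoring, and evaluation as shell
subcommands.

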