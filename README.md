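# fuzzygrn

Reverse-engineering of signed, directed gene regulatory networks (GRNs) from
short time-series expression data — the regime of classic microarray
experiments such as the yeast cell-cycle series, where a dozen genes are
observed at 14–24 time points and most statistical machinery is starved for
samples.

`fuzzygrn` implements a rule-based neuro-fuzzy approach. One small fuzzy
network is trained per gene, with all remaining genes as inputs; the IF-THEN
rules those networks share are then compared across networks to decide which
gene activates or represses which.

## Method

For each gene *i* (the target), every other gene is an input:

1. **Normalize**: each gene's series is min–max scaled to [0, 1]:
   *O* = (*G* − min *G*) / (max *G* − min *G*).
2. **Fuzzify**: values are mapped to three Gaussian membership functions
   ("Low", "Medium", "High"), μ(*x*) = exp(−(*x* − *m*)²/σ²), with fixed
   centers *m* = (0.2, 0.5, 0.8) and variance σ² = 0.25.
3. **Rules**: each training time point proposes an IF-THEN rule — the
   antecedent is the dominant label of every input gene, the consequent the
   dominant label of the target. Duplicate antecedents are merged, so the
   rule count never exceeds the sample count.
4. **Fire and combine**: a rule's firing strength on a sample is the product
   T-norm of its per-gene memberships; strengths are normalized to firing
   powers, and the prediction is the weighted sum Σᵢ *w*ᵢ *O*ᵢ⁽⁴⁾ of powers
   with learned singleton weights.
5. **Learn**: the weights *w* minimize the mean squared prediction error,
   solved in closed form by (ridge-regularizable, minimum-norm) least
   squares.

Network extraction then compares the *same* canonical rule across all N
per-gene networks. Each network's **effectivity threshold** *T*ᵢ is the mean
magnitude of its rule weights; a rule's weight maps to an **effectivity
symbol** ES ∈ {−1, 0, +1} (no effect / activation / repression above
threshold). For each rule, every gene whose own network shows ES = 0 is
connected to every gene whose network shows ES ≠ 0, with the sign of the
target's symbol. Activator and repressor evidence counts AC/RC are
accumulated over rules, the net interaction is the pairwise subtraction
AC[i,p] − AC[p,i] (likewise RC), and strictly positive net counts become the
final signed edges.

Evaluation against a signed reference network scores each reference edge as
**Consistent** (recovered with direction and sign), **Inconsistent**
(recovered misdirected or mis-signed) or **NotFound**, giving
TP/FP/FN and Sensitivity = TP/(TP+FN), Precision = TP/(TP+FP),
F = 1/(α/P + (1−α)/S) with α = 0.5. The package ships the 33-edge
KEGG-derived yeast cell-cycle reference over 12 core regulators (CLN1-3,
CLB5-6, CDC6/20/28, SIC1, SWI4/6, MBP1) used in the published benchmark.

## Worked example

```r
library(fuzzygrn)

cfg   <- simulation_config(seed = 7)        # 12 genes, 24 time points, 15 edges
truth <- generate_grn(cfg)
expr  <- simulate_expression(truth, cfg)

res <- infer_network(expr)
res
#> Neuro-fuzzy GRN inference: 12 genes, 24 time points
#>   shared rules: 22 ; inferred edges: 112 ( 56 activator / 56 repressor )

head(res$network, 4)
#>   source target      sign score
#> 1    G01    G02 activator     3
#> 2    G01    G04 repressor     2
#> 3    G01    G05 repressor     4
#> 4    G01    G06 activator     1

ev <- evaluate_network(res$network, truth, universe = rownames(expr))
round(unlist(ev[c("tp", "fp", "fn", "sensitivity", "precision", "f_score")]), 3)
#>          tp          fp          fn sensitivity   precision     f_score
#>       8.000       4.000       7.000       0.533       0.667       0.593
```

Of the 15 ground-truth edges, 8 are recovered with correct direction and
sign, 4 are recovered misdirected or mis-signed, and 7 are missed; the
`score` column is the net rule-evidence supporting each edge. The method is
deliberately permissive (any strictly positive net evidence becomes an
edge), so it trades precision for sensitivity on sparse truths — raise
`pipeline_config(min_score = ...)` to prune.

Files work the same way via `run_simulate()` / `run_infer()` /
`run_evaluate()` or the `inst/cli/fuzzygrn` script
(`simulate | infer | evaluate` subcommands).

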