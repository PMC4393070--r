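---
title: "Rule-based neuro-fuzzy GRN inference: model, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based neuro-fuzzy GRN inference: model, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fuzzygrn)
```

## The problem and the model

Short time-series expression experiments — a dozen genes, a few dozen time
points — carry too few samples for most parametric network-learning
machinery. The approach implemented here sidesteps the sample-size problem
by describing the data with linguistic IF-THEN rules ("IF CLN1 is High and
SIC1 is Low THEN CLB5 is Medium") whose only trained parameters are one
scalar weight per rule.

One model is trained per gene. For target gene $i$ with all other genes as
inputs, the five layers are:

1. **Normalization** $O_g = (G_g - \min G_g)/(\max G_g - \min G_g)$,
   per gene, onto $[0,1]$. A constant gene has no dynamics to explain and is
   rejected with an error naming it.
2. **Fuzzification** by three Gaussian membership functions
   $\mu_j(x) = \exp(-(x - m_j)^2/\sigma^2)$ with shared centers
   $m = (0.2, 0.5, 0.8)$ and variance $\sigma^2 = 0.25$. Fixed, shared MF
   parameters keep the linguistic labels comparable across genes and keep
   the parameter count independent of gene number — essential with 14–24
   samples.
3. **Rule base**: each training time point proposes a candidate rule
   (antecedent = dominant label of every input gene, consequent = dominant
   label of the target). Candidates with identical antecedents merge, so
   rules $\le$ samples by construction.
4. **Firing and normalization**: product T-norm over the antecedent's
   per-gene memberships, then division by the total so per-sample firing
   powers sum to one.
5. **Defuzzification**: prediction $= \sum_i w_i\, O^{(4)}_i$, the
   power-weighted sum of singleton consequent weights.

The weights solve the least-squares problem
$\min_w \lVert Dw - y\rVert^2 + \lambda\lVert w\rVert^2$ where $D$ is the
samples-by-rules matrix of normalized firing powers. With $\lambda = 0$
(default) the minimum-norm pseudoinverse solution is used, so collinear rule
columns — common when label patterns repeat — never break the fit. Training
quality is tracked as the mean squared error between fitted and measured
normalized series.

## From rules to a signed network

Rule comparison across the per-gene networks drives edge calling:

* **Canonicalization** writes each rule as a full-length label vector with
  the consequent inserted at the target gene's own position, so rules from
  different networks share one gene order.
* **Grouping** collects identical canonical vectors across networks; each
  group records which networks learned the rule and with what weight.
* **Effectivity threshold** $T_i$: the mean magnitude of network $i$'s rule
  weights. **Effectivity symbol**: $ES = 0$ if $|w| < T_i$, else the sign
  of $w$.
* **Connection extraction**: within one rule's symbol vector, every gene
  with $ES = 0$ is connected to every gene with $ES \ne 0$, signed by the
  target's symbol. The rationale: a gene unaffected by the rule in its own
  network but co-occurring in a rule that strongly drives another gene is
  read as a putative regulator of that gene.
* **Accumulation and subtraction**: activator/repressor counts AC/RC are
  summed over rules; the net interaction $AC_{i\to p} - AC_{p\to i}$
  (likewise RC) resolves direction; strictly positive net counts become
  edges with the net count as score.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `centers` | 0.2, 0.5, 0.8 | label centers on the normalized scale; even cover of $[0,1]$ |
| `variance` | 0.25 | Gaussian MF variance $\sigma^2$ (so $\sigma = 0.5$); wide enough that all labels fire everywhere |
| `threshold_mode` | `"abs"` | effectivity threshold as mean of \|w\| (see below) |
| `ridge` | 0 | optional $L_2$ penalty for ill-conditioned designs |
| `lag` | 0 | inputs at $t$ predict the target at $t+\mathrm{lag}$ |
| `min_score` | 1 | minimum net evidence for a final edge |
| `alpha` | 0.5 | F-score weight; 0.5 is the harmonic mean |
| `knn_k` | 5 | imputation neighbours |

## Design decisions that were genuinely open

**Signed vs. absolute threshold.** The threshold is described as the average
of a network's rule weights, but the symbol rule compares $|w|$ against it.
A signed mean can be zero or negative, in which case *every* rule becomes
"effective" and the threshold loses its meaning. The default therefore
averages magnitudes, preserving the above-average-effect semantics;
`threshold_mode = "literal"` reproduces the signed average for users who
want the formula verbatim. The boundary case $|w| = T$ is mapped to "no
effect" — the ternary rule leaves equality undefined, and assigning it to 0
keeps symbols conservative.

**Contemporaneous regression.** The rule tables index all genes at the same
time point $k$, so inputs predict the target at the same time by default.
Nothing in the formulation forbids a lagged reading; `lag` shifts the
inputs for users who prefer explicit dynamics, at the cost of `lag` samples.

**Exact rule identity.** Rules group across networks by exact label-vector
equality. A fuzzier similarity (e.g. one-label Hamming slack) would merge
more evidence but needs a similarity threshold the formulation does not
provide; exact equality is the minimal, parameter-free reading.

**Consequent ties.** When merged candidates disagree on the consequent, the
majority label wins and ties go to the first-seen occurrence — a
deterministic choice on data where any choice is equally defensible.

**Argmax ties.** Dominant labels break exact membership ties toward the
lower center. The only inputs where this matters under the defaults are the
equidistance points 0.35 and 0.65.

**Final edge rule.** How the subtraction tables become edges is not pinned
down by the formulation; strict positivity of the net count is the minimal
assumption and is exposed as `min_score`. Both signs may survive for one
pair (the two evidence channels are accumulated independently);
`dominant_sign = TRUE` keeps only the stronger.

**Misdirection protocol.** In evaluation, FP counts only reference edges
recovered with wrong direction or sign. Predicted edges between pairs the
reference never mentions are reported separately (`spurious`) instead of
entering FP: the reference is a curated subset, not a complete truth, so
absence of a pair there is no evidence the prediction is wrong. This is
also the only protocol consistent with the published verdict-to-confusion
arithmetic across all five benchmarked methods.

## What the synthetic generator does and does not emulate

`simulate_expression()` produces matrices shaped like the yeast cell-cycle
series (default 12 genes, 24 time points, nonnegative values, optional
missing cells) from a known signed network, via discrete-time sigmoidal
dynamics: regulated genes follow
$x_g(t{+}1) = \mathrm{clamp}_{[0,1]}\!\big(\mathrm{logistic}(s \sum_r
\pm x_r(t)) + \varepsilon\big)$ with gain $s = 3$ and Gaussian noise
$\sigma = 0.05$ by default; unregulated genes follow seeded sinusoidal
baselines (period 8–14 points) mimicking cycling transcripts. The latent
trajectories are mapped to a 10–100 expression range.

The generator is deliberately *not* a fuzzy-rule process: testing recovery
on data drawn from the method's own model class would be circular. It also
omits measurement-model realism (multiplicative microarray noise, probe
effects), transcription delays and cell-cycle synchronization loss. Passing
recovery tests therefore show that the pipeline extracts directed, signed
co-expression structure from dynamics it did not assume — not that it
matches wet-lab truth on real chips.

The recovery study compares the pipeline's F-score against the generating
network with the same pipeline run on per-gene time-shuffled matrices. The
shuffle preserves every gene's marginal distribution (and hence its labels)
while destroying cross-gene timing, which is exactly the signal the rule
comparison uses. Because inference is invariant to a *joint* permutation of
time points, shuffling must be per-gene to be a meaningful control.

## Problem sizes and numerical tolerances

The test suite trains on matrices between 3×8 and 12×24; the recovery study
uses 20 seeded replicates of the default 12×24/15-edge configuration, and
the acceptance script uses 100 replicates of the same configuration for a
tighter mean. Firing-power simplex sums are asserted to 1e−12;
least-squares optimality is asserted against 1,000 random weight vectors
with 1e−9 slack; interpolating fits are asserted to 1e−10. All randomness
flows through explicit integer seeds; two runs with identical inputs and
configuration produce byte-identical SIF output.

## Known limitations

* Edge direction rests on the zero-source/nonzero-target reading of the
  symbol vectors, which conflates "unaffected in its own network" with
  "upstream"; on dense truths this over-generates edges (the worked example
  emits ~100 edges from 15 true ones at `min_score = 1`).
* With one rule per observed time point and exact-match grouping, evidence
  is sparse for short series; weights, not rule structure, carry most of
  the signal.
* The evaluation protocol scores only reference pairs; it cannot penalize
  hallucinated regulators outside the curated reference beyond the
  `spurious` tally.
* No uncertainty is attached to edges; the score is a raw evidence count,
  not a calibrated confidence.
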