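---
title: "Paired-RBM scoring of gene-gene interactions: model, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Paired-RBM scoring of gene-gene interactions: model, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rbmgrn)
```

## The model

`rbmgrn` scores the interaction between two genes by asking how well each
gene's expression pattern across samples can be *reconstructed from the
other's learned features*. Each gene of a pair gets a single-layer RBM with
`n` visible and `n` hidden units, `n` being the number of samples. The two
machines are coupled in two ways:

1. **Shared initialization.** Both n×n weight matrices are one draw from
   uniform `[-1/n, 1/n]`; the single bias vector starts at zero and is never
   updated (the update rule adjusts weights only, and a fixed zero bias keeps
   the two machines exactly exchangeable).
2. **The bridge.** At epoch 1 each RBM reconstructs its own gene from its own
   forward hidden activation. From epoch 2 onward the *partner's* forward
   activation drives the reconstruction. A gene pair can therefore only reach
   a low reconstruction error if each gene's profile is predictable from the
   other's hidden representation — co-expression expressed as mutual
   reconstructability.

Per epoch, for gene vectors $g_1, g_2 \in [0,1]^n$:

- forward: $h = \sigma(b + g W)$, with binary states $h_i > t_i$ for one
  random threshold vector $t \sim U(0,1)^n$ drawn fresh each epoch and
  **shared by both RBMs**;
- backward: visible reconstruction $v' = \sigma(b + h_\text{src} W^\top)$ and
  hidden re-activation $h' = \sigma(b + v' W)$;
- error: $\sum_i (g_i - v'_i)^2$ per gene;
- update: $W \mathrel{+}= \eta\,(g \otimes h - v' \otimes h')/n$ — the gap
  between the data association and the reconstruction association, one step
  of a contrastive-divergence-style rule.

Training stops when (a) **both** errors are at or below `error_tol` (the
pair *converged*), (b) the two interaction strengths differ by more than
`weight_diff_break` (such a pair cannot survive any acceptance threshold in
the conventional range, so training is cut short; the pair is recorded
unconverged), or (c) `max_epochs` is reached.

At the final epoch, the **matched active set** M collects hidden positions
whose state is on in *both* machines under the shared threshold; gene $k$'s
interaction strength is the mean of its own activations over M. A pair is an
accepted interaction iff it converged and $|s_1 - s_2| \le \theta$.

### Why identical genes always pass

With equal inputs, equal initial weights and a shared threshold vector the
two trajectories are identical at every epoch, so $s_1 = s_2$ exactly (to
the last bit) and the pair passes any $\theta \ge 0$ once converged. This is
the method's internal consistency check and is asserted over 20 seeds in the
test suite.

## Edge orientation

Accepted pairs are directed with a two-way Gaussian comparison on the **raw**
(pre-normalization) intensities: fit $(\mu, \sigma)$ to each gene —
$\sigma$ the *population* standard deviation (divisor $n$), which is what the
worked example's printed values imply — and evaluate each gene's density at
the partner's mean expression. The gene whose distribution better explains
the other's mean is the regulator, and the edge carries the regulator's
strength value. The evaluation point had to be chosen (a distribution can be
evaluated at any summary of the partner); the mean is the simplest
representative value, makes the rule a deterministic function of the two
$(\mu, \sigma)$ pairs, and reproduces the worked example's conclusion. Exact
ties (e.g. two identical vectors) are flagged and resolved toward the
lexicographically smaller id so network assembly is deterministic.

Note the asymmetry this rule creates: a high-variance gene is generous with
density and therefore tends to be named regulator of a distant-mean,
low-variance partner. That is a property of the published rule, not of this
implementation.

## Tunable parameters

| parameter | default | units | notes |
|---|---|---|---|
| `error_tol` | 0.01 | squared intensity (normalized) | part of the method: pairs above it are ignored |
| `weight_diff_break` | 0.01 | strength (activation mean) | part of the method's early break |
| `theta` | 0.006 | strength gap | conventional range 0.004–0.016; sweep with `edges_vs_threshold()` |
| `learning_rate` | 0.1 | — | free choice; the method's description leaves it open |
| `max_epochs` | 1000 | epochs | free choice; identical-gene pairs on 6 samples converge in ~300 |
| `backward_uses_transpose` | `TRUE` | — | standard RBM reconstruction through $W^\top$; `FALSE` restores a literal same-orientation product (the two agree for symmetric $W$) |

Seeds: every pair trains under `pair_seed(global_seed, id_a, id_b)` — a hash
of the *sorted* ids mixed with the global seed — so a whole-matrix run is
reproducible and independent of pair iteration order.

## The synthetic generator

`synthetic_spec()` / `generate_expression()` emulate log-scale microarray
intensities: per-gene baseline offsets `Normal(0, 1)` around `baseline_mu =
7` with sample noise `baseline_sd = 1.2`, spanning roughly the 4–9 range
seen in the worked tables. A planted pair sets
`target = effect * (regulator - mean(regulator)) + baseline + Normal(0,
noise_sd)`, i.e. a controlled co-expression signal on top of an
uncorrelated background. `generate_condition_pair()` produces two matrices
over the same gene ids with independently planted structure for
network-differencing tests.

What the generator does **not** model: probe effects, background/saturation
artifacts, MAS5/RMA pre-processing, heavy-tailed noise, correlated
backgrounds. Passing tests on this generator therefore show the pipeline
recovers planted linear co-expression under Gaussian noise — not that it
recovers true regulatory edges in real microarray data.

## Numerical and design choices

- **Constant gene rows** have zero range, so MAXMIN normalization maps them
  to all zeros (with a warning) rather than dividing by zero; a flat gene
  carries no signal either way.
- **Normalization placement**: gene selection happens *before*
  normalization, so each run's gene subset defines its own row ranges. (Row
  ranges are per-gene, so the order only matters for which samples are
  present, not which genes.)
- **Strength-divergence break**: stopping training rather than discarding
  the pair outright; the θ filter then makes the accept/reject decision.
  Since the break fires exactly when the gap exceeds 0.01 and every
  conventional θ ≤ 0.016, broken pairs are almost always rejected anyway —
  the distinction only matters for bookkeeping.
- **Wilcoxon ranking** uses mid-ranks and the tie-corrected normal
  approximation without continuity correction, and applies no
  multiple-testing correction because only the *ranking* is consumed. With 8
  or fewer samples the p-values deviate from the exact permutation values by
  up to ~0.15 mid-range (~0.05 in the tails); the induced ranking is much
  more stable.
- **Energy function**: the classical RBM energy (with its separate hidden
  bias) is exposed as a diagnostic, but the training procedure never
  evaluates it — the update rule above is the whole of learning.
- **Degenerate inputs**: training requires values in [0, 1] (use
  `maxmin_normalize()` first) and at least two samples; the direction rule
  refuses constant regulator vectors (degenerate Gaussian).

## Problem sizes and stochastic behaviour

The shipped tests and the acceptance script run at desk scale: worked tables
(5×6, 4×4, 2×9), synthetic matrices of 8 genes × 20 samples, full training
at the default 1000-epoch cap (an 8-gene all-pairs run takes well under a
second). At these conditions, with planted `effect = 1`, `noise_sd = 0.2`:

- unplanted pairs essentially never converge (the break fires within tens of
  epochs), so specificity is near perfect;
- planted pairs converge and pass θ = 0.016 only stochastically — replicate
  averages put sensitivity around 15–40%. The stochastic threshold vector
  and the strict break rule make acceptance a noisy event, which matches the
  method's own description of run-to-run variability (a 10–20% change in
  detected interactions between runs is expected behaviour, not a defect).

## Known limitations

- Strength values concentrate in a narrow band around 0.5–0.7 (they are
  means of logistic activations), so θ operates on small differences; the
  absolute strengths are less informative than their gap.
- The direction rule uses only two moments of each gene; genes with similar
  means and variances produce near-tie scores whose orientation is fragile.
- The hidden-layer width is tied to the sample count, so very small cohorts
  give the machines little capacity, and large cohorts make the n×n weight
  matrices the dominant cost.
- GEO SOFT support covers the minimal GDS dataset dialect only (no GSE/GPL
  family files, no downloading).
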