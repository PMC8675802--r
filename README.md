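# rbmgrn

Gene–gene interaction scoring and directed gene regulatory network (GRN)
inference from expression matrices, using a *bridged pair* of single-layer
restricted Boltzmann machines (RBMs) per gene pair, a threshold rule on the
pair's two interaction strengths, and a two-way Gaussian naive-Bayes
comparison to orient accepted edges. The package targets differential
co-expression studies — e.g. contrasting the interaction network of normal
versus tumour samples, or of two tumour stages — where both the *presence*
and the *direction* of a pairwise interaction may change between conditions.

## Method

For each unordered gene pair (g₁, g₂), both expression vectors (one value per
sample, MAXMIN-normalized per gene to [0, 1]) are fed to two n-unit RBMs whose
n×n weight matrices start as one shared uniform draw from [−1/n, 1/n]:

- **Forward pass** (per epoch): hidden pre-activations `b + g·W`, logistic
  activations, and binary states from one random threshold vector *shared by
  both RBMs*.
- **Bridge**: at epoch 1 each RBM reconstructs its gene from its own hidden
  activation; from epoch 2 onward from its *partner's* — each gene must be
  reconstructable from the other's features.
- **Update**: each weight matrix moves by
  `lr · (g ⊗ h_fwd − v_rec ⊗ h_rec) / n`, one contrastive-divergence-style
  step from the forward/backward association gap.
- **Stopping**: both summed squared reconstruction errors ≤ 0.01
  (convergence), or the two interaction strengths diverge past 0.01
  (break), or the epoch cap.
- **Strengths**: over the hidden units active in *both* RBMs at the final
  epoch, each gene's strength is the mean of its own activations. A pair is
  accepted as an interaction iff it converged and
  `|strength₁ − strength₂| ≤ θ` (θ conventionally 0.004–0.016).
- **Direction**: for an accepted pair, fit a Gaussian (mean, population SD)
  to each gene's *raw* expression; the gene whose density better explains the
  partner's mean expression is the regulator. The edge carries the
  regulator's strength.

Networks built per condition can be compared: edge pairs are partitioned into
only-in-x, only-in-y, shared-same-direction, shared-reversed-direction.

## Worked example

The worked 5-gene × 6-sample example data set ships with the package:

```r
library(rbmgrn)

tabs <- fixture_tables()
norm <- maxmin_normalize(tabs$table1)
round(norm["Gene1", ], 4)
#> Sample1 Sample2 Sample3 Sample4 Sample5 Sample6
#>  0.6356  0.0000  0.4382  0.5726  1.0000  0.1982

# threshold rule on the published 4-gene strength table at theta = 0.004
kept <- filter_interactions(strength_matrix_candidates(tabs$table4), 0.004)
paste(kept$gene_a, kept$gene_b, sep = "-")
#> [1] "Gene1-Gene3" "Gene2-Gene3" "Gene3-Gene4"

# orienting one accepted pair on raw intensities
decide_direction(tabs$table5["Gene1", ], tabs$table5["Gene3", ],
                 "Gene1", "Gene3")
#> # A tibble: 1 × 5
#>   regulator target score_forward score_backward tie
#>   <chr>     <chr>          <dbl>          <dbl> <lgl>
#> 1 Gene3     Gene1        0.00222       1.37e-22 FALSE
```

Gene3's fitted Gaussian (µ ≈ 7.307, σ ≈ 0.896) places density 2.2 × 10⁻³ on
Gene1's mean expression, while Gene1's (µ ≈ 4.390, σ ≈ 0.290) places
~1.4 × 10⁻²² on Gene3's — so the edge is Gene3 → Gene1.

An end-to-end run on synthetic data with two planted regulator→target pairs:

```r
sp <- synthetic_spec(8, 20,
  list(list(regulator = 1, target = 2, effect = 1, noise_sd = 0.2),
       list(regulator = 3, target = 4, effect = 1, noise_sd = 0.2)), seed = 11)
x <- generate_expression(sp)
res <- run_pipeline(list(synthetic = x), "runs/demo", theta = 0.016, seed = 5)
res$networks$synthetic$edges
#> # A tibble: 2 × 6
#>   regulator target strength score_forward score_backward tie
#>   <chr>     <chr>     <dbl>         <dbl>          <dbl> <lgl>
#> 1 g01       g02       0.587         0.300          0.297 FALSE
#> 2 g03       g04       0.695         0.404          0.391 FALSE
```

Both planted pairs are recovered with the planted regulator on the tail of
the edge; all 26 background pairs are rejected (they hit the
strength-divergence break before converging). Recovery is stochastic by
design — across seeds, sensitivity at this noise level is well below 100%
while specificity stays essentially perfect (see the methods vignette).

A shell entry point wrapping the same pipeline lives at
`inst/scripts/grn-pipeline.R` (see `--help`).

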