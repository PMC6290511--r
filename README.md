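# gatan

Multi-task feed-forward networks for small clinical tabular datasets, with
cosine-weighted fusion of shared and task-specific representations and
connection-weight feature ranking.

## The problem

Clinical prediction cohorts are small (a few hundred patients), features are
moderately many, and the continuous outcome of interest — a cardiac-MRI
measure, a time to tumor recurrence — is expensive to label. The labeling
process usually yields *other* correlated measurements (stroke volume, wall
thickness, recurrence status). **gatan** uses those as auxiliary prediction
tasks: the network predicts the primary and auxiliary targets
simultaneously, so the auxiliary losses regularize the scarce primary
signal.

## The model

Separate sigmoid feed-forward subnetworks produce a shared representation
$h^s$, a primary-specific $h^c$ and one $h^{a_k}$ per auxiliary task
(default hidden sizes 80 and 40; the 40-dim layer is the representation).
Each task's fused representation is a per-sample convex combination

$$h^{fc} = a_1 h^c + a_2 h^s,\qquad a_1 = \tfrac12\cos(h^c, h^s),\quad a_2 = 1 - a_1,$$

so the shared branch always contributes at least half
($0 < a_1 \le \tfrac12$ under sigmoid activations). Task heads are linear
with identity/sigmoid/softmax links. Training minimizes
$\sum_i L^c + \omega \sum_k \sum_i L^{a_k}$ (squared loss or cross-entropy
per task type, $\omega = 1$ by default) with full-batch gradient descent;
gradients flow exactly through the fusion weights and are verified against
finite differences. Features are ranked by back-propagating shares of
absolute connection weights from the primary head to the inputs through
both branches and combining them with the averaged fusion weights
$C = \bar a_1 C^{(c)} + \bar a_2 C^{(s)}$. See the methods vignette
(`vignettes/gatan-methods.Rmd`) for the full account.

## Worked example

Simulate a cohort-like multi-task table (30 features of which the first 5
drive the targets through a shared nonlinear latent), split it, fit, and
inspect:

```r
library(gatan)

sim   <- simulate_multitask(n = 160, p = 30, k_informative = 5,
                            num_aux = 1, relatedness = 0.8, seed = 1)
parts <- split_dataset(sim$data, c(100, 30, 30), seed = 1)

fit <- gatan(parts$train, primary = "y", aux = "aux1",
             validation = parts$val, epochs = 4000,
             early_stop_patience = 300, seed = 1)
fit
#> <gatan_fit> primary 'y' (continuous) + aux [aux1]; 30 features
#> <train_report> 753 epoch(s); selected epoch 453; final objective 115.9632; mean a1 0.4860339

evaluate(fit, parts$test)
#> # A tibble: 1 × 4
#>     mse   evs   mae     n
#>   <dbl> <dbl> <dbl> <int>
#> 1  1.02 0.454 0.546    30

head(tidy(fit), 7)
#> # A tibble: 7 × 5
#>   feature specific shared combined  rank
#>   <chr>      <dbl>  <dbl>    <dbl> <int>
#> 1 x01       0.0434 0.0583   0.0511     1
#> 2 x02       0.0433 0.0415   0.0424     2
#> 3 x04       0.0390 0.0406   0.0398     3
#> 4 x05       0.0343 0.0431   0.0388     4
#> 5 x03       0.0356 0.0372   0.0364     5
#> 6 x16       0.0356 0.0328   0.0342     6
#> 7 x12       0.0337 0.0344   0.0341     7
```

Training selected epoch 453 by validation early stopping; the mean fusion
weight `a1 ≈ 0.49` says the primary branch and the shared branch
contribute almost equally. On the 30 held-out samples the model explains
about 45% of the outcome variance (MSE 1.02, median absolute error 0.55 on
a unit-scale target). The contribution table ranks the five generatively
informative features (`x01`–`x05`) in the top five; `specific` and
`shared` are the per-branch contribution shares and `combined` their
fusion-weighted sum, which sums to 1 over features.

`predict()` returns a tibble of predictions, `glance()` a one-row fit
summary, `autoplot()` the training curves, and
`plot_contributions(tidy(fit))` the ranking bar chart. `write_gatan()` /
`read_gatan()` round-trip a fitted model through a JSON archive exactly.

A command-line interface wraps the same pipeline:

```sh
Rscript exec/gatan simulate --n 160 --p 30 --seed 1 --out data.csv
Rscript exec/gatan train --data data.csv --primary-target y --aux-target aux1 --out model.json
Rscript exec/gatan evaluate --model model.json --data data.csv
Rscript exec/gatan rank --model model.json --data data.csv --out contributions.csv
```

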