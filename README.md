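# milkorder

Unsupervised analysis of dairy **milking-order** records — the sequence in
which cows enter the milking parlor, logged automatically by RFID at every
milking. For ethologists and precision-livestock researchers, these
records are a free behavioral signal from commercial herds, but they are
ordinal, heterogeneous across animals, non-independent (every cow moving
forward pushes others back), and non-stationary in ways that defeat
standard summary statistics. `milkorder` provides the exploratory toolkit
for such data, plus a synthetic herd generator with planted, recoverable
structure so the entire pipeline is testable without farm data.

## What it computes

Entry positions are first normalized to **entry quantiles**
`q = position / N_d ∈ (0, 1]` (with `N_d` the cows recorded that day) and
filtered (warm-up window, management-change windows, a 75% daily-coverage
rule, a 50% cow-attendance rule). On the resulting cows × days matrix:

* **Stochasticity via conditional Shannon entropy.** With the queue cut
  into K = 20 segments,

  `H_q = −Σ_c (n_c|q / N_q) log2(n_c|q / N_q)`  — entropy of cow identity
  within queue segment `q`;

  `H_c = −Σ_q (n_q|c / N_c) log2(n_q|c / N_c)`  — entropy of segment
  membership within cow `c`.

  Low entropy = consistent behavior; the analytic maxima `log2(#cows)` and
  `log2 K` are the purely-random references. Significance comes from
  within-day permutation nulls (each cow against its own null; add-one
  p-values). Per-cow variance is computed alongside as the conventional
  contrast — unlike entropy it cannot recognize a cow that enters either
  first or last as consistent.

* **Inter-animal structure.** PCA on the pairwise-complete correlation
  matrix, and a diffusion map built from missingness-scaled Euclidean
  distances → inverted similarities → k = 10 nearest-neighbor graph →
  spectral decomposition of the (normalized) graph Laplacian, with
  relative-eigengap dimension selection, a within-day-permuted null
  control, and closed-form harmonic (path-graph) reference curves to label
  embedding artifacts on chain-like data.

* **Temporal dynamics.** Pen-vs-pasture consistency of per-cow median
  quantiles (Pearson R, Kendall tau-b), and **Data Mechanics** iterative
  co-clustering: cows and days are alternately Ward-clustered, each axis
  re-represented by the other's cluster means, converging to a minimally
  heterogeneous cell partition. A 10 × 10 granularity grid exposes
  subgroup-specific non-stationarity and persistently isolated **outlier
  days**.

* **Association tests.** Mutual conditional entropy
  `MCE = ½{H(A|B) + H(B|A)}` between queue-derived clusterings and cow
  attributes or hourly accelerometer time budgets, with label-permutation
  p-values and metaparameter selection over a (k_a, k_b) grid by minimal
  average marginal rank, reported in the `p_{ka,kb}` convention. Sensor
  records can be windowed into morning / afternoon / night lounging
  periods, and tube-plot median tables summarize behavior by queue group.

## Worked example

```r
library(milkorder)

cfg    <- sim_config(seed = 42)          # 200 cows, 80 days (26 pen / 54 pasture)
study  <- simulate_study(cfg)
qm     <- to_quantiles(study$log)
qm     <- filter_days(qm, warmup = 0, drop_windows = NULL)   # synthetic data has no warm-up
qm     <- filter_cows(qm)
qmh    <- subset_healthy(qm, study$profiles)
qmh
#> <quantile_matrix> 129 cows x 80 days (26 pen, 54 pasture), 4.7% missing

queue_stochasticity(qmh, B = 1000, seed = 1)
#> <stochasticity> 129 cows, 20 segments, B = 1000 permutations
#>   cows rejecting randomness at alpha = 0.05: 129/129 (entropy), 129/129 (variance)

subperiod_consistency(qm)
#> <subperiod_summary> 200 cows; Pearson R = 0.947 (p = <2e-16), Kendall tau = 0.826 (p = <2e-16)

diffusion_map(qmh)
#> <queue_embedding> method = diffusion, 129 cows, 10 dims retained, 1 significant

grid <- dm_grid(qm, max_iter = 10)
flag_outlier_days(grid)
#> [1] "45" "48" "50" "51"
```

Reading the output: every cow queues non-randomly (entropy far below the
`log2(20) = 4.32`-bit random reference, permutation p ≤ 0.05), median
positions are strongly conserved across the housing change (R = 0.95), the
herd's inter-animal structure is one-dimensional (a single dominant
eigengap — cows ordered by preferred position, no social clusters), and
the co-clustering grid isolates exactly the four days on which the
simulator scrambled the whole herd's queue.

`run_pipeline(cfg, outdir)` executes all of the above end to end and
writes CSV tables, PNG figures, and a JSON run manifest;
`inst/scripts/run-milkorder.R` is a thin command-line wrapper around it.

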