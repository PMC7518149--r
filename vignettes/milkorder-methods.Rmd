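---
title: "Methods: unsupervised analysis of milking-order records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: unsupervised analysis of milking-order records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(milkorder)
```

## The problem

Rotary milking parlors log the order in which cows enter at every milking.
Over months, a 200-cow herd produces a dense ordinal panel: thousands of
(day, cow, entry position) records riddled with missing entries from RFID
misreads and hospital-pen absences. Such data hold behavioral signal — do
individual cows keep stable queue positions? does the social structure of
the queue change when overnight housing changes? are queue positions tied
to production traits or to home-pen activity budgets? — but the records are
heterogeneous, non-independent between animals, and non-stationary in
complicated ways. `milkorder` implements an unsupervised toolkit for this
kind of data: entropy-based stochasticity quantification, spectral
embeddings of inter-animal relationships, Data Mechanics co-clustering for
temporal structure and outlier days, and mutual-conditional-entropy (MCE)
association tests. A synthetic herd generator with planted, recoverable
structure makes every stage testable without access to farm data.

## Data model and wrangling

The raw unit is the **milk log**: per day, the ordinal entry position of
each recorded cow. Positions are normalized to **entry quantiles**
$q = \text{position} / N_d \in (0, 1]$, where $N_d$ is the number of cows
recorded that day; this removes uncontrolled daily variation in herd size
(a cow that always enters last has $q = 1$ regardless of $N_d$). The
central container is the cows × days `quantile_matrix`, with `NA` the only
missing marker — zero is outside the valid range, so absences can never
masquerade as leading positions.

Three record filters are applied day-first, then cow-wise:

* a warm-up window (default 55 days for raw farm logs, during which rolling
  enrollment lets the herd settle; the simulator emits post-warm-up data,
  so pipelines on synthetic data pass `warmup = 0`);
* drop windows around management changes (defaults: the 2 days before the
  transition to overnight pasture, the 4 days after, and the final 7 days
  of trial, derived from the subperiod labels);
* a coverage rule removing days on which fewer than 75% of the enrolled
  herd was recorded. The denominator is the enrolled herd size that day,
  supplied by the simulator or a roster file; whether hospital-pen cows
  count is farm-specific, so the denominator is an explicit input.

Cows present in fewer than half of the surviving milkings are then removed;
the boundary is inclusive (exactly 50% attendance survives), following the
usual "at least 50%" phrasing of such rules.

## Quantifying stochasticity

The queue is discretized into $K = 20$ equal segments of the quantile
scale. Bins are half-open, $((j-1)/K,\, j/K]$: quantiles are strictly
positive and reach exactly 1, so this convention covers the range with no
empty edge bin. Two conditional Shannon entropies (base 2 throughout) are
computed from the pooled segment counts:

$$H_q = -\sum_c \frac{n_{c|q}}{N_q} \log_2 \frac{n_{c|q}}{N_q}, \qquad
  H_c = -\sum_q \frac{n_{q|c}}{N_c} \log_2 \frac{n_{q|c}}{N_c},$$

the entropy of cow identity within each queue segment, and of segment
membership within each cow. Their analytic maxima, $\log_2(\#\text{cows})$
and $\log_2 K$, are the "purely random queue" reference lines
($\log_2 114 \approx 6.83$ bits for a 114-cow herd, $\log_2 20 \approx
4.32$ bits per cow). Against per-cow variance, entropy is scale-free,
robust to outliers, and treats multimodal patterns correctly: a cow that
enters either first or last has entropy 1 bit (highly consistent) but
near-maximal variance — a divergence the test suite checks directly.

Significance is assessed by permuting quantiles **within each observation
day** (preserving both each day's quantile multiset and the missingness
pattern) and recomputing the statistic, default $B = 5000$ times. Three
numerical choices are deliberate:

* one-sided p-values use the add-one correction
  $p = (1 + \#\{T_{\text{null}} \le T_{\text{obs}}\}) / (B + 1)$, so $p$
  is never exactly 0 and ties count conservatively;
* each cow is compared against **its own** permutation null rather than a
  pooled null: attendance patterns differ between cows, and a pooled null
  would miscalibrate low-attendance animals. This is the conservative
  reading of a shared 5,000-permutation stream;
* the per-segment null reference and both per-cow tests are fed by one
  shared permutation stream per run (`queue_stochasticity()`), which keeps
  the summary internally consistent and halves the cost.

## Embeddings of inter-animal relationships

Cow–cow dissimilarity is the missingness-scaled Euclidean distance
$d_{ij} = \sqrt{(T/|S_{ij}|) \sum_{t \in S_{ij}} (q_{it} - q_{jt})^2}$,
where $S_{ij}$ is the set of days with both cows recorded. The $T/|S|$
factor exactly compensates masking: hiding half the days of a
constant-difference pair leaves the distance unchanged (a test). Pairs
with fewer than `overlap_min = 10` shared days are an error rather than a
silent extrapolation.

**PCA** treats days as variables: the day × day correlation matrix uses
pairwise-complete cow pairs, and scores are computed after per-day
standardization with missing cells set to the post-standardization day
mean (0). Mean-filling is isolated in one place so alternatives (row
medians) can be swapped; the Kaiser rule (eigenvalues > 1) counts
"significant" dimensions and the full scree is exported for a manual
override, since any automatic rule on real data deserves an audit.

**Diffusion map**: distances are inverted to similarities
($s = 1/d$; a zero distance between distinct cows is capped at 10× the
largest finite similarity — the cap only matters for duplicated records and
is flagged as a modeling convenience), a k-nearest-neighbor graph
(union-symmetrized, $k = 10$) is built, and the symmetric normalized
Laplacian $L = I - D^{-1/2} W D^{-1/2}$ is eigendecomposed. Coordinates
are the eigenvectors of the smallest non-trivial eigenvalues (trivial =
numerically zero, one per connected component). Unnormalized and
random-walk Laplacians are exposed as a switch, and a test asserts the
recovered geometry is robust across all three — a qualitative claim should
not hinge on a normalization. Each eigenvector is sign-oriented to
correlate non-negatively with median entry quantile, for plot stability.

Dimension selection uses the largest **relative** eigengap
$\lambda_{i+1}/\lambda_i$ among the first `n_dims_max` non-trivial
eigenvalues. Relative gaps discriminate sharply in practice: a herd with a
1-D latent order shows $\lambda_2/\lambda_1 \approx 7$ and larger, while
within-day-permuted data yields a flat spectrum with all ratios near 1.05
(absolute gap differences, by contrast, fluctuate enough across
permutations to be useless as a null control).

Chain-like ("rope") data imprint a cosine harmonic series on spectral
embeddings. `harmonic_reference()` returns the closed-form eigenvectors of
the path-graph Laplacian, $v_k(j) = \cos(\pi k (j + 0.5)/n)$, for overlay
against coordinates sorted by the first axis: curvature matching these
curves is an embedding artifact, not herd structure. The tests verify the
overlay correlates at $|r| \ge 0.8$ on a simulated herd — the artifact is
reproduced and labeled, not hidden.

## Data Mechanics co-clustering

`dm_cocluster()` alternately clusters cows and days, each axis informing
the other's metric: (1) scaled Euclidean distances between rows and
between columns of the current representations; (2) Ward D2 trees cut at
$r$ and $c$; (3) each day re-represented by its $r$-vector of
within-cow-cluster mean quantiles and each cow by its $c$-vector of
within-day-cluster means. The cross-axis update realized as
distance-in-cluster-mean-space is this module's central interpretation of
"weighted distance" sharing between axes; it is isolated behind one
function so alternates can be tested. Iteration stops when the label pair
repeats exactly; energy (the sum of within-cell variances of the original
entries, missing cells excluded) is recorded per iteration, and if labels
cycle without converging the minimum-energy iterate is returned with
`converged = FALSE`. Convergence is on labels, not energy, because energy
can plateau while labels oscillate. The algorithm is deterministic: same
input, same output, no randomness anywhere.

Note that energy as defined (unweighted sum of cell variances) is **not**
monotone under grid refinement — splitting a pure-noise cell adds one more
noise variance to the sum, and splitting the day axis under a single row
cluster can increase it substantially. It is a within-fit convergence
diagnostic and a between-fit comparison at fixed $(r, c)$, not a model
selection criterion; accordingly `dm_grid()` reports it alongside cluster
sizes and subperiod purity, and granularity selection remains a visual
decision, which the package supports but does not automate.

Whole-herd **outlier days** are flagged from the grid: a day qualifies if,
across all grid cells with at least 6 column clusters (all row
granularities), it lands in a column cluster of size ≤ `max_size` in at
least 80% of cells. Persistence across row granularities separates
herd-level anomalies from ordinary cluster-boundary days. The default
`max_size = 4` reflects a structural property of co-clustering: several
anomalous days sharing one signature (a single disruptive event spanning a
few milkings) cluster with *each other*, not as singletons, so the size
cap must be at least the number of simultaneously anomalous days one wants
to catch. With `max_size = 2` the detector can only find anomalies that
are pairwise dissimilar.

## MCE association tests

Two clusterings of the same cows form a contingency table; the mutual
conditional entropy is the average of the two weighted conditional
entropies,
$\mathrm{MCE} = \tfrac12\{H(A \mid B) + H(B \mid A)\}$ (bits, $0 \log 0
= 0$). MCE is 0 iff the labelings determine each other and grows toward
$\tfrac12(\log_2 k_a + \log_2 k_b)$ for independent uniform labels. The
permutation test shuffles one labeling across cows ($B = 2000$ by
default), with the same add-one, ties-count-as-extreme convention as the
stochasticity tests; which labeling is shuffled is fixed (the attribute
side) for reproducibility, the test being symmetric in theory.

Cluster counts are metaparameters. `mce_grid_select()` evaluates the full
$(k_a, k_b)$ grid (2–10 by default on both axes) and selects the cell
minimizing the **average marginal rank**: the rank of the cell's p-value
within its grid row plus within its grid column, averaged; ties break
toward the smallest $k_a + k_b$, then smallest $k_a$, so a flat
(null) grid falls back to the most parsimonious (2, 2). Ranking p-values
rather than raw MCE is this package's reading of the selection rule — raw
MCE always favors larger $k$ because entropy scales with table size — and
the alternative is available behind `rank_on = "mce"`. Results are
reported in the $p_{k_a,k_b}$ subscript convention. Because selection
scans a grid of tests, the suite checks empirically that the fixed-$(k_a,
k_b)$ pipeline's type-I error stays at nominal; no multiplicity adjustment
is applied across sensor channels and windows, matching exploratory
reporting practice (`p.adjust` can be applied downstream by the user).

For sensor data, `sensor_subsets()` carves the hourly records into
lounging-period windows — morning 07–12, afternoon 13–19, night 21–04
(wrapping midnight). These boundaries are package defaults bracketing a
thrice-daily milking routine, not measured values from any herd, and are
plain configuration.

## The synthetic herd generator

The generator is first-class, tested code: its planted structure is the
ground truth for every recovery test. Defaults describe the study
conditions the analyses target:

| parameter | default | meaning |
|---|---|---|
| `n_cows` | 200 | closed mixed-parity herd |
| `n_days` / `pen_days` | 80 / 26 | observation days; first 26 with overnight pen housing, remaining 54 with pasture access |
| `missing_rate` | 0.05 | per cow-day missing record probability |
| `sigma_min`, `sigma_max` | 0.02, 0.20 | daily positional noise SD at queue extremes / center |
| `shift_fraction`, `shift_magnitude` | 0.10, 0.30 | mid-queue subgroup with a subperiod position shift |
| `outlier_days` | 4 days mid-pasture | whole-herd anomalous milkings |
| `attr_rho` | 0.70 | age–peak-yield correlation |
| `health_rate` | 0.35 | cows with ≥1 recorded health event |
| `sensor_effect` | 5 min/h | rear-quartile activity offset during lounging |

Design choices worth spelling out:

* **Score-and-rank queue model.** Each cow draws a daily latent score
  $s = \mu + \text{shift} \cdot 1[\text{pasture}] + N(0, \sigma)$ and the
  present cows are ranked (ties broken by cow id, standing in for unique
  RFID read times). No generative mechanism of queue formation (individual
  preference vs. jockeying) is established in the literature; score-and-
  rank is one consistent choice and is flagged as such. Rank compensation
  is automatic: any cow moving forward pushes others back.
* **Parabolic noise** $\sigma(\mu) = \sigma_{\min} + (\sigma_{\max} -
  \sigma_{\min})(1 - 4(\mu - 0.5)^2)$ reproduces the well-documented
  U-shape: consistency is highest at the front and rear of the queue. The
  field describes the pattern, not a law; the coefficients are exposed.
  Note the implied sign: cow entropy *falls* as the median quantile
  approaches either extreme, so the U-shape check is a strongly negative
  rank correlation between $H_c$ and $|\text{median} - 0.5|$.
* **Forward subperiod shifts.** The planted shifting subgroup moves toward
  the head of the queue (all one direction), matching the observed
  tendency of extreme shifts; the compensatory backward subgroup emerges
  from rank compensation rather than being planted. Random-sign shifts
  would largely cancel in cluster-mean space and would not reproduce the
  clean two-cluster pen/pasture stratification the co-clustering analysis
  is meant to expose.
* **Outlier-day transform** $s' = 1 - 2|s - 0.5|$: a measure-preserving
  swap sending queue extremes to the center and inverting the center.
  Any center/extreme swap would serve; this one is closed-form and keeps
  each day's quantile multiset valid. Because all outlier days share this
  transform, they co-cluster (see `max_size` above).
* **Health events** are independent of queue position by default
  (`health_mu_coupling = 0`), consistent with sick animals appearing
  evenly dispersed along the queue; a coupling knob exists for power
  studies.
* **Sensor budgets** are Dirichlet draws around hour-block mean budgets
  with concentration 60, so every cow-hour sums to exactly 60 minutes and
  the planted rear-quartile activity offset is exact in expectation
  (compensated out of non-activity).

What the generator does **not** emulate: social cohesion (cows move
independently given their preferences — which is why the embedding tests
expect *no* clustering), disease progression, weather, estrus, or feeding
treatments; sensor channels are conditionally independent across hours
given the hour-block means, unlike real accelerometer streams with strong
autocorrelation. Passing recovery tests therefore show the algorithms
recover the structure they claim to recover under a fair, realistic noise
model — not that real herds contain such structure, nor that effect sizes
on a farm resemble the planted ones.

## Problem sizes and numerical tolerances

Oracle-equivalence tests (entropy, variance, MCE, Kendall tau) run at
tolerance 1e−12 against explicit term-by-term summations on fixtures of
≤ 120 cows. Monte-Carlo checks use fixed seeds and the following sizes,
chosen so the whole suite completes in a few minutes: calibration of the
permutation tests on 500 exchangeable cows × 60 days at $B = 1000$;
U-shape and embedding recovery on the default 200-cow herd; outlier-day
recovery on 50 replicates of a 100-cow × 60-day herd (grid capped at 5
iterations per fit); sensor-association power on 50 replicates of a
120-cow × 15-day herd at $B = 300$. The acceptance script
(`scripts/acceptance.R`) re-runs the same analyses at these sizes from a
single command-line seed. Eigen-decompositions use LAPACK via `eigen(...,
symmetric = TRUE)`; Laplacian eigenvalues are clamped against −1e−10
round-off, and quantile-to-segment mapping subtracts 1e−9 before the
ceiling to keep exact bin edges (`position/N` ratios) in their closed bin.

## Known limitations

* The co-clustering cross-axis update is one concrete realization of
  metric sharing between axes; other weighted-distance constructions are
  plausible and may converge differently. The update sits behind a single
  internal interface (`cluster_mean_repr()` + `repr_distance()`) so
  alternates can be evaluated.
* MCE cannot adjust for confounders; associations it finds are bivariate.
* Grid selection for MCE is rank-based and can select different cells on
  near-flat surfaces; the full grid is always returned.
* `flag_outlier_days` assumes anomalies are rare relative to `c`; with
  more than `max_size` simultaneously anomalous days sharing one
  signature, the isolation criterion fails by construction.
* Real parlor logs need a roster to define the daily coverage denominator;
  the simulator supplies it, farm data may not.
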