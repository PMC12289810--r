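# flatmetric

Computing distances between distributions of **unequal total mass**.

Optimal-transport distances such as Wasserstein-1 compare shapes but are
undefined when the two measures carry different mass; total variation sees
mass but ignores geometry entirely. The **flat metric** (dual bounded
Lipschitz distance / Fortet–Mourier distance)

```
rho_F(mu, nu) = sup { integral f d(mu - nu) : ||f||_inf <= 1, |f|_Lip <= 1 }
```

interpolates: mass moves at transport cost up to distance 2, beyond which it
is cheaper to delete and recreate it at unit cost. This makes it the natural
metric when sample size or population size is part of the signal — growing
cell populations in single-cell transcriptomics, cluster-size-aware
matching, unnormalizable intensities.

The package provides:

* **Exact solvers** for discrete measures — `flat_exact()` (the dual LP,
  solved via an equivalent min-cost transportation problem with
  creation/deletion arcs, returning the optimal test function),
  `wasserstein_exact()`, `tv_distance()`, and closed forms
  `dirac_sphere_flat()` / `one_point_flat()` for Dirac configurations.
* A **neural estimator** — `train_flat()` trains a spectrally normalized
  GroupSort network (a certified 1-Lipschitz critic) to maximize the dual
  objective with an adaptively weighted sup-norm penalty; `-L_m` at
  convergence is the distance estimate. `train_wasserstein()` is the same
  critic with the bound switched off, for comparison columns.
* A **calibration pipeline** — `run_experiment1()` measures the estimator's
  systematic relative error on Dirac-sphere configurations with exact ground
  truth; `fit_correction()` models it as a negative log-normal surface in
  (mass ratio, dimension); `apply_correction()` removes it.
  `run_experiment2()` validates on arbitrary-support configurations.
* **Synthetic studies** — Gamma-Poisson single-cell-like count clusters
  (`simulate_clusters()`, `cluster_distance_table()`), unbalanced domain
  matching (`domain_match()`), and grayscale benchmark images
  (`generate_benchmark_images()`, `image_pixel_residuals()`).
* A CLI, `inst/cli/flatdist`, with subcommands
  `exact | compute | calibrate | validate | demo`.

## Worked example

Two point clouds from the same standard normal, but with 200 vs 30 points —
identical in shape, very different in mass:

```r
library(flatmetric)
set.seed(7)
mu <- discrete_measure(matrix(rnorm(400, sd = 1), 200, 2), label = "big")
nu <- discrete_measure(matrix(rnorm(60,  sd = 1),  30, 2), label = "small")

flat_exact(mu, nu)$value                              # 174.6071
wasserstein_exact(mu, nu, normalize = TRUE)$value     # 0.4369344
tv_distance(mu, nu)                                   # 230

est <- train_flat(mu, nu, seed = 1, calibration = default_calibration())
est
#> <distance_estimate (flat): raw 172.281, corrected 174.4,
#>  sup violation +0.0263, Lip bound certified <= 1>
```

Reading the numbers: normalized Wasserstein (0.44, pure sampling noise)
cannot tell the clouds apart; TV (230, the sum of both masses) sees no
geometry at all; the flat distance (174.6) is dominated by the 170-unit mass
gap (deleting the surplus costs 1 per unit; `rho_F >= |170|` always) plus a
small transport term. The neural estimate lands within 1.3% of the LP raw,
and within 0.1% after calibration; the certificate line reports the max
|f| excess over 1 on the support (penalized, soft) and the analytic
Lipschitz bound (architectural, always certified).

The mass-aware matching demo:

```r
dm <- domain_match(seed = 1)
dm$flat_assignment          # X:A  Y:B  Z:C   (mass-consistent line-up)
dm$wasserstein_assignment   # X:A  Y:B  Z:B   (mass-blind mismatch)
```

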