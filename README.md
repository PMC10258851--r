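# spectmap

Unsupervised learning of **slow collective variables (CVs)** from
high-dimensional molecular configuration descriptors, with free-energy
landscape estimation in the learned CV space. The package is aimed at
people analyzing equilibrium sampling of metastable systems — e.g. long
protein-folding trajectories represented by pairwise Cα–Cα distances — who
need one or two coordinates that resolve the rare transitions between
long-lived states rather than the fast intra-state noise.

## Method

A feed-forward mapping `z = ξ_θ(x)` projects `n` configuration descriptors
to `d ≪ n` CVs. On each minibatch of projected samples, a Markov chain is
built geometrically (no time series needed):

    g_kl = exp(−‖z_k − z_l‖² / ε)            Gaussian kernel
    κ_kl = g_kl / √(ϱ_k ϱ_l),  ϱ_k = Σ_l g_kl  anisotropic diffusion kernel
    m_kl = κ_kl / Σ_j κ_kj                    row-stochastic transition matrix

The spectrum `1 = λ₀ ≥ λ₁ ≥ …` of `M` (computed through the symmetric
conjugate `S = D^{−1/2} κ D^{−1/2}`, so it is provably real) measures
time-scale separation; for an assumed number of metastable states `k`, the
**spectral gap** `σ_k = λ_{k−1} − λ_k` is maximized with respect to θ by
backpropagating its analytically derived gradient (eigenvalue perturbation
`dλ = vᵀ dS v`, chained through both density normalizations, the Gaussian
kernel and — under the median heuristic — the scale ε itself). The
free-energy landscape of the learned CVs is the Boltzmann inversion
`F(z) = −(1/β) ln p(z)` of their histogram, min-shifted to zero, with
empty bins flagged unreachable.

Everything is plain R; the only imports are `withr` and `yaml`.

## Worked example

The packaged two-state benchmark integrates overdamped Langevin dynamics in
a quartic double well (barrier 5 kT at 300 K = 12.47 kJ/mol) and lifts the
trajectory into 40 noisy features. Training uses every 10th sample; the
trained network then evaluates the full trajectory:

```r
library(spectmap)

bench   <- make_benchmark("two_state", n_samples = 50000, seed = 1,
                          stride = 10)
x_train <- bench$features[seq(1, 50000, by = 10), ]   # 5000 samples

fit <- train_mapping(x_train, mapping_config(n_in = 40, seed = 1))
fit$history[c(1, 100), ]
#>     epoch sigma_batch sigma_monitor
#> 1       1   0.3063136     0.3513782
#> 100   100   0.8391477     0.8585431

z <- predict(fit, bench$features)
abs(cor(z[, 1], bench$slow, method = "spearman"))
#> [1] 0.8245415

prof <- marginal_profile(z, axis = 1, bins = 100, thermo = bench$thermo)
barrier_height(prof)
#> [1] 11.35573
```

The monitor spectral gap rises from 0.35 after the first epoch to 0.86:
the embedding separates two long-lived states with fast internal
relaxation. `z1` tracks the generator's hidden slow coordinate (rank
correlation 0.82), and the free-energy profile along `z1` shows a barrier
of 11.4 kJ/mol against the generator's analytic 12.47 kJ/mol. To choose
the number of metastable states on unknown data, scan it:

```r
scan <- scan_k(x_train, mapping_config(n_in = 40, epochs = 40, seed = 1),
               k_values = 2:4)
scan$table
#>   k     sigma
#> 1 2 0.8814104
#> 2 3 0.6156427
#> 3 4 0.3185567
```

The gap peaks at `k = 2` — the generator's true state count — and decays
as additional states are forced to split a genuine basin. (See the
vignette for an important caveat on reading this curve for systems with
more states: state-merging embeddings can hold the `k = 2` gap high.)

A shell interface covers the same pipeline
(`exec/spectmap simulate | featurize | train | scan-k | project | fes |
inspect-kernel`); every run writes its fully resolved configuration next
to its outputs.

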