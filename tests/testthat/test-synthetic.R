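# Langevin sampler, model potentials, linear lift and packaged benchmarks.

test_that("model potentials are consistent at their stated minima", {
  for (name in c("double_well_1d", "double_well_2d", "three_well_2d")) {
    pot <- model_potential(name)
    expect_lt(max(abs(pot$U(pot$minima) - pot$minima_energy)), 1e-9)
    # gradient vanishes at refined minima
    expect_lt(max(abs(pot$grad(pot$minima))), 1e-5)
    expect_true(is.finite(pot$barrier) && pot$barrier > 0)
  }
  dw <- model_potential("double_well_1d")
  expect_equal(dw$barrier, 5 * 0.0083144626 * 300, tolerance = 1e-9)
  tw <- model_potential("three_well_2d")
  expect_equal(nrow(tw$minima), 3L)
})

test_that("zero-step simulation returns only the initial point", {
  pot <- model_potential("harmonic", curvature = 50)
  trj <- simulate_langevin(pot, langevin_config(n_steps = 0, seed = 1))
  expect_equal(dim(trj$latent), c(1L, 1L))
  expect_equal(trj$latent[1, ], pot$minima[1, ])
})

test_that("harmonic stationary variance matches 1/(beta a) within 5%", {
  a <- 50
  th <- thermo(300)
  pot <- model_potential("harmonic", curvature = a)
  # timestep small enough that the Euler-Maruyama variance bias (~a dt / 2)
  # is well below the 5% band being tested
  trj <- simulate_langevin(pot, langevin_config(
    n_steps = 4e5, thermo = th, timestep = 5e-4, stride = 40, seed = 5))
  v <- var(trj$latent[-1, 1])
  expect_lt(abs(v - 1 / (th$beta * a)) / (1 / (th$beta * a)), 0.05)
})

test_that("double-well occupancies match quadrature Boltzmann weights", {
  th <- thermo(300)
  pot <- model_potential("double_well_1d", tilt = 3)  # asymmetric wells
  trj <- simulate_langevin(pot, langevin_config(
    n_steps = 8e5, thermo = th, timestep = 0.002, stride = 20, seed = 6))
  s <- trj$latent[-1, 1]
  in_deep <- s < pot$saddle  # tilt > 0 deepens the left well
  w_oracle <- oracle_boltzmann_weight_1d(
    function(x) pot$U(cbind(x)), th$beta, -4, pot$saddle)
  expect_gt(w_oracle, 0.5)
  se <- batch_se(in_deep)
  expect_lt(abs(mean(in_deep) - w_oracle), 3 * se + 1e-12)
})

test_that("equilibrium histogram is consistent with exp(-beta U) / Z", {
  th <- thermo(300)
  pot <- model_potential("double_well_1d")
  trj <- simulate_langevin(pot, langevin_config(
    n_steps = 1e6, thermo = th, timestep = 0.002, stride = 20, seed = 7))
  s <- trj$latent[-1, 1]
  edges <- seq(-1.6, 1.6, length.out = 13)
  counts <- histogram_density(s, bins = edges)$counts
  w <- vapply(seq_len(length(edges) - 1L), function(b)
    integrate(function(x) exp(-th$beta * pot$U(cbind(x))),
              edges[b], edges[b + 1], rel.tol = 1e-10)$value, numeric(1))
  keep <- counts >= 5
  # chi-square against quadrature weights, inflated by the correlation time
  # estimated from batch means (samples are not independent)
  n_eff <- (mean(s < 0) * (1 - mean(s < 0))) / batch_se(s < 0)^2
  infl <- length(s) / n_eff
  chi2 <- sum((counts[keep] - sum(counts) * w[keep] / sum(w))^2 /
                (sum(counts) * w[keep] / sum(w))) / infl
  expect_gt(pchisq(chi2, df = sum(keep) - 1, lower.tail = FALSE), 0.01)
})

test_that("simulation is seeded, guarded and stability-checked", {
  pot <- model_potential("double_well_1d")
  cfg <- langevin_config(n_steps = 2000, stride = 10, seed = 11)
  t1 <- simulate_langevin(pot, cfg)
  t2 <- simulate_langevin(pot, cfg)
  expect_identical(t1$latent, t2$latent)
  expect_warning(
    simulate_langevin(pot, langevin_config(n_steps = 10, timestep = 0.006,
                                           stride = 1, seed = 1)),
    "unstable")
  expect_error(
    suppressWarnings(simulate_langevin(pot, langevin_config(
      n_steps = 50, timestep = 0.1, stride = 1, seed = 1))),
    class = "spectmap_numerical_error")
})

test_that("linear lift: identity, isometry and decodability", {
  set.seed(51)
  latent <- matrix(rnorm(200), ncol = 2)

  # identity lift at matching dimensions and zero noise
  l0 <- lift_config(2, 2, noise_sigma = 0, seed = 1)
  l0$mixing <- diag(2)
  expect_equal(unname(lift_to_features(latent, l0)), latent)

  # orthonormal lift preserves pairwise distances at zero noise
  l1 <- lift_config(15, 2, noise_sigma = 0, seed = 2)
  x <- lift_to_features(latent, l1)
  expect_lt(max(abs(dist(x) - dist(latent))), 1e-10)

  # default system: slow coordinate linearly decodable with R^2 > 0.95
  bench <- make_benchmark("two_state", n_samples = 1500, seed = 3)
  fit <- lm(bench$slow ~ bench$features)
  expect_gt(summary(fit)$r.squared, 0.95)
})

test_that("benchmarks are deterministic with sane ground truth", {
  b1 <- make_benchmark("two_state", n_samples = 300, seed = 5)
  b2 <- make_benchmark("two_state", n_samples = 300, seed = 5)
  expect_identical(b1$features, b2$features)
  expect_identical(b1$labels, b2$labels)
  expect_setequal(unique(b1$labels), 1:2)
  expect_equal(ncol(b1$features), 40L)

  b3 <- make_benchmark("three_state", n_samples = 400, seed = 5)
  expect_equal(sort(unique(b3$labels)), 1:3)
  expect_equal(nrow(b3$potential$minima), 3L)
})

test_that("three-state occupancies match 2-D quadrature weights", {
  bench <- make_benchmark("three_state", n_samples = 6000, seed = 2)
  th <- bench$thermo
  w <- oracle_boltzmann_weights_2d(bench$potential$U, th$beta,
                                   bench$potential$minima)
  occ <- tabulate(bench$labels, 3) / length(bench$labels)
  for (s in 1:3) {
    se <- batch_se(bench$labels == s)
    expect_lt(abs(occ[s] - w[s]), 3 * se + 0.01)
  }
})
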