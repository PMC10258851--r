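# Kernel pipeline: Gaussian kernel, density, anisotropic normalization,
# transition matrix and spectrum, against brute-force oracles.

test_that("gaussian kernel matches closed forms and the double-loop oracle", {
  # zero distance and analytically forced entry
  z <- rbind(c(0, 0), c(0, 0))
  g <- gaussian_kernel(z, kernel_scale("fixed", epsilon = 0.3))
  expect_equal(g[1, 2], 1)
  z <- rbind(0, sqrt(0.7))  # squared distance 0.7 = epsilon
  g <- gaussian_kernel(z, kernel_scale("fixed", epsilon = 0.7))
  expect_equal(g[1, 2], exp(-1), tolerance = 1e-12)

  set.seed(11)
  z <- rand_cvs(5, 2)
  g <- gaussian_kernel(z, kernel_scale("fixed", epsilon = 0.7))
  expect_lt(max(abs(g - oracle_gaussian(z, 0.7))), 1e-12)
  expect_identical(g, t(g))
  expect_true(all(diag(g) == 1))
  expect_true(all(g > 0 & g <= 1))
})

test_that("gaussian kernel validates its inputs", {
  expect_error(gaussian_kernel(matrix(c(0, NA), 2, 1)),
               class = "spectmap_invalid_input")
  expect_error(gaussian_kernel(matrix(1, 1, 1)),
               class = "spectmap_invalid_input")
  expect_error(kernel_scale("fixed", epsilon = -1),
               class = "spectmap_parameter_error")
})

test_that("epsilon resolution: fixed passthrough and median heuristic", {
  z <- rand_cvs(5, 2)
  expect_identical(resolve_epsilon(z, kernel_scale("fixed", epsilon = 0.5)),
                   0.5)
  # collinear points at 0, 1, 2: squared distances {1, 4, 1}, median 1
  z3 <- matrix(c(0, 1, 2), 3, 1)
  expect_equal(resolve_epsilon(z3), 1)

  set.seed(12)
  z <- rand_cvs(50, 3)
  expect_equal(resolve_epsilon(z, kernel_scale(multiplier = 2)),
               2 * oracle_median_sq_dist(z), tolerance = 1e-12)
  # coincident points fall back to the machine-epsilon floor
  expect_gt(resolve_epsilon(matrix(0, 4, 2)), 0)
})

test_that("density estimate is the row sum of the Gaussian kernel", {
  expect_equal(density_estimate(matrix(1, 3, 3)), c(3, 3, 3))
  set.seed(13)
  z <- rand_cvs(5, 2)
  g <- gaussian_kernel(z, kernel_scale("fixed", epsilon = 0.7))
  rho <- density_estimate(g)
  oracle <- vapply(1:5, function(k) sum(g[k, ]), numeric(1))
  expect_lt(max(abs(rho - oracle)), 1e-12)
  expect_true(all(rho >= 1))
  # isolated-points limit: off-diagonals vanish as epsilon -> 0
  g0 <- gaussian_kernel(z, kernel_scale("fixed", epsilon = 1e-12))
  expect_equal(density_estimate(g0), rep(1, 5), tolerance = 1e-8)
})

test_that("anisotropic kernel divides by the geometric mean of densities", {
  # two identical points: g = 1 everywhere, densities 2 -> kappa = 1/2
  z <- matrix(0, 2, 1)
  g <- gaussian_kernel(z, kernel_scale("fixed", epsilon = 1))
  kap <- anisotropic_kernel(g, density_estimate(g))
  expect_equal(kap[1, 2], 0.5)

  # constant density c reduces to g / c
  g <- matrix(0.5, 4, 4); diag(g) <- 1
  rho <- density_estimate(g)
  expect_equal(anisotropic_kernel(g, rho), g / rho[1])

  set.seed(14)
  z <- rand_cvs(5, 2)
  g <- gaussian_kernel(z, kernel_scale("fixed", epsilon = 0.7))
  rho <- density_estimate(g)
  kap <- anisotropic_kernel(g, rho)
  oracle <- g
  for (k in 1:5) for (l in 1:5) oracle[k, l] <- g[k, l] / sqrt(rho[k] * rho[l])
  expect_lt(max(abs(kap - oracle)), 1e-12)
  expect_error(anisotropic_kernel(g, c(1, 1, 0, 1, 1)),
               class = "spectmap_numerical_error")
})

test_that("transition matrix is the row-normalized anisotropic kernel", {
  a <- 0.4
  m <- transition_matrix(rbind(c(1, a), c(a, 1)))
  expect_equal(m, rbind(c(1, a), c(a, 1)) / (1 + a))

  set.seed(15)
  z <- rand_cvs(5, 2)
  mm <- markov_model(z, kernel_scale("fixed", epsilon = 0.7))
  oracle <- mm$aniso / vapply(1:5, function(k) sum(mm$aniso[k, ]), numeric(1))
  expect_lt(max(abs(mm$transition - oracle)), 1e-12)
  expect_true(all(abs(rowSums(mm$transition) - 1) < 1e-10))
  expect_true(all(mm$transition > 0 & mm$transition < 1))
})

test_that("spectrum: closed form, disconnected limit, non-symmetric oracle", {
  # 2x2 symmetric kernel [[1, a], [a, 1]]: lambda_1 = (1 - a)/(1 + a)
  a <- 1 / 3
  ev <- transition_spectrum(rbind(c(1, a), c(a, 1)))
  expect_equal(as.numeric(ev), c(1, 0.5), tolerance = 1e-12)

  # two tight, well-separated clusters: lambda_1 -> 1, lambda_2 -> 0
  set.seed(16)
  z <- rbind(rand_cvs(15, 2, sd = 1e-3),
             sweep(rand_cvs(15, 2, sd = 1e-3), 2, c(50, 0), "+"))
  m <- markov_model(z, kernel_scale("fixed", epsilon = 1))
  expect_equal(m$eigenvalues[2], 1, tolerance = 1e-5)
  expect_lt(abs(m$eigenvalues[3]), 1e-5)

  # N = 30 random points vs dense non-symmetric eigensolver on M itself
  z <- rand_cvs(30, 2)
  eps <- resolve_epsilon(z)
  m <- markov_model(z)
  expect_lt(max(abs(m$eigenvalues - oracle_spectrum(z, eps))), 1e-8)
})

test_that("spectral gap subtracts neighboring eigenvalues", {
  expect_equal(spectral_gap(c(1, 1, 0, 0), k = 2)$sigma, 1)
  expect_equal(spectral_gap(c(1, 0.9, 0.8), k = 2)$sigma, 0.1)
  expect_error(spectral_gap(c(1, 0.5), k = 2),
               class = "spectmap_parameter_error")

  set.seed(17)
  z <- rbind(rand_cvs(15, 2, sd = 0.1),
             sweep(rand_cvs(15, 2, sd = 0.1), 2, c(8, 0), "+"))
  eps <- resolve_epsilon(z)
  m <- markov_model(z)
  ev_oracle <- oracle_spectrum(z, eps)
  expect_equal(spectral_gap(m$eigenvalues, 2)$sigma,
               ev_oracle[2] - ev_oracle[3], tolerance = 1e-8)
})

test_that("pipeline invariants: stochasticity, real spectrum, lambda0 = 1", {
  set.seed(18)
  for (rep in 1:10) {
    n <- sample(5:60, 1)
    d <- sample(1:3, 1)
    z <- rand_cvs(n, d, sd = runif(1, 0.1, 3))
    m <- markov_model(z)
    expect_lt(max(abs(rowSums(m$transition) - 1)), 1e-10)
    expect_lt(abs(m$eigenvalues[1] - 1), 1e-8)
    expect_true(all(m$eigenvalues <= 1 + 1e-8))
    ev_direct <- eigen(m$transition)$values
    expect_lt(max(abs(Im(ev_direct))), 1e-8)
    expect_lt(max(abs(sort(Re(ev_direct), decreasing = TRUE) -
                        m$eigenvalues)), 1e-8)
  }
})

test_that("isometry invariance: rigid motions of CV space change nothing", {
  set.seed(19)
  z <- rand_cvs(25, 2)
  theta <- 0.7
  rot <- rbind(c(cos(theta), -sin(theta)), c(sin(theta), cos(theta)))
  z2 <- sweep(z %*% rot, 2, c(3, -5), "+")
  m1 <- markov_model(z)
  m2 <- markov_model(z2)
  expect_lt(max(abs(m1$gaussian - m2$gaussian)), 1e-10)
  expect_lt(max(abs(m1$transition - m2$transition)), 1e-10)
  expect_lt(max(abs(m1$eigenvalues - m2$eigenvalues)), 1e-10)
  expect_equal(spectral_gap(m1$eigenvalues, 2)$sigma,
               spectral_gap(m2$eigenvalues, 2)$sigma, tolerance = 1e-10)
})

test_that("permutation equivariance of the kernel pipeline", {
  set.seed(20)
  z <- rand_cvs(20, 2)
  p <- sample(20)
  m1 <- markov_model(z)
  m2 <- markov_model(z[p, ])
  expect_lt(max(abs(m2$transition - m1$transition[p, p])), 1e-10)
  expect_lt(max(abs(m1$eigenvalues - m2$eigenvalues)), 1e-10)
})

test_that("scale coupling: z -> c z with eps -> c^2 eps is exact; the median
           heuristic absorbs uniform rescaling on its own", {
  set.seed(21)
  z <- rand_cvs(15, 2)
  cc <- 2.7
  m1 <- markov_model(z, kernel_scale("fixed", epsilon = 0.9))
  m2 <- markov_model(cc * z, kernel_scale("fixed", epsilon = cc^2 * 0.9))
  expect_lt(max(abs(m1$transition - m2$transition)), 1e-10)
  m3 <- markov_model(z)
  m4 <- markov_model(cc * z)
  expect_lt(max(abs(m3$eigenvalues - m4$eigenvalues)), 1e-10)
})
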