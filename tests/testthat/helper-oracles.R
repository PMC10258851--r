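# Independent oracles used across tests: scalar double loops and quadrature,
# deliberately naive so they share no code with the implementation.

oracle_sq_dists <- function(z) {
  n <- nrow(z)
  d2 <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    d2[i, j] <- sum((z[i, ] - z[j, ])^2)
  d2
}

oracle_gaussian <- function(z, eps) {
  d2 <- oracle_sq_dists(z)
  g <- d2
  for (i in seq_len(nrow(g))) for (j in seq_len(ncol(g)))
    g[i, j] <- exp(-d2[i, j] / eps)
  g
}

oracle_median_sq_dist <- function(z) {
  n <- nrow(z)
  v <- numeric(0)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    v <- c(v, sum((z[i, ] - z[j, ])^2))
  median(v)
}

# Full pipeline to eigenvalues using a *non-symmetric* dense eigensolver on M.
oracle_spectrum <- function(z, eps) {
  g <- oracle_gaussian(z, eps)
  rho <- rowSums(g)
  kap <- g / sqrt(outer(rho, rho))
  m <- kap / rowSums(kap)
  sort(Re(eigen(m)$values), decreasing = TRUE)
}

# 1-D Boltzmann weight of a basin by adaptive quadrature.
oracle_boltzmann_weight_1d <- function(Ufun, beta, lower, upper,
                                       lo = -4, hi = 4) {
  z_basin <- integrate(function(s) exp(-beta * Ufun(s)), lower, upper,
                       rel.tol = 1e-10)$value
  z_all <- integrate(function(s) exp(-beta * Ufun(s)), lo, hi,
                     rel.tol = 1e-10)$value
  z_basin / z_all
}

# 2-D Boltzmann weights over basins assigned by nearest minimum, on a grid.
oracle_boltzmann_weights_2d <- function(Ufun, beta, minima,
                                        xlim = c(-2.5, 2.5),
                                        ylim = c(-2, 3), n = 400L) {
  xs <- seq(xlim[1], xlim[2], length.out = n)
  ys <- seq(ylim[1], ylim[2], length.out = n)
  grid <- expand.grid(x = xs, y = ys)
  w <- exp(-beta * Ufun(as.matrix(grid)))
  d2 <- sapply(seq_len(nrow(minima)), function(i)
    (grid$x - minima[i, 1])^2 + (grid$y - minima[i, 2])^2)
  lab <- max.col(-d2)
  tapply(w, lab, sum) / sum(w)
}

# Batch-means standard error for the mean of an indicator over a correlated
# series (honest about autocorrelation).
batch_se <- function(x, n_blocks = 20L) {
  n <- length(x)
  block <- n %/% n_blocks
  means <- vapply(seq_len(n_blocks), function(b)
    mean(x[((b - 1L) * block + 1L):(b * block)]), numeric(1))
  sd(means) / sqrt(n_blocks)
}

rand_cvs <- function(n, d, sd = 1) matrix(rnorm(n * d, sd = sd), n, d)
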