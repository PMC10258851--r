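# Metastable toy systems: model potentials, an overdamped Langevin sampler
# (Euler-Maruyama) and a linear lift into many noisy features. Together they
# emulate the statistical structure of protein-folding descriptor data --
# rare transitions between long-lived states, observed through n >> d
# correlated features -- with a known slow coordinate and analytic barrier,
# so every downstream module can be validated without external trajectories.

#' Model potentials with analytic gradients
#'
#' Available potentials (energies in kJ/mol, coordinates dimensionless):
#' \describe{
#'   \item{`double_well_1d`}{\eqn{U(s) = B (s^2 - 1)^2 + t s}. Default
#'     barrier `B` is 5 kT at 300 K (12.47 kJ/mol): high enough for clear
#'     metastability, low enough to cross in short runs. `tilt` `t` biases
#'     one well.}
#'   \item{`double_well_2d`}{the 1-D double well in `x` plus a harmonic
#'     transverse mode, \eqn{+ a_y y^2 / 2}.}
#'   \item{`three_well_2d`}{a Gaussian triple well: wells near (-1, 0),
#'     (1, 0) and (0, 1.5) of comparable depth, with quartic confinement.
#'     `scale` multiplies the dimensionless form; the default (1.5 kT at
#'     300 K per unit) makes all three states long-lived (~6 kT deep) with
#'     exchange on accessible time scales.}
#'   \item{`harmonic`}{\eqn{U(z) = a \|z\|^2 / 2} in `d` dimensions.}
#' }
#' Minima are refined numerically at construction, so the stored minimum
#' energies agree with `U` evaluated there to solver precision. For the
#' triple well the barrier between the two deepest wells is found as the
#' minimax ("bottleneck") level on a fine grid; for the double wells it is
#' analytic.
#'
#' @param name one of `"double_well_1d"`, `"double_well_2d"`,
#'   `"three_well_2d"`, `"harmonic"`.
#' @param barrier double-well barrier height B, kJ/mol.
#' @param tilt linear tilt of the 1-D double well, kJ/mol per unit.
#' @param transverse transverse curvature \eqn{a_y} of the 2-D double well.
#' @param scale energy scale of the triple well, kJ/mol per dimensionless
#'   unit.
#' @param curvature harmonic force constant a, kJ/mol per unit^2.
#' @param d dimensionality of the harmonic well.
#' @return List of class `"model_potential"` with `U` (matrix -> vector),
#'   `grad` (vector or matrix in, same shape out), `minima`,
#'   `minima_energy`, `barrier`, `max_curvature`, `domain`, `slow_index`.
#' @examples
#' pot <- model_potential("double_well_1d")
#' pot$U(cbind(c(-1, 0, 1)))     # 0, B, 0
#' @export
model_potential <- function(name = c("double_well_1d", "double_well_2d",
                                     "three_well_2d", "harmonic"),
                            barrier = 5 * KB_KJ_MOL_K * 300, tilt = 0,
                            transverse = 10,
                            scale = 1.5 * KB_KJ_MOL_K * 300,
                            curvature = 100, d = 1L) {
  name <- match.arg(name)
  pot <- switch(name,
    double_well_1d = pot_double_well_1d(barrier, tilt),
    double_well_2d = pot_double_well_2d(barrier, transverse),
    three_well_2d = pot_three_well_2d(scale),
    harmonic = pot_harmonic(curvature, d))
  pot$name <- name
  if (!all(is.finite(pot$minima_energy)))
    stop_numeric("potential minima have non-finite energy")
  class(pot) <- "model_potential"
  pot
}

#' @export
print.model_potential <- function(x, ...) {
  cat(sprintf("model potential '%s' (%d-D), barrier %.3f kJ/mol, %d minima\n",
              x$name, x$d, x$barrier, nrow(x$minima)))
  invisible(x)
}

as_points <- function(z, d) {
  if (is.matrix(z)) z else matrix(z, ncol = d)
}

pot_double_well_1d <- function(barrier, tilt) {
  b <- barrier
  U <- function(z) { s <- as_points(z, 1L)[, 1L]; b * (s^2 - 1)^2 + tilt * s }
  grad <- function(z) {
    vec <- !is.matrix(z)
    s <- as_points(z, 1L)[, 1L]
    g <- cbind(4 * b * s * (s^2 - 1) + tilt)
    if (vec) as.numeric(g) else g
  }
  minima <- rbind(refine_minimum(U, grad, -1), refine_minimum(U, grad, 1))
  me <- U(minima)
  saddle <- if (tilt == 0) 0 else
    stats::optimize(function(s) -U(cbind(s)), c(-0.9, 0.9))$minimum
  list(U = U, grad = grad, d = 1L, params = list(barrier = b, tilt = tilt),
       minima = minima, minima_energy = me,
       barrier = as.numeric(U(cbind(saddle))) - max(me), saddle = saddle,
       max_curvature = 8 * b, domain = cbind(-3, 3), slow_index = 1L)
}

pot_double_well_2d <- function(barrier, transverse) {
  b <- barrier; ay <- transverse
  U <- function(z) {
    z <- as_points(z, 2L)
    b * (z[, 1L]^2 - 1)^2 + ay / 2 * z[, 2L]^2
  }
  grad <- function(z) {
    vec <- !is.matrix(z)
    z <- as_points(z, 2L)
    g <- cbind(4 * b * z[, 1L] * (z[, 1L]^2 - 1), ay * z[, 2L])
    if (vec) as.numeric(g) else g
  }
  minima <- rbind(c(-1, 0), c(1, 0))
  list(U = U, grad = grad, d = 2L,
       params = list(barrier = b, transverse = ay),
       minima = minima, minima_energy = U(minima), barrier = b,
       saddle = c(0, 0), max_curvature = max(8 * b, ay),
       domain = rbind(c(-3, 3), c(-3, 3)), slow_index = 1L)
}

pot_three_well_2d <- function(scale) {
  # Upper-well amplitude 5 (not the textbook 3): calibrated so all three
  # wells are comparably deep and the latent-space Markov spectrum shows
  # lambda_1 ~ lambda_2 >> lambda_3, i.e. three genuinely metastable states.
  U0 <- function(x, y) {
    3 * exp(-x^2 - (y - 1/3)^2) - 5 * exp(-x^2 - (y - 5/3)^2) -
      5 * exp(-(x - 1)^2 - y^2) - 5 * exp(-(x + 1)^2 - y^2) +
      0.2 * x^4 + 0.2 * (y - 1/3)^4
  }
  U <- function(z) { z <- as_points(z, 2L); scale * U0(z[, 1L], z[, 2L]) }
  grad <- function(z) {
    vec <- !is.matrix(z)
    z <- as_points(z, 2L)
    x <- z[, 1L]; y <- z[, 2L]
    e1 <- 3 * exp(-x^2 - (y - 1/3)^2)
    e2 <- -5 * exp(-x^2 - (y - 5/3)^2)
    e3 <- -5 * exp(-(x - 1)^2 - y^2)
    e4 <- -5 * exp(-(x + 1)^2 - y^2)
    gx <- -2 * x * (e1 + e2) - 2 * (x - 1) * e3 - 2 * (x + 1) * e4 +
      0.8 * x^3
    gy <- -2 * (y - 1/3) * e1 - 2 * (y - 5/3) * e2 - 2 * y * (e3 + e4) +
      0.8 * (y - 1/3)^3
    g <- scale * cbind(gx, gy)
    if (vec) as.numeric(g) else g
  }
  minima <- rbind(refine_minimum(U, grad, c(-1, 0)),
                  refine_minimum(U, grad, c(1, 0)),
                  refine_minimum(U, grad, c(0, 1.5)))
  me <- U(minima)
  level0 <- three_well_bottleneck_level()   # unit-scale minimax level
  deepest <- order(me)[1:2]
  list(U = U, grad = grad, d = 2L, params = list(scale = scale),
       minima = minima, minima_energy = me,
       barrier = scale * level0 - max(me[deepest]),
       max_curvature = 22 * scale,
       domain = rbind(c(-2.5, 2.5), c(-2, 3)), slow_index = 1L)
}

pot_harmonic <- function(curvature, d) {
  a <- curvature; d <- as.integer(d)
  U <- function(z) { z <- as_points(z, d); a / 2 * rowSums(z^2) }
  grad <- function(z) {
    vec <- !is.matrix(z)
    g <- a * as_points(z, d)
    if (vec) as.numeric(g) else g
  }
  minima <- matrix(0, 1L, d)
  list(U = U, grad = grad, d = d, params = list(curvature = a),
       minima = minima, minima_energy = U(minima), barrier = NA_real_,
       max_curvature = a,
       domain = matrix(rep(c(-5, 5), each = d), d, 2L), slow_index = 1L)
}

refine_minimum <- function(U, grad, start) {
  fit <- stats::optim(start, function(p) U(rbind(p)),
                      function(p) as.numeric(grad(rbind(p))),
                      method = "BFGS",
                      control = list(reltol = 1e-14, maxit = 500))
  matrix(fit$par, 1L)
}

# Minimax ("bottleneck") level between the two deep wells of the unit-scale
# triple well, via union-find percolation on a fine grid: the lowest energy
# level at which the two basins become connected. Cached per session.
.spectmap_cache <- new.env(parent = emptyenv())

three_well_bottleneck_level <- function(nx = 161L, ny = 161L) {
  key <- paste0("tw_", nx, "_", ny)
  if (!is.null(.spectmap_cache[[key]])) return(.spectmap_cache[[key]])
  xs <- seq(-2, 2, length.out = nx)
  ys <- seq(-1.5, 2.5, length.out = ny)
  u <- outer(xs, ys, function(x, y)
    3 * exp(-x^2 - (y - 1/3)^2) - 5 * exp(-x^2 - (y - 5/3)^2) -
      5 * exp(-(x - 1)^2 - y^2) - 5 * exp(-(x + 1)^2 - y^2) +
      0.2 * x^4 + 0.2 * (y - 1/3)^4)
  cell <- function(x, y)
    (which.min(abs(ys - y)) - 1L) * nx + which.min(abs(xs - x))
  a <- cell(-1, 0); b <- cell(1, 0)
  n <- nx * ny
  parent <- seq_len(n)
  added <- logical(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  ord <- order(as.vector(u))
  level <- NA_real_
  for (c0 in ord) {
    added[c0] <- TRUE
    i <- (c0 - 1L) %% nx + 1L
    j <- (c0 - 1L) %/% nx + 1L
    for (nb in c(if (i > 1L) c0 - 1L, if (i < nx) c0 + 1L,
                 if (j > 1L) c0 - nx, if (j < ny) c0 + nx)) {
      if (added[nb]) {
        ra <- find(c0); rb <- find(nb)
        if (ra != rb) parent[ra] <- rb
      }
    }
    if (added[a] && added[b] && find(a) == find(b)) {
      level <- u[c0]
      break
    }
  }
  .spectmap_cache[[key]] <- level
  level
}

#' Overdamped Langevin configuration
#'
#' @param n_steps number of integration steps.
#' @param thermo a [thermo()] state.
#' @param friction friction coefficient gamma, 1/ps.
#' @param timestep integration time step, ps.
#' @param stride keep every `stride`-th step (the initial point is always
#'   kept, so `n_steps = 0` yields just the initial point).
#' @param seed RNG seed for the thermal noise.
#' @param initial starting coordinates; defaults to the potential's first
#'   minimum.
#' @return List of class `"langevin_config"`.
#' @export
langevin_config <- function(n_steps, thermo = spectmap::thermo(300),
                            friction = 1, timestep = 0.002, stride = 100L,
                            seed = 1L, initial = NULL) {
  if (timestep <= 0) stop_param("'timestep' must be positive")
  if (friction <= 0) stop_param("'friction' must be positive")
  stride <- as.integer(stride)
  if (stride < 1L) stop_param("'stride' must be >= 1")
  n_steps <- as.integer(n_steps)
  if (n_steps < 0L) stop_param("'n_steps' must be >= 0")
  if (n_steps > 0L && n_steps < stride)
    stop_param("'n_steps' must be at least 'stride'")
  structure(list(n_steps = n_steps, thermo = thermo, friction = friction,
                 timestep = timestep, stride = stride,
                 seed = as.integer(seed), initial = initial),
            class = "langevin_config")
}

#' Simulate overdamped Langevin dynamics on a model potential
#'
#' Euler-Maruyama discretization of
#' \deqn{z_{t+1} = z_t - (\Delta t/\gamma)\,\nabla U(z_t) +
#'   \sqrt{2\Delta t/(\beta\gamma)}\,\eta_t,}
#' with standard-normal noise. This is the effective dynamics assumed for
#' motion along slow CVs: diffusion on a landscape, no inertia. A stability
#' warning is raised when `timestep * max_curvature / friction >= 0.5`.
#'
#' @param potential a [model_potential()].
#' @param config a [langevin_config()].
#' @return List of class `"langevin_trajectory"`: `latent` (strided samples
#'   including the initial point), `slow` (the true slow coordinate of each
#'   sample), `potential_name`, `config`.
#' @examples
#' pot <- model_potential("double_well_1d")
#' trj <- simulate_langevin(pot, langevin_config(n_steps = 5000, seed = 1))
#' @export
simulate_langevin <- function(potential, config) {
  if (!inherits(potential, "model_potential"))
    stop_param("'potential' must be a model_potential")
  if (!inherits(config, "langevin_config"))
    stop_param("'config' must be a langevin_config")
  dt <- config$timestep; gam <- config$friction
  if (dt * potential$max_curvature / gam >= 0.5)
    warning("timestep ", dt, " may be unstable for this potential ",
            "(dt * max_curvature / friction >= 0.5)", call. = FALSE)
  d <- potential$d
  z <- as.numeric(config$initial %||% potential$minima[1L, ])
  if (length(z) != d) stop_input("initial point has wrong dimension")
  n_steps <- config$n_steps
  n_out <- n_steps %/% config$stride + 1L
  out <- matrix(NA_real_, n_out, d)
  out[1L, ] <- z
  guard <- 10 * max(abs(potential$domain))
  if (n_steps > 0L) {
    noise <- withr::with_seed(config$seed,
                              matrix(stats::rnorm(n_steps * d), n_steps, d))
    amp <- sqrt(2 * dt / (config$thermo$beta * gam))
    drift <- dt / gam
    grad <- potential$grad
    row <- 1L
    for (t in seq_len(n_steps)) {
      z <- z - drift * grad(z) + amp * noise[t, ]
      if (any(abs(z) > guard))
        stop_numeric("simulation blow-up at step ", t,
                     " (|z| exceeded the domain guard)")
      if (t %% config$stride == 0L) {
        row <- row + 1L
        out[row, ] <- z
      }
    }
  }
  structure(list(latent = out, slow = out[, potential$slow_index],
                 potential_name = potential$name, config = config),
            class = "langevin_trajectory")
}

#' Linear lift of a latent trajectory into many noisy features
#'
#' @param n_out number of output features n.
#' @param d_latent latent dimensionality (must not exceed `n_out`).
#' @param noise_sigma standard deviation of the isotropic Gaussian noise
#'   added to every feature dimension.
#' @param seed seed for the (orthonormal) mixing matrix and the noise.
#' @return List of class `"lift_config"` with the seeded `mixing` matrix
#'   (`n_out` x `d_latent`, orthonormal columns).
#' @export
lift_config <- function(n_out, d_latent, noise_sigma = 0.1, seed = 1L) {
  n_out <- as.integer(n_out); d_latent <- as.integer(d_latent)
  if (d_latent > n_out)
    stop_param("'d_latent' cannot exceed 'n_out'")
  if (noise_sigma < 0) stop_param("'noise_sigma' must be >= 0")
  mixing <- withr::with_seed(derive_seed(seed, 11L),
    qr.Q(qr(matrix(stats::rnorm(n_out * d_latent), n_out, d_latent))))
  structure(list(n_out = n_out, d_latent = d_latent,
                 noise_sigma = noise_sigma, seed = as.integer(seed),
                 mixing = mixing),
            class = "lift_config")
}

#' Lift latent samples into feature space
#'
#' Computes `features = latent %*% t(mixing) + noise`. Because the mixing
#' columns are orthonormal, pairwise distances are preserved exactly at zero
#' noise, and the slow coordinate stays linearly decodable (projection onto
#' the mixing columns recovers it up to the noise floor).
#'
#' @param latent numeric matrix of latent samples (or a
#'   `"langevin_trajectory"`).
#' @param lift a [lift_config()].
#' @return Numeric feature matrix with columns `f1, f2, ...`.
#' @export
lift_to_features <- function(latent, lift) {
  if (inherits(latent, "langevin_trajectory")) latent <- latent$latent
  latent <- as_num_matrix(latent, "latent trajectory")
  if (!inherits(lift, "lift_config"))
    stop_param("'lift' must be a lift_config")
  if (ncol(latent) != lift$d_latent)
    stop_input("latent trajectory has ", ncol(latent),
               " columns; lift expects ", lift$d_latent)
  x <- latent %*% t(lift$mixing)
  if (lift$noise_sigma > 0) {
    noise <- withr::with_seed(derive_seed(lift$seed, 12L),
      matrix(stats::rnorm(length(x), sd = lift$noise_sigma),
             nrow(x), ncol(x)))
    x <- x + noise
  }
  colnames(x) <- paste0("f", seq_len(ncol(x)))
  x
}

#' Packaged metastable benchmarks
#'
#' Deterministic end-to-end fixtures: a Langevin trajectory on a reference
#' potential, lifted into `n_features` noisy features. The true slow
#' coordinate, analytic basin labels and the analytic barrier of the
#' generator ride along as ground truth.
#'
#' \describe{
#'   \item{`"two_state"`}{1-D double well, barrier 5 kT at 300 K, 2 states.}
#'   \item{`"three_state"`}{2-D triple well, 3 states (labels by nearest
#'     minimum).}
#' }
#'
#' @param name `"two_state"` or `"three_state"`.
#' @param n_samples number of strided samples to return (after a discarded
#'   burn-in of 50 strided blocks).
#' @param seed master seed (trajectory and lift are derived from it).
#' @param n_features number of lifted features (default 40).
#' @param noise_sigma feature noise level (default 0.1).
#' @param stride integration steps between kept samples (default 100); use
#'   a smaller stride to emulate a densely sampled evaluation trajectory of
#'   the same physical length.
#' @return List of class `"cv_benchmark"`: `features`, `slow`, `labels`,
#'   `latent`, `potential`, `barrier` (kJ/mol), `thermo`, `lift`, `name`,
#'   `seed`.
#' @examples
#' bench <- make_benchmark("two_state", n_samples = 500, seed = 1)
#' table(bench$labels)
#' @export
make_benchmark <- function(name = c("two_state", "three_state"), n_samples,
                           seed, n_features = 40L, noise_sigma = 0.1,
                           stride = 100L) {
  name <- match.arg(name)
  n_samples <- as.integer(n_samples)
  if (n_samples < 2L) stop_param("'n_samples' must be >= 2")
  th <- thermo(300)
  if (name == "two_state") {
    pot <- model_potential("double_well_1d")
    dt <- 0.002
  } else {
    pot <- model_potential("three_well_2d")
    dt <- 0.004
  }
  burn <- 50L
  cfg <- langevin_config(n_steps = (n_samples + burn) * stride, thermo = th,
                         friction = 1, timestep = dt, stride = stride,
                         seed = derive_seed(seed, 21L))
  trj <- simulate_langevin(pot, cfg)
  latent <- trj$latent[-seq_len(burn + 1L), , drop = FALSE]
  lift <- lift_config(n_features, pot$d, noise_sigma = noise_sigma,
                      seed = derive_seed(seed, 22L))
  features <- lift_to_features(latent, lift)
  labels <- basin_labels(pot, latent)
  structure(list(name = name, features = features,
                 slow = latent[, pot$slow_index], labels = labels,
                 latent = latent, potential = pot, barrier = pot$barrier,
                 thermo = th, lift = lift, seed = as.integer(seed),
                 n_samples = n_samples),
            class = "cv_benchmark")
}

# Basin membership: split at the saddle for the 1-D double well, nearest
# minimum otherwise.
basin_labels <- function(potential, latent) {
  if (potential$name == "double_well_1d") {
    return(ifelse(latent[, 1L] < potential$saddle, 1L, 2L))
  }
  mins <- potential$minima
  d2 <- vapply(seq_len(nrow(mins)), function(i)
    rowSums(sweep(latent, 2L, mins[i, ], "-")^2), numeric(nrow(latent)))
  max.col(-d2)
}

#' @export
print.cv_benchmark <- function(x, ...) {
  cat(sprintf("benchmark '%s': %d samples, %d features, barrier %.2f kJ/mol\n",
              x$name, nrow(x$features), ncol(x$features), x$barrier))
  cat("state occupancies:",
      paste(sprintf("%.3f", tabulate(x$labels) / length(x$labels)),
            collapse = " "), "\n")
  invisible(x)
}

#' Write a benchmark to delimited text files
#'
#' Writes `<prefix>_features.tsv` (the feature matrix) and
#' `<prefix>_truth.tsv` (slow coordinate, labels and, for 2-D latents, the
#' remaining latent coordinates) plus `<prefix>_meta.yaml` with the
#' generator constants (analytic barrier, temperature, seed).
#'
#' @param bench a `"cv_benchmark"`.
#' @param prefix output path prefix.
#' @return Invisibly, the paths written.
#' @export
write_benchmark <- function(bench, prefix) {
  if (!inherits(bench, "cv_benchmark"))
    stop_param("'bench' must be a cv_benchmark")
  fpath <- paste0(prefix, "_features.tsv")
  tpath <- paste0(prefix, "_truth.tsv")
  mpath <- paste0(prefix, "_meta.yaml")
  write_feature_matrix(bench$features, fpath)
  truth <- data.frame(slow = bench$slow, label = bench$labels)
  if (ncol(bench$latent) > 1L)
    truth <- cbind(truth, latent2 = bench$latent[, 2L])
  utils::write.table(format(truth, digits = 17, trim = TRUE), tpath,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  yaml::write_yaml(list(package = "spectmap",
                        version = as.character(utils::packageVersion("spectmap")),
                        name = bench$name, seed = bench$seed,
                        n_samples = bench$n_samples,
                        barrier_kJ_mol = bench$barrier,
                        temperature_K = bench$thermo$temperature), mpath)
  invisible(c(fpath, tpath, mpath))
}
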