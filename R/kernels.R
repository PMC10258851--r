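# Anisotropic diffusion kernel, Markov transition matrix and its spectrum.
#
# Pipeline on N CV samples z_1..z_N in R^d:
#   g_kl   = exp(-||z_k - z_l||^2 / eps)          (Gaussian kernel)
#   rho_k  = sum_l g_kl                           (kernel density estimate)
#   kap_kl = g_kl / sqrt(rho_k rho_l)             (anisotropic kernel)
#   m_kl   = kap_kl / sum_j kap_kj                (row-stochastic Markov matrix)
# The spectrum of M is computed through the symmetric conjugate
# S = D^(-1/2) kap D^(-1/2) with D = diag(rowSums(kap)), which shares the
# eigenvalues of M and guarantees they are real.

#' Kernel scale specification
#'
#' Describes how the Gaussian-kernel scale constant \eqn{\varepsilon} is
#' resolved for a set of CV samples. In `"median_heuristic"` mode (the
#' default) \eqn{\varepsilon} is the median of all off-diagonal squared
#' pairwise distances times `multiplier`, recomputed for every sample set it
#' is applied to; this keeps the kernel -- and hence the spectral-gap loss --
#' invariant to a uniform rescaling of the CVs. In `"fixed"` mode the given
#' `epsilon` is used as is.
#'
#' @param mode `"median_heuristic"` or `"fixed"`.
#' @param epsilon positive scale constant, required for `"fixed"` mode.
#' @param multiplier positive factor applied to the median heuristic.
#' @return An object of class `"kernel_scale"`.
#' @examples
#' kernel_scale()                      # self-tuning median heuristic
#' kernel_scale("fixed", epsilon = 0.5)
#' @export
kernel_scale <- function(mode = c("median_heuristic", "fixed"),
                         epsilon = NULL, multiplier = 1) {
  mode <- match.arg(mode)
  if (mode == "fixed") {
    if (is.null(epsilon) || !is.numeric(epsilon) || length(epsilon) != 1L ||
        !is.finite(epsilon) || epsilon <= 0)
      stop_param("fixed kernel scale requires a single positive 'epsilon'")
  }
  if (!is.numeric(multiplier) || length(multiplier) != 1L ||
      !is.finite(multiplier) || multiplier <= 0)
    stop_param("'multiplier' must be a single positive number")
  structure(list(mode = mode, epsilon = epsilon, multiplier = multiplier),
            class = "kernel_scale")
}

as_kernel_scale <- function(scale) {
  if (inherits(scale, "kernel_scale")) return(scale)
  if (is.numeric(scale) && length(scale) == 1L)
    return(kernel_scale("fixed", epsilon = scale))
  stop_param("'scale' must be a kernel_scale object or a single number")
}

sq_dist_matrix <- function(z) {
  d2 <- as.matrix(stats::dist(z))^2
  dimnames(d2) <- NULL
  d2
}

#' Resolve the Gaussian kernel scale for a sample set
#'
#' @param z numeric matrix of CV samples (N x d), N >= 2.
#' @param scale a [kernel_scale()] object (or a single number, taken as a
#'   fixed epsilon).
#' @return A single positive number, \eqn{\varepsilon}.
#' @details Under the median heuristic the result is
#'   `multiplier * median` of the N(N-1)/2 off-diagonal squared pairwise
#'   distances, floored at machine epsilon so that coincident point sets do
#'   not produce a zero scale.
#' @export
resolve_epsilon <- function(z, scale = kernel_scale()) {
  scale <- as_kernel_scale(scale)
  if (scale$mode == "fixed") return(scale$epsilon)
  z <- check_cv_samples(z)
  d2 <- sq_dist_matrix(z)
  eps <- scale$multiplier * stats::median(d2[upper.tri(d2)])
  max(eps, .Machine$double.eps)
}

#' Gaussian kernel matrix of CV samples
#'
#' Computes \eqn{g_{kl} = \exp(-\|z_k - z_l\|^2 / \varepsilon)} for all
#' sample pairs. The diagonal is exactly 1 and all entries lie in (0, 1].
#'
#' @inheritParams resolve_epsilon
#' @return Symmetric N x N matrix.
#' @export
gaussian_kernel <- function(z, scale = kernel_scale()) {
  z <- check_cv_samples(z)
  eps <- resolve_epsilon(z, scale)
  if (!is.finite(eps) || eps <= 0) stop_param("resolved epsilon must be > 0")
  exp(-sq_dist_matrix(z) / eps)
}

#' Kernel density estimate from a Gaussian kernel matrix
#'
#' The (unnormalized) density at sample k is the k-th row sum of the Gaussian
#' kernel, \eqn{\varrho_k = \sum_l g_{kl}}; every entry is at least 1 because
#' the diagonal contributes 1.
#'
#' @param gaussian symmetric Gaussian kernel matrix.
#' @return Numeric vector of N positive densities.
#' @export
density_estimate <- function(gaussian) {
  gaussian <- as_num_matrix(gaussian, "gaussian kernel")
  if (!all(is.finite(gaussian))) stop_input("kernel contains non-finite values")
  rowSums(gaussian)
}

#' Anisotropic diffusion kernel
#'
#' Divides the Gaussian kernel by the geometric mean of the density estimates
#' at its two endpoints, \eqn{\kappa_{kl} = g_{kl} / \sqrt{\varrho_k
#' \varrho_l}}. This removes the sampling-density bias so the inferred
#' dynamics reflect the landscape rather than how densely it was sampled.
#'
#' @param gaussian symmetric Gaussian kernel matrix.
#' @param density vector of strictly positive densities (row sums of
#'   `gaussian`).
#' @return Symmetric N x N matrix with strictly positive entries.
#' @export
anisotropic_kernel <- function(gaussian, density) {
  gaussian <- as_num_matrix(gaussian, "gaussian kernel")
  if (any(!is.finite(density)) || any(density <= 0))
    stop_numeric("density estimates must be strictly positive and finite")
  inv <- 1 / sqrt(density)
  gaussian * tcrossprod(inv, inv)
}

#' Markov transition matrix from the anisotropic kernel
#'
#' Row-normalizes the anisotropic kernel: \eqn{m_{kl} = \kappa_{kl} / \sum_j
#' \kappa_{kj}}. Entry (k, l) is the probability of moving from sample k to
#' sample l in one auxiliary step of the kernel-defined Markov chain.
#'
#' @param aniso symmetric, strictly positive anisotropic kernel matrix.
#' @return Row-stochastic N x N matrix.
#' @export
transition_matrix <- function(aniso) {
  aniso <- as_num_matrix(aniso, "anisotropic kernel")
  d <- rowSums(aniso)
  if (any(!is.finite(d)) || any(d <= 0))
    stop_numeric("anisotropic kernel has a non-positive row sum")
  aniso / d
}

#' Eigenvalues of the transition matrix via its symmetric conjugate
#'
#' The transition matrix M = D^-1 kappa (D = diag of row sums of kappa) is
#' similar to the symmetric matrix S = D^-1/2 kappa D^-1/2, so its spectrum is
#' provably real. Eigenvalues are returned sorted in decreasing order with
#' \eqn{\lambda_0 = 1} leading.
#'
#' @param aniso symmetric, strictly positive anisotropic kernel matrix (the
#'   un-normalized precursor of M, which carries the row scaling needed for
#'   the symmetric conjugate).
#' @param vectors if `TRUE`, attach the eigenvectors of the symmetric
#'   conjugate and the row sums as attributes `"vectors"` and `"row_sums"`
#'   (needed to reconstruct eigenvectors of M as \eqn{\psi = D^{-1/2} v}).
#' @return Numeric vector of N real eigenvalues, sorted descending.
#' @export
transition_spectrum <- function(aniso, vectors = FALSE) {
  aniso <- as_num_matrix(aniso, "anisotropic kernel")
  d <- rowSums(aniso)
  if (any(!is.finite(d)) || any(d <= 0))
    stop_numeric("anisotropic kernel has a non-positive row sum")
  inv <- 1 / sqrt(d)
  s <- aniso * tcrossprod(inv, inv)
  eig <- tryCatch(
    eigen(s, symmetric = TRUE, only.values = !vectors),
    error = function(e) stop_numeric("eigendecomposition failed: ",
                                     conditionMessage(e)))
  values <- eig$values  # LAPACK returns them sorted decreasing
  if (vectors) {
    attr(values, "vectors") <- eig$vectors
    attr(values, "row_sums") <- d
  }
  values
}

#' Spectral gap of a sorted eigenvalue sequence
#'
#' For k assumed metastable states the spectral gap is
#' \eqn{\sigma_k = \lambda_{k-1} - \lambda_k} (0-based eigenvalue indexing
#' with \eqn{\lambda_0 = 1}), i.e. `k = 2` gives \eqn{\lambda_1 - \lambda_2}.
#' A gap close to 1 after the k-th eigenvalue signals k long-lived states
#' with fast intra-state relaxation.
#'
#' @param eigenvalues numeric vector sorted in decreasing order.
#' @param k number of metastable states, `1 <= k <= length(eigenvalues) - 1`.
#' @return A list of class `"spectral_gap"` with elements `k` and `sigma`.
#' @export
spectral_gap <- function(eigenvalues, k) {
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k != round(k))
    stop_param("'k' must be a single integer >= 1")
  ev <- as.numeric(eigenvalues)
  if (k > length(ev) - 1L)
    stop_param("'k' = ", k, " out of range for ", length(ev), " eigenvalues")
  structure(list(k = as.integer(k), sigma = ev[k] - ev[k + 1L]),
            class = "spectral_gap")
}

#' @export
print.spectral_gap <- function(x, ...) {
  cat(sprintf("spectral gap: sigma = %.6f at k = %d\n", x$sigma, x$k))
  invisible(x)
}

#' Full Markov model of a CV sample set
#'
#' Convenience wrapper chaining [gaussian_kernel()], [density_estimate()],
#' [anisotropic_kernel()], [transition_matrix()] and [transition_spectrum()].
#'
#' @inheritParams resolve_epsilon
#' @return A list of class `"markov_model"` with elements `gaussian`,
#'   `density`, `aniso`, `transition`, `eigenvalues`, `epsilon`, `n`, `d`.
#' @examples
#' z <- matrix(rnorm(60), ncol = 2)
#' m <- markov_model(z)
#' spectral_gap(m$eigenvalues, k = 2)
#' @export
markov_model <- function(z, scale = kernel_scale()) {
  z <- check_cv_samples(z)
  eps <- resolve_epsilon(z, scale)
  g <- gaussian_kernel(z, kernel_scale("fixed", epsilon = eps))
  rho <- density_estimate(g)
  kap <- anisotropic_kernel(g, rho)
  m <- transition_matrix(kap)
  ev <- transition_spectrum(kap)
  structure(list(gaussian = g, density = rho, aniso = kap, transition = m,
                 eigenvalues = as.numeric(ev), epsilon = eps,
                 n = nrow(z), d = ncol(z)),
            class = "markov_model")
}

#' @export
print.markov_model <- function(x, ...) {
  cat(sprintf("Markov model: %d samples, %d CV(s), epsilon = %.4g\n",
              x$n, x$d, x$epsilon))
  nshow <- min(6L, length(x$eigenvalues))
  cat("leading eigenvalues:",
      paste(sprintf("%.4f", x$eigenvalues[seq_len(nshow)]), collapse = " "),
      "\n")
  invisible(x)
}
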