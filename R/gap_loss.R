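# Spectral-gap loss and its analytic gradient with respect to CV coordinates.
#
# The loss is L = -sigma_k = -(lambda_{k-1} - lambda_k) of the Markov
# transition matrix built from the batch. Gradients are propagated through
# the whole kernel pipeline by hand:
#
#   * eigenvalue of the symmetric conjugate S with unit eigenvector v:
#       d lambda = v' dS v
#   * S = kap / sqrt(d_i d_j), d = rowSums(kap):
#       dL/d kap_ij = Gs_ij / sqrt(d_i d_j) - t_i / d_i,
#       t_i = sum_j (Gs_ij + Gs_ji) S_ij / 2
#   * kap = g / sqrt(rho_i rho_j), rho = rowSums(g): same structure
#   * g_ij = exp(-D2_ij / eps):
#       dL/dD2_ij = -Gg_ij g_ij / eps,  dL/deps = sum Gg g D2 / eps^2
#   * D2_ij = ||z_i - z_j||^2:
#       dL/dz_i = sum_j (A_ij) 2 (z_i - z_j),  A = GD2 + GD2'
#   * median-heuristic eps = mult * median(D2 off-diagonal): the gradient
#     flows through the order statistic(s) attaining the median (exact almost
#     everywhere; at ties a subgradient is used).
#
# Eigenvalue gradients are well-defined wherever the eigenvalue is simple; a
# near-degeneracy |lambda_{k-1} - lambda_k| < 1e-9 is flagged via the
# "degenerate" attribute rather than perturbed, because the gap's own
# gradient stays finite when only the two gap-defining eigenvalues approach
# one another.

#' Negative spectral gap of a CV batch, with analytic gradient
#'
#' Chains the kernel pipeline ([gaussian_kernel()] through
#' [transition_spectrum()]) on a batch of CV samples and returns
#' \eqn{-\sigma_k}; this is the quantity minimized when training a mapping.
#'
#' @param z numeric matrix of CV samples (batch), at least `k + 1` rows.
#' @param k number of assumed metastable states.
#' @param scale a [kernel_scale()] object; under the median heuristic the
#'   scale is resolved on this batch and differentiated through.
#' @param gradient if `TRUE`, attach the N x d gradient of the loss with
#'   respect to `z` as attribute `"gradient"`.
#' @return Scalar loss with attributes `"sigma"`, `"eigenvalues"`,
#'   `"degenerate"` and optionally `"gradient"`.
#' @examples
#' z <- rbind(matrix(rnorm(20, -3, .2), ncol = 2),
#'            matrix(rnorm(20,  3, .2), ncol = 2))
#' gap_loss(z, k = 2)   # close to -1: two well-separated clusters
#' @export
gap_loss <- function(z, k = 2, scale = kernel_scale(), gradient = FALSE) {
  z <- check_cv_samples(z)
  scale <- as_kernel_scale(scale)
  n <- nrow(z)
  if (n < k + 1L)
    stop_param("batch of ", n, " samples is too small for k = ", k,
               " (need at least k + 1)")

  d2 <- sq_dist_matrix(z)

  # resolve epsilon, remembering which pair(s) set the median
  med_pairs <- NULL
  med_w <- NULL
  if (scale$mode == "fixed") {
    eps <- scale$epsilon
  } else {
    ut <- which(upper.tri(d2))
    v <- d2[ut]
    p <- length(v)
    ord <- order(v)
    if (p %% 2L == 1L) {
      sel <- ord[(p + 1L) %/% 2L]
      med <- v[sel]
      med_w <- 1
    } else {
      sel <- ord[c(p %/% 2L, p %/% 2L + 1L)]
      med <- mean(v[sel])
      med_w <- c(0.5, 0.5)
    }
    eps <- scale$multiplier * med
    if (eps < .Machine$double.eps) {
      eps <- .Machine$double.eps
      med_pairs <- NULL          # floored: no gradient through the median
    } else {
      idx <- ut[sel]
      med_pairs <- cbind(row = (idx - 1L) %% n + 1L,
                         col = (idx - 1L) %/% n + 1L)
    }
  }

  g <- exp(-d2 / eps)
  rho <- rowSums(g)
  inv_rho <- 1 / sqrt(rho)
  kap <- g * tcrossprod(inv_rho, inv_rho)
  dd <- rowSums(kap)
  inv_dd <- 1 / sqrt(dd)
  s <- kap * tcrossprod(inv_dd, inv_dd)

  eig <- eigen(s, symmetric = TRUE, only.values = !gradient)
  ev <- eig$values
  sigma <- ev[k] - ev[k + 1L]
  loss <- -sigma
  if (!is.finite(loss)) stop_numeric("spectral-gap loss is non-finite")

  out <- loss
  attr(out, "sigma") <- sigma
  attr(out, "eigenvalues") <- ev
  attr(out, "degenerate") <- abs(sigma) < 1e-9

  if (gradient) {
    va <- eig$vectors[, k]
    vb <- eig$vectors[, k + 1L]
    # dL/dS = -(va va' - vb vb')
    gs <- -(tcrossprod(va) - tcrossprod(vb))

    # S <- kap (row sums dd)
    t_i <- rowSums(gs * s)           # gs, s symmetric
    gkap <- gs * tcrossprod(inv_dd, inv_dd) - t_i / dd

    # kap <- g (row sums rho)
    u_i <- rowSums((gkap + t(gkap)) * kap) / 2
    gg <- gkap * tcrossprod(inv_rho, inv_rho) - u_i / rho

    # g <- d2, eps
    gd2 <- -gg * g / eps
    if (!is.null(med_pairs)) {
      geps <- sum(gg * g * d2) / eps^2
      gmed <- geps * scale$multiplier * med_w
      for (i in seq_len(nrow(med_pairs)))
        gd2[med_pairs[i, 1L], med_pairs[i, 2L]] <-
          gd2[med_pairs[i, 1L], med_pairs[i, 2L]] + gmed[i]
    }

    # d2 <- z
    a <- gd2 + t(gd2)
    gz <- 2 * (z * rowSums(a) - a %*% z)
    attr(out, "gradient") <- gz
  }
  out
}
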