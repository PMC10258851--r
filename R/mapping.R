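# Parametric target mapping z = xi_theta(x): a small feed-forward network
# trained by minibatch gradient descent on the negative spectral gap.

#' Configuration of the target mapping and its training protocol
#'
#' @param n_in number of input configuration descriptors (features).
#' @param n_out number of collective variables d (default 2, matching the
#'   two-dimensional landscapes typically inspected).
#' @param hidden integer vector of hidden layer widths; default `c(8, 8)`.
#'   A narrow bottleneck deliberately limits how sharply the network can
#'   fold and collapse metastable basins: wider nets reach the same
#'   spectral gap but scramble the within-basin ordering of samples, which
#'   degrades the learned CV as a reaction coordinate. `integer(0)` gives a
#'   purely linear mapping.
#' @param activation hidden-layer nonlinearity, `"tanh"` (smooth, bounded
#'   curvature -- keeps the kernel well-conditioned) or `"linear"`.
#' @param seed master seed; initialization, minibatch shuffling and the
#'   monitor subset are all derived deterministically from it.
#' @param optimizer only `"adam"` is provided.
#' @param learning_rate Adam step size (default 1e-3).
#' @param epochs number of passes over the data (default 100).
#' @param batch_size samples per minibatch (default 100); the transition
#'   matrix, and hence the loss, is batch-local.
#' @param k assumed number of metastable states entering the gap (default 2).
#' @param scale [kernel_scale()] used for every batch kernel.
#' @param standardize_input if `TRUE` (default), per-feature standardization
#'   to zero mean / unit variance is computed on the training set and frozen
#'   into the mapping.
#' @param monitor_size cap on the fixed evaluation subset used to record a
#'   monitoring spectral gap once per epoch (default 1000).
#' @return An object of class `"mapping_config"`.
#' @export
mapping_config <- function(n_in, n_out = 2L, hidden = NULL,
                           activation = c("tanh", "linear"),
                           seed = 1L, optimizer = "adam",
                           learning_rate = 3e-4, epochs = 100L,
                           batch_size = 100L, k = 2L,
                           scale = kernel_scale(),
                           standardize_input = TRUE,
                           monitor_size = 1000L) {
  activation <- match.arg(activation)
  if (!is.numeric(n_in) || n_in < 1) stop_param("'n_in' must be >= 1")
  if (!is.numeric(n_out) || n_out < 1) stop_param("'n_out' must be >= 1")
  hidden <- if (is.null(hidden)) c(8L, 8L) else as.integer(hidden)
  if (length(hidden) && any(hidden <= 0L))
    stop_param("hidden layer widths must be positive")
  if (!identical(optimizer, "adam"))
    stop_param("unknown optimizer: ", optimizer)
  if (epochs < 1L) stop_param("'epochs' must be >= 1")
  if (k < 1L) stop_param("'k' must be >= 1")
  if (batch_size < k + 1L)
    stop_param("'batch_size' must be at least k + 1 = ", k + 1L,
               " (need k + 1 eigenvalues per batch)")
  if (learning_rate <= 0) stop_param("'learning_rate' must be positive")
  structure(list(n_in = as.integer(n_in), n_out = as.integer(n_out),
                 hidden = hidden, activation = activation,
                 seed = as.integer(seed), optimizer = optimizer,
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), k = as.integer(k),
                 scale = as_kernel_scale(scale),
                 standardize_input = isTRUE(standardize_input),
                 monitor_size = as.integer(monitor_size)),
            class = "mapping_config")
}

# Glorot-uniform initialization of all layers, deterministic in the seed.
init_layers <- function(config) {
  widths <- c(config$n_in, config$hidden, config$n_out)
  withr::with_seed(derive_seed(config$seed, 1L), {
    lapply(seq_len(length(widths) - 1L), function(i) {
      fan_in <- widths[i]; fan_out <- widths[i + 1L]
      lim <- sqrt(6 / (fan_in + fan_out))
      list(W = matrix(stats::runif(fan_in * fan_out, -lim, lim),
                      fan_in, fan_out),
           b = rep(0, fan_out))
    })
  })
}

mlp_forward <- function(layers, x, activation, cache = FALSE) {
  n_layers <- length(layers)
  acts <- if (cache) vector("list", n_layers + 1L)
  h <- x
  if (cache) acts[[1L]] <- h
  for (i in seq_len(n_layers)) {
    h <- sweep(h %*% layers[[i]]$W, 2L, layers[[i]]$b, "+")
    if (i < n_layers && activation == "tanh") h <- tanh(h)
    if (cache) acts[[i + 1L]] <- h
  }
  if (cache) list(out = h, acts = acts) else h
}

mlp_backward <- function(layers, acts, g_out, activation) {
  n_layers <- length(layers)
  grads <- vector("list", n_layers)
  delta <- g_out
  for (i in rev(seq_len(n_layers))) {
    grads[[i]] <- list(W = crossprod(acts[[i]], delta), b = colSums(delta))
    if (i > 1L) {
      delta <- delta %*% t(layers[[i]]$W)
      if (activation == "tanh") delta <- delta * (1 - acts[[i]]^2)
    }
  }
  grads
}

adam_init <- function(layers) {
  lapply(layers, function(l)
    list(mW = l$W * 0, vW = l$W * 0, mb = l$b * 0, vb = l$b * 0))
}

adam_step <- function(layers, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  c1 <- 1 - beta1^t; c2 <- 1 - beta2^t
  for (i in seq_along(layers)) {
    st <- state[[i]]; gr <- grads[[i]]
    st$mW <- beta1 * st$mW + (1 - beta1) * gr$W
    st$vW <- beta2 * st$vW + (1 - beta2) * gr$W^2
    st$mb <- beta1 * st$mb + (1 - beta1) * gr$b
    st$vb <- beta2 * st$vb + (1 - beta2) * gr$b^2
    layers[[i]]$W <- layers[[i]]$W - lr * (st$mW / c1) / (sqrt(st$vW / c2) + eps)
    layers[[i]]$b <- layers[[i]]$b - lr * (st$mb / c1) / (sqrt(st$vb / c2) + eps)
    state[[i]] <- st
  }
  list(layers = layers, state = state)
}

#' Build an (untrained) target mapping
#'
#' Initializes network parameters deterministically from `config$seed`
#' (Glorot-uniform weights, zero biases). Standardization vectors default to
#' identity until [train_mapping()] fills them in.
#'
#' @param config a [mapping_config()].
#' @return An object of class `"spectral_mapping"`.
#' @export
build_mapping <- function(config) {
  if (!inherits(config, "mapping_config"))
    stop_param("'config' must be a mapping_config object")
  structure(list(config = config,
                 layers = init_layers(config),
                 input_mean = rep(0, config$n_in),
                 input_scale = rep(1, config$n_in),
                 output_perm = seq_len(config$n_out),
                 output_sign = rep(1, config$n_out),
                 history = NULL),
            class = "spectral_mapping")
}

#' Project feature samples into CV space
#'
#' Applies the stored standardization (subtract `input_mean`, divide by
#' `input_scale`) and then the network; output columns are ordered and signed
#' by the slow-mode alignment stored at training time (see
#' [train_mapping()]), so `z1` carries the slowest process.
#'
#' @param object a `"spectral_mapping"`.
#' @param newdata numeric matrix, N x n_in.
#' @param ... unused.
#' @return Numeric N x n_out matrix with columns `z1, z2, ...`.
#' @export
predict.spectral_mapping <- function(object, newdata, ...) {
  x <- as_num_matrix(newdata, "feature matrix")
  if (!all(is.finite(x))) stop_input("feature matrix contains non-finite values")
  if (ncol(x) != object$config$n_in)
    stop_input("feature matrix has ", ncol(x), " columns; mapping expects ",
               object$config$n_in)
  xs <- sweep(sweep(x, 2L, object$input_mean, "-"),
              2L, object$input_scale, "/")
  z <- mlp_forward(object$layers, xs, object$config$activation)
  z <- sweep(z[, object$output_perm, drop = FALSE],
             2L, object$output_sign, "*")
  colnames(z) <- paste0("z", seq_len(ncol(z)))
  z
}

#' @export
print.spectral_mapping <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("spectral mapping: %d -> %s -> %d (%s), k = %d\n",
              cfg$n_in,
              if (length(cfg$hidden)) paste(cfg$hidden, collapse = "-")
              else "linear",
              cfg$n_out, cfg$activation, cfg$k))
  if (!is.null(x$history)) {
    h <- utils::tail(x$history, 1L)
    cat(sprintf("trained %d epochs; final monitor sigma = %.4f\n",
                nrow(x$history), h$sigma_monitor))
  } else cat("untrained\n")
  invisible(x)
}

monitor_sigma <- function(layers, config, xs_monitor) {
  z <- mlp_forward(layers, xs_monitor, config$activation)
  loss <- gap_loss(z, k = config$k, scale = config$scale)
  attr(loss, "sigma")
}

#' Train a target mapping by spectral-gap maximization
#'
#' Runs `epochs` passes of minibatch Adam on the negative spectral gap
#' ([gap_loss()]). Minibatch shuffling is seeded per epoch from the master
#' seed; a fixed, seeded subset of `min(N, monitor_size)` samples provides a
#' per-epoch monitoring gap. After training, output CVs are permuted (and
#' sign-fixed) so that `z1` is the coordinate best aligned with the dominant
#' relaxation eigenvector of the Markov matrix on the monitor subset.
#'
#' @param x numeric feature matrix, N x n_in, with `N >= batch_size`.
#' @param config a [mapping_config()].
#' @return A trained `"spectral_mapping"` whose `history` data frame has one
#'   row per epoch: `epoch`, `sigma_batch` (mean over minibatches),
#'   `sigma_monitor`.
#' @examples
#' \donttest{
#' bench <- make_benchmark("two_state", n_samples = 600, seed = 7)
#' cfg <- mapping_config(n_in = ncol(bench$features), hidden = c(32, 32),
#'                       epochs = 5, batch_size = 100, seed = 7)
#' fit <- train_mapping(bench$features, cfg)
#' z <- predict(fit, bench$features)
#' }
#' @export
train_mapping <- function(x, config) {
  x <- check_feature_matrix(x)
  if (!inherits(config, "mapping_config"))
    stop_param("'config' must be a mapping_config object")
  if (ncol(x) != config$n_in)
    stop_input("feature matrix has ", ncol(x), " columns; config expects ",
               config$n_in)
  n <- nrow(x)
  if (n < config$batch_size)
    stop_input("need at least batch_size = ", config$batch_size,
               " samples, got ", n)

  if (config$standardize_input) {
    mu <- colMeans(x)
    sdev <- apply(x, 2L, stats::sd)
    sdev[!is.finite(sdev) | sdev < 1e-12] <- 1
  } else {
    mu <- rep(0, ncol(x)); sdev <- rep(1, ncol(x))
  }
  xs <- sweep(sweep(x, 2L, mu, "-"), 2L, sdev, "/")

  layers <- init_layers(config)
  state <- adam_init(layers)

  m_idx <- withr::with_seed(derive_seed(config$seed, 2L),
                            sample.int(n, min(n, config$monitor_size)))
  xs_mon <- xs[m_idx, , drop = FALSE]

  hist_epoch <- integer(config$epochs)
  hist_batch <- numeric(config$epochs)
  hist_mon <- numeric(config$epochs)
  n_degenerate <- 0L
  t_step <- 0L

  for (epoch in seq_len(config$epochs)) {
    perm <- withr::with_seed(derive_seed(config$seed, 100L + epoch),
                             sample.int(n))
    starts <- seq(1L, n, by = config$batch_size)
    sigmas <- numeric(0)
    for (s0 in starts) {
      idx <- perm[s0:min(s0 + config$batch_size - 1L, n)]
      if (length(idx) < config$k + 1L) next  # partial tail too small for k+1 eigenvalues
      cache <- mlp_forward(layers, xs[idx, , drop = FALSE],
                           config$activation, cache = TRUE)
      loss <- tryCatch(
        gap_loss(cache$out, k = config$k, scale = config$scale,
                 gradient = TRUE),
        error = function(e) e)
      if (inherits(loss, "error") || !is.finite(as.numeric(loss)))
        stop_numeric("training diverged at epoch ", epoch, ", step ",
                     t_step + 1L,
                     if (inherits(loss, "error"))
                       paste0(": ", conditionMessage(loss)) else "")
      if (isTRUE(attr(loss, "degenerate"))) n_degenerate <- n_degenerate + 1L
      sigmas <- c(sigmas, attr(loss, "sigma"))
      grads <- mlp_backward(layers, cache$acts, attr(loss, "gradient"),
                            config$activation)
      t_step <- t_step + 1L
      upd <- adam_step(layers, grads, state, config$learning_rate, t_step)
      layers <- upd$layers; state <- upd$state
    }
    hist_epoch[epoch] <- epoch
    hist_batch[epoch] <- mean(sigmas)
    hist_mon[epoch] <- monitor_sigma(layers, config, xs_mon)
  }

  history <- data.frame(epoch = hist_epoch, sigma_batch = hist_batch,
                        sigma_monitor = hist_mon)
  attr(history, "n_degenerate") <- n_degenerate

  mapping <- structure(list(config = config, layers = layers,
                            input_mean = mu, input_scale = sdev,
                            output_perm = seq_len(config$n_out),
                            output_sign = rep(1, config$n_out),
                            history = history),
                       class = "spectral_mapping")
  order_cvs(mapping, xs_mon)
}

# Permute/sign output CVs so z1 best tracks the dominant relaxation
# eigenvector psi_1 = D^-1/2 v_1 of the monitor-subset Markov matrix.
# A coordinate permutation with signs is an isometry of CV space, so the
# kernel, spectrum and gap are unchanged.
order_cvs <- function(mapping, xs_monitor) {
  d <- mapping$config$n_out
  if (d == 1L) return(mapping)
  z <- mlp_forward(mapping$layers, xs_monitor, mapping$config$activation)
  eps <- resolve_epsilon(z, mapping$config$scale)
  g <- exp(-sq_dist_matrix(z) / eps)
  kap <- anisotropic_kernel(g, rowSums(g))
  ev <- transition_spectrum(kap, vectors = TRUE)
  psi <- attr(ev, "vectors")[, 2L] / sqrt(attr(ev, "row_sums"))
  cors <- suppressWarnings(
    vapply(seq_len(d), function(j) stats::cor(z[, j], psi), numeric(1)))
  cors[!is.finite(cors)] <- 0
  perm <- order(abs(cors), decreasing = TRUE)
  sgn <- sign(cors[perm]); sgn[sgn == 0] <- 1
  mapping$output_perm <- perm
  mapping$output_sign <- sgn
  mapping
}

#' Scan the metastable-state count k
#'
#' Trains one mapping per candidate k (seed offset by k, so runs are
#' independent but reproducible) and reports the final monitoring spectral
#' gap of each. The recommended k is the argmax of sigma: past the true
#' number of metastable states the gap drops, because the extra "state" has
#' to split a genuine basin.
#'
#' @param x numeric feature matrix.
#' @param config a [mapping_config()]; its `k` is overridden per candidate.
#' @param k_values integer vector of candidate state counts.
#' @return An object of class `"spectral_scan"`: list with `table` (data
#'   frame of `k`, `sigma`), `mappings` (one per k), `best_k`.
#' @export
scan_k <- function(x, config, k_values) {
  if (length(k_values) == 0L) stop_param("'k_values' must be non-empty")
  k_values <- as.integer(k_values)
  if (any(k_values < 1L)) stop_param("all k values must be >= 1")
  if (any(k_values > config$batch_size - 1L))
    stop_param("k values must be <= batch_size - 1 = ",
               config$batch_size - 1L)
  mappings <- vector("list", length(k_values))
  sigma <- numeric(length(k_values))
  for (i in seq_along(k_values)) {
    cfg <- config
    cfg$k <- k_values[i]
    cfg$seed <- derive_seed(config$seed, 9000L + k_values[i])
    mappings[[i]] <- train_mapping(x, cfg)
    sigma[i] <- utils::tail(mappings[[i]]$history$sigma_monitor, 1L)
  }
  tab <- data.frame(k = k_values, sigma = sigma)
  structure(list(table = tab, mappings = mappings,
                 best_k = k_values[which.max(sigma)]),
            class = "spectral_scan")
}

#' @export
print.spectral_scan <- function(x, ...) {
  cat("spectral-gap scan over k:\n")
  print(x$table, row.names = FALSE)
  cat("largest gap at k =", x$best_k, "\n")
  invisible(x)
}
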