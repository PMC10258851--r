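# Internal helpers: classed conditions, seed derivation, input coercion.

stop_input <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("spectmap_invalid_input", "spectmap_error")))
}

stop_param <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("spectmap_parameter_error", "spectmap_error")))
}

stop_numeric <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("spectmap_numerical_error", "spectmap_error")))
}

stop_format <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("spectmap_format_error", "spectmap_error")))
}

# Deterministically derive a child seed from a master seed and a salt,
# keeping the result inside the 32-bit integer range R requires.
derive_seed <- function(seed, salt) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(salt)) %% 2147483563L) + 1L
}

# Coerce CV samples / feature matrices to a plain numeric matrix.
as_num_matrix <- function(x, what = "input") {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.vector(x) && is.numeric(x)) x <- matrix(x, ncol = 1L)
  if (!is.matrix(x) || !is.numeric(x))
    stop_input(what, " must be a numeric matrix")
  x
}

check_cv_samples <- function(z, min_rows = 2L) {
  z <- as_num_matrix(z, "CV samples")
  if (nrow(z) < min_rows)
    stop_input("need at least ", min_rows, " samples, got ", nrow(z))
  if (ncol(z) < 1L) stop_input("need at least one CV column")
  if (!all(is.finite(z))) stop_input("CV samples contain non-finite values")
  z
}

check_feature_matrix <- function(x) {
  x <- as_num_matrix(x, "feature matrix")
  if (nrow(x) < 2L) stop_input("need at least 2 samples, got ", nrow(x))
  if (!all(is.finite(x))) stop_input("feature matrix contains non-finite values")
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a
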