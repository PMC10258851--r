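# Featurization from Cartesian coordinates, delimited/serialized matrix I/O
# and the schema-validated run configuration.

#' Pairwise-distance featurization of per-frame coordinates
#'
#' Builds the standard high-dimensional representation for folding
#' trajectories: all S(S-1)/2 pairwise Euclidean distances between S
#' selected sites (e.g. C-alpha atoms), per frame. Feature order is
#' lexicographic in the site-index pair (i < j); units follow the input
#' coordinates.
#'
#' @param coordinates a 3-D array `frames x sites x 3`, or a list of
#'   per-frame `sites x 3` matrices.
#' @return Feature matrix `frames x S(S-1)/2` with columns `d<i>_<j>`.
#' @examples
#' coords <- array(rnorm(5 * 10 * 3), c(5, 10, 3))
#' x <- featurize_pairwise_distances(coords)  # 5 x 45
#' @export
featurize_pairwise_distances <- function(coordinates) {
  if (is.list(coordinates)) {
    frames <- coordinates
  } else if (is.array(coordinates) && length(dim(coordinates)) == 3L) {
    frames <- lapply(seq_len(dim(coordinates)[1L]), function(i)
      coordinates[i, , ])
  } else {
    stop_input("'coordinates' must be a frames x sites x 3 array ",
               "or a list of sites x 3 matrices")
  }
  if (length(frames) == 0L) stop_input("no frames provided")
  s <- nrow(frames[[1L]])
  if (is.null(s) || s < 2L) stop_input("need at least 2 sites per frame")
  pairs <- which(upper.tri(diag(s)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
  out <- matrix(NA_real_, length(frames), nrow(pairs))
  for (f in seq_along(frames)) {
    fr <- frames[[f]]
    if (!is.matrix(fr) || nrow(fr) != s || ncol(fr) != 3L ||
        !all(is.finite(fr)))
      stop_input("frame ", f, " has missing or malformed coordinates")
    diff <- fr[pairs[, 1L], , drop = FALSE] - fr[pairs[, 2L], , drop = FALSE]
    out[f, ] <- sqrt(rowSums(diff^2))
  }
  colnames(out) <- paste0("d", pairs[, 1L], "_", pairs[, 2L])
  out
}

#' Read / write a feature matrix
#'
#' `"delimited"` files are whitespace- or tab-separated text with an
#' optional header row of feature names; `"rds"` uses R's self-describing
#' serialization and round-trips bit-exactly.
#'
#' @param path file path.
#' @param format `"delimited"` or `"rds"`.
#' @return `read_feature_matrix()` returns a numeric matrix;
#'   `write_feature_matrix()` returns `path` invisibly.
#' @export
read_feature_matrix <- function(path, format = c("delimited", "rds")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_input("file not found: ", path)
  if (format == "rds") {
    x <- readRDS(path)
    return(check_feature_matrix(x))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0L) stop_input("empty input file: ", path)
  nf <- utils::count.fields(textConnection(lines), sep = "")
  if (length(unique(nf)) != 1L)
    stop_format("ragged rows in ", path, ": line ",
                which(nf != nf[1L])[1L], " has ", nf[nf != nf[1L]][1L],
                " fields, expected ", nf[1L])
  first <- strsplit(trimws(lines[1L]), "[ \t,]+")[[1L]]
  has_header <- anyNA(suppressWarnings(as.numeric(first)))
  df <- utils::read.table(text = lines, header = has_header,
                          colClasses = "character")
  m <- suppressWarnings(
    matrix(as.numeric(as.matrix(df)), nrow(df), ncol(df)))
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1L, ]
    stop_format("non-numeric cell at data row ", bad[1L], ", column ",
                bad[2L], " in ", path)
  }
  if (has_header) colnames(m) <- colnames(df)
  m
}

#' @param x numeric matrix (feature names taken from `colnames`).
#' @rdname read_feature_matrix
#' @export
write_feature_matrix <- function(x, path, format = c("delimited", "rds")) {
  format <- match.arg(format)
  x <- as_num_matrix(x, "feature matrix")
  if (format == "rds") {
    saveRDS(x, path)
    return(invisible(path))
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(colnames(x)))
    writeLines(paste(colnames(x), collapse = "\t"), con)
  utils::write.table(format(x, digits = 17, trim = TRUE, scientific = TRUE),
                     con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# ---- run configuration ----------------------------------------------------

run_config_schema <- function() {
  list(
    seed = 1L,
    temperature = 300,
    mapping = list(n_out = 2L, hidden = NULL, activation = "tanh",
                   learning_rate = 3e-4, epochs = 100L, batch_size = 100L,
                   k = 2L, standardize_input = TRUE, monitor_size = 1000L),
    kernel = list(mode = "median_heuristic", epsilon = NULL, multiplier = 1),
    binning = list(bins = 100L),
    simulate = list(name = "two_state", n_samples = 5000L, n_features = 40L,
                    noise_sigma = 0.1, stride = 100L),
    train_stride = 1L,
    package_version = NULL)  # stamped by write_run_config()
}

merge_config <- function(defaults, user, path = "") {
  for (key in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(defaults))
      stop_param("unknown configuration key: ", full)
    if (is.list(defaults[[key]]) && !is.null(user[[key]])) {
      if (!is.list(user[[key]]))
        stop_param("configuration key ", full, " must be a mapping")
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]], full)
    } else {
      defaults[key] <- user[key]
    }
  }
  defaults
}

#' Run configuration: defaults, reading, writing
#'
#' A run configuration is a nested key-value document (YAML on disk)
#' covering the seed, temperature, mapping hyperparameters, kernel scale,
#' binning and the synthetic generator. Unknown keys are rejected;
#' [write_run_config()] emits the fully resolved document (defaults filled
#' in) next to a run's outputs, together with the package version, so any
#' run can be reproduced from its output directory alone.
#'
#' @param overrides named list overriding defaults (validated against the
#'   schema).
#' @return `default_run_config()` / `read_run_config()` return the resolved
#'   configuration list.
#' @export
default_run_config <- function(overrides = list()) {
  merge_config(run_config_schema(), overrides)
}

#' @param path YAML file path.
#' @rdname default_run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_input("config file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  default_run_config(user)
}

#' @param config resolved configuration list.
#' @rdname default_run_config
#' @export
write_run_config <- function(config, path) {
  config$package_version <- as.character(utils::packageVersion("spectmap"))
  yaml::write_yaml(config, path)
  invisible(path)
}

# Build a mapping_config from a resolved run configuration + feature count.
config_to_mapping <- function(config, n_in) {
  kc <- if (identical(config$kernel$mode, "fixed"))
    kernel_scale("fixed", epsilon = config$kernel$epsilon,
                 multiplier = config$kernel$multiplier)
  else kernel_scale("median_heuristic",
                    multiplier = config$kernel$multiplier)
  m <- config$mapping
  mapping_config(n_in = n_in, n_out = m$n_out, hidden = m$hidden,
                 activation = m$activation, seed = config$seed,
                 learning_rate = m$learning_rate, epochs = m$epochs,
                 batch_size = m$batch_size, k = m$k, scale = kc,
                 standardize_input = m$standardize_input,
                 monitor_size = m$monitor_size)
}
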