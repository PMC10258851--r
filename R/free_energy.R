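# Free-energy landscapes F(z) = -(1/beta) ln p(z) from projected CV samples.
# p(z) is estimated by plain histogramming: empty bins are flagged
# unreachable (NA) rather than pseudo-counted, because pseudo-counts bias
# barrier heights, the key observable.

KB_KJ_MOL_K <- 0.0083144626  # Boltzmann constant, kJ/(mol K)

#' Thermodynamic state
#'
#' @param temperature temperature in kelvin.
#' @return List of class `"thermo"` with `temperature`, `kB`
#'   (0.0083144626 kJ/(mol K)) and `beta` = 1/(kB T) in mol/kJ.
#' @export
thermo <- function(temperature = 300) {
  if (!is.numeric(temperature) || length(temperature) != 1L ||
      !is.finite(temperature) || temperature <= 0)
    stop_param("'temperature' must be a single positive number (kelvin)")
  structure(list(temperature = temperature, kB = KB_KJ_MOL_K,
                 beta = 1 / (KB_KJ_MOL_K * temperature)),
            class = "thermo")
}

resolve_edges <- function(zj, bins_j, range_j) {
  if (is.numeric(bins_j) && length(bins_j) > 1L) {
    edges <- as.numeric(bins_j)
    if (is.unsorted(edges, strictly = TRUE))
      stop_param("explicit bin edges must be strictly increasing")
    return(edges)
  }
  nb <- as.integer(bins_j)
  if (nb < 1L) stop_param("bin count must be >= 1")
  if (is.null(range_j)) {
    lo <- min(zj); hi <- max(zj)
    pad <- 0.01 * (hi - lo)
    if (pad == 0) pad <- max(abs(lo), 1) * 1e-8  # degenerate: all equal
    lo <- lo - pad; hi <- hi + pad
  } else {
    lo <- range_j[1L]; hi <- range_j[2L]
    if (!is.finite(lo) || !is.finite(hi) || hi <= lo)
      stop_param("range must have positive width")
  }
  seq(lo, hi, length.out = nb + 1L)
}

#' Histogram density of CV samples
#'
#' Bins samples on a regular grid. Each axis gets 100 bins by default,
#' spanning the data range padded by 1% on each side. Samples outside an
#' explicit `ranges` are dropped (their number is recorded in `n_dropped`).
#'
#' @param z CV samples: vector, or matrix with 1 or 2 columns (use
#'   [marginal_profile()] for single axes of higher-dimensional CVs).
#' @param bins per-axis bin count (scalar or one per axis) or, per axis, an
#'   explicit vector of strictly increasing edges.
#' @param ranges optional list (or vector for 1-D) of per-axis `c(lo, hi)`.
#' @return List of class `"cv_histogram"`: `counts` (vector or matrix),
#'   `edges`, `centers` (lists per axis), `n_in`, `n_dropped`.
#' @export
histogram_density <- function(z, bins = 100, ranges = NULL) {
  z <- check_cv_samples(z, min_rows = 1L)
  d <- ncol(z)
  if (d > 2L)
    stop_param("surfaces support d <= 2; use marginal_profile() for one ",
               "axis of a higher-dimensional CV set")
  if (is.numeric(ranges) && d == 1L) ranges <- list(ranges)
  if (!is.list(bins)) bins <- if (length(bins) == d) as.list(bins)
                              else rep(list(bins), d)
  edges <- lapply(seq_len(d), function(j)
    resolve_edges(z[, j], bins[[j]], ranges[[j]]))
  nb <- vapply(edges, function(e) length(e) - 1L, integer(1))

  idx <- matrix(0L, nrow(z), d)
  for (j in seq_len(d)) {
    e <- edges[[j]]
    i <- findInterval(z[, j], e, rightmost.closed = TRUE)
    i[z[, j] < e[1L] | z[, j] > e[length(e)]] <- 0L
    idx[, j] <- i
  }
  keep <- rowSums(idx >= 1L) == d
  n_dropped <- sum(!keep)
  if (n_dropped > 0L)
    message(n_dropped, " sample(s) outside the histogram range were dropped")
  idx <- idx[keep, , drop = FALSE]

  if (d == 1L) {
    counts <- tabulate(idx[, 1L], nbins = nb[1L])
  } else {
    flat <- idx[, 1L] + (idx[, 2L] - 1L) * nb[1L]
    counts <- matrix(tabulate(flat, nbins = nb[1L] * nb[2L]), nb[1L], nb[2L])
  }
  centers <- lapply(edges, function(e) (e[-1L] + e[-length(e)]) / 2)
  structure(list(counts = counts, edges = edges, centers = centers,
                 n_in = sum(keep), n_dropped = n_dropped),
            class = "cv_histogram")
}

#' Convert histogram counts to a free-energy surface
#'
#' Occupied bins get \eqn{F = -(1/\beta)\,\ln(c / N)} and the surface is
#' shifted so its minimum is exactly 0 ("up to an irrelevant constant").
#' Empty bins are `NA`, i.e. unreachable at the available sampling.
#'
#' @param h a `"cv_histogram"` (or a bare counts vector/matrix).
#' @param thermo a [thermo()] state.
#' @return List of class `"fes"`: `free_energy` (kJ/mol, `NA` = unoccupied),
#'   `counts`, `edges`, `centers`, `thermo`, `n_samples`.
#' @export
to_free_energy <- function(h, thermo = spectmap::thermo(300)) {
  if (!inherits(h, "cv_histogram")) {
    counts <- h
    h <- list(counts = counts, edges = NULL, centers = NULL,
              n_in = sum(counts), n_dropped = 0L)
  }
  counts <- h$counts
  total <- sum(counts)
  if (total <= 0) stop_input("all histogram bins are empty")
  f <- counts * NA_real_
  occ <- counts > 0
  f[occ] <- -log(counts[occ] / total) / thermo$beta
  f <- f - min(f[occ])
  structure(list(free_energy = f, counts = counts, edges = h$edges,
                 centers = h$centers, thermo = thermo,
                 n_samples = h$n_in),
            class = "fes")
}

#' Free-energy surface of CV samples
#'
#' One-call wrapper around [histogram_density()] and [to_free_energy()].
#'
#' @inheritParams histogram_density
#' @inheritParams to_free_energy
#' @return An object of class `"fes"`.
#' @examples
#' z <- cbind(rnorm(2000), rnorm(2000))
#' surf <- free_energy_surface(z, bins = 40, thermo = thermo(300))
#' @export
free_energy_surface <- function(z, bins = 100, ranges = NULL,
                                thermo = spectmap::thermo(300)) {
  to_free_energy(histogram_density(z, bins, ranges), thermo)
}

#' Marginal free-energy profile along one CV
#'
#' Integrates out all other CVs: under shared binning this is exactly the
#' histogram of the selected coordinate alone, so
#' \eqn{F(z_1) = -(1/\beta)\ln\int \mathrm{d}z_2\, p(z_1, z_2)}
#' equals the 1-D estimate from the `axis` column.
#'
#' @param z CV samples, matrix with d >= 1 columns (any d).
#' @param axis which CV to keep (1-based).
#' @param bins bin count or explicit edges for the kept axis.
#' @param ranges optional `c(lo, hi)` for the kept axis.
#' @inheritParams to_free_energy
#' @return A 1-D `"fes"`.
#' @export
marginal_profile <- function(z, axis = 1L, bins = 100, ranges = NULL,
                             thermo = spectmap::thermo(300)) {
  z <- check_cv_samples(z, min_rows = 1L)
  if (axis < 1L || axis > ncol(z))
    stop_param("'axis' out of range: got ", axis, " for d = ", ncol(z))
  free_energy_surface(z[, axis, drop = FALSE], bins = bins,
                      ranges = if (is.null(ranges)) NULL else list(ranges),
                      thermo = thermo)
}

#' @export
print.fes <- function(x, ...) {
  dims <- if (is.matrix(x$counts)) paste(dim(x$counts), collapse = " x ")
          else length(x$counts)
  cat(sprintf("free-energy surface: %s bins, %d samples, T = %g K\n",
              dims, x$n_samples, x$thermo$temperature))
  occ <- x$counts > 0
  cat(sprintf("occupied bins: %d; max F over occupied: %.2f kJ/mol\n",
              sum(occ), max(x$free_energy[occ])))
  invisible(x)
}

# Run-length plateaus of a profile with NA treated as +Inf (unreachable).
profile_plateaus <- function(f) {
  v <- ifelse(is.na(f), Inf, f)
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(value = r$values, start = starts, end = ends)
}

#' Barrier height of a 1-D free-energy profile
#'
#' Locates local minima of the profile (unoccupied bins count as infinitely
#' high), selects the two deepest (ties broken toward the leftmost) and
#' returns the height of the lowest crossing between them: the maximum
#' intervening free energy minus the higher of the two minima.
#'
#' @param profile a 1-D `"fes"` (e.g. from [marginal_profile()]) or a bare
#'   numeric free-energy vector.
#' @return Barrier height in kJ/mol with attributes `"minima"` (bin indices)
#'   and `"top"` (crossing bin index), or `NA_real_` if the profile has
#'   fewer than two local minima (single-basin "no barrier" result).
#' @examples
#' barrier_height(c(0, 5, 1))   # 4
#' barrier_height(c(0, 1, 2))   # NA: monotone, single basin
#' @export
barrier_height <- function(profile) {
  f <- if (inherits(profile, "fes")) profile$free_energy else as.numeric(profile)
  if (is.matrix(f)) stop_param("barrier_height() expects a 1-D profile")
  p <- profile_plateaus(f)
  np <- nrow(p)
  lower_left <- c(Inf, p$value[-np])   # boundaries count as high walls
  lower_right <- c(p$value[-1L], Inf)
  is_min <- is.finite(p$value) & p$value < lower_left & p$value < lower_right
  mins <- p[is_min, , drop = FALSE]
  if (nrow(mins) < 2L) return(NA_real_)
  ord <- order(mins$value, mins$start)  # deepest first, leftmost on ties
  two <- mins[ord[1:2], , drop = FALSE]
  two <- two[order(two$start), ]
  between <- seq(two$end[1L] + 1L, two$start[2L] - 1L)
  fb <- f[between]
  fb <- fb[is.finite(fb)]
  if (length(fb) == 0L) return(NA_real_)  # gap entirely unsampled
  out <- max(fb) - max(two$value)
  attr(out, "minima") <- c(two$start[1L], two$start[2L])
  attr(out, "top") <- between[which.max(f[between])]
  out
}

#' Write / read a free-energy surface as delimited text
#'
#' The writer emits a self-describing tab-separated file: comment lines
#' carry the package version, temperature and per-axis bin edges; data rows
#' hold bin centers, count and free energy (17 significant digits, so the
#' round trip is value-exact). `read_fes()` restores the `"fes"` object.
#'
#' @param fes an `"fes"` object.
#' @param path output file.
#' @return `write_fes()` returns `path` invisibly; `read_fes()` an `"fes"`.
#' @export
write_fes <- function(fes, path) {
  if (!inherits(fes, "fes")) stop_param("'fes' must be an fes object")
  d <- length(fes$edges)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# spectmap ", as.character(utils::packageVersion("spectmap")),
           " free-energy surface"),
    paste0("# temperature_K: ", format(fes$thermo$temperature, digits = 17)),
    paste0("# n_samples: ", fes$n_samples),
    vapply(seq_len(d), function(j)
      paste0("# edges", j, ": ",
             paste(format(fes$edges[[j]], digits = 17, trim = TRUE),
                   collapse = " ")), character(1))), con)
  if (d == 1L) {
    df <- data.frame(center1 = fes$centers[[1L]], count = fes$counts,
                     free_energy = fes$free_energy)
  } else {
    grid <- expand.grid(i = seq_along(fes$centers[[1L]]),
                        j = seq_along(fes$centers[[2L]]))
    df <- data.frame(center1 = fes$centers[[1L]][grid$i],
                     center2 = fes$centers[[2L]][grid$j],
                     count = as.vector(fes$counts),
                     free_energy = as.vector(fes$free_energy))
  }
  num <- function(x) format(x, digits = 17, trim = TRUE)
  writeLines(paste(colnames(df), collapse = "\t"), con)
  writeLines(do.call(paste, c(lapply(df, num), sep = "\t")), con)
  invisible(path)
}

#' @rdname write_fes
#' @export
read_fes <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  temp <- as.numeric(sub(".*temperature_K: ", "",
                         grep("temperature_K", hdr, value = TRUE)))
  n_samples <- as.integer(sub(".*n_samples: ", "",
                              grep("n_samples", hdr, value = TRUE)))
  edge_lines <- grep("^# edges", hdr, value = TRUE)
  edges <- lapply(edge_lines, function(l)
    as.numeric(strsplit(sub("^# edges[0-9]+: ", "", l), " +")[[1]]))
  body <- lines[!grepl("^#", lines)]
  df <- utils::read.table(text = body, header = TRUE, sep = "\t")
  d <- length(edges)
  nb <- vapply(edges, function(e) length(e) - 1L, integer(1))
  if (d == 1L) {
    counts <- df$count
    f <- df$free_energy
  } else {
    counts <- matrix(df$count, nb[1L], nb[2L])
    f <- matrix(df$free_energy, nb[1L], nb[2L])
  }
  centers <- lapply(edges, function(e) (e[-1L] + e[-length(e)]) / 2)
  structure(list(free_energy = f, counts = counts, edges = edges,
                 centers = centers, thermo = thermo(temp),
                 n_samples = n_samples),
            class = "fes")
}
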