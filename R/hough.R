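#' Line Hough transform accumulator
#'
#' Each edge pixel `(x, y)` (0-based column/row) votes once per orientation
#' bin: for angle `theta` the signed distance `rho = x cos(theta) +
#' y sin(theta)` is binned at `rho_resolution` pixels per bin. Angles span
#' `[-90, 90)` degrees in `theta_bins` equal steps. Long straight image
#' structures concentrate votes in few accumulator cells; irregular textures
#' spread them out.
#'
#' @param edges An `edge_map` from [detect_edges()] or a logical matrix.
#' @param theta_bins Number of orientation bins (default 180, i.e. 1 degree).
#' @param rho_resolution Pixels per distance bin (default 1).
#' @return A `hough_accumulator`: list with the integer `counts` matrix
#'   (rows = rho bins, cols = theta bins), `theta_deg`, and `rho_breaks`.
#' @export
hough_accumulate <- function(edges, theta_bins = 180L, rho_resolution = 1) {
  mask <- if (inherits(edges, "edge_map")) edges$mask else edges
  stopifnot(is.matrix(mask), is.logical(mask))
  if (theta_bins < 2L) stop("`theta_bins` must be >= 2", call. = FALSE)
  if (rho_resolution <= 0) stop("`rho_resolution` must be > 0", call. = FALSE)
  w <- which(mask, arr.ind = TRUE)
  if (nrow(w) == 0L)
    stop("empty edge mask: Hough accumulator undefined", call. = FALSE)
  y <- w[, 1] - 1; x <- w[, 2] - 1
  theta <- (-90 + (0:(theta_bins - 1L)) * 180 / theta_bins) * pi / 180
  diag_len <- sqrt((nrow(mask) - 1)^2 + (ncol(mask) - 1)^2)
  n_rho <- max(1L, ceiling(2 * diag_len / rho_resolution) + 1L)
  rho <- outer(x, cos(theta)) + outer(y, sin(theta))
  bin <- floor((rho + diag_len) / rho_resolution) + 1L
  bin[bin < 1L] <- 1L; bin[bin > n_rho] <- n_rho
  counts <- matrix(0L, n_rho, theta_bins)
  for (t in seq_len(theta_bins)) {
    tb <- tabulate(bin[, t], nbins = n_rho)
    counts[, t] <- counts[, t] + tb
  }
  structure(list(counts = counts,
                 theta_deg = -90 + (0:(theta_bins - 1L)) * 180 / theta_bins,
                 rho_resolution = rho_resolution),
            class = "hough_accumulator")
}

#' @export
print.hough_accumulator <- function(x, ...) {
  cat(sprintf("<hough_accumulator> %d rho bins x %d theta bins, %d votes\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts)))
  invisible(x)
}

#' Gini inequality index
#'
#' For non-negative values `X` sorted ascending,
#' `GI = 2 sum_i i X_(i) / (n sum_i X_i) - (n + 1)/n`.
#' Equals 0 when all values are equal and approaches 1 when a single value
#' carries all the mass (the exact upper bound for a one-hot vector is
#' `(n - 1)/n`). Identical to the normalized mean absolute pairwise
#' difference.
#'
#' @param values Non-negative numeric vector with a positive sum.
#' @return Scalar in `[0, (n - 1)/n]`.
#' @export
gini_index <- function(values) {
  if (length(values) < 1L || !is.numeric(values))
    stop("`values` must be a non-empty numeric vector", call. = FALSE)
  if (any(values < 0))
    stop("Gini index requires non-negative values", call. = FALSE)
  if (sum(values) == 0)
    stop("Gini index undefined for an all-zero vector", call. = FALSE)
  x <- sort(as.double(values))
  n <- as.double(length(x))
  2 * sum(seq_len(n) * x) / (n * sum(x)) - (n + 1) / n
}

#' Hough-Gini texture feature
#'
#' Treats the flattened Hough accumulator counts as incomes and scores their
#' inequality with [gini_index()]. Regular textures (long straight edges)
#' concentrate votes and yield a high index; scattered, irregular edges
#' spread votes and yield a lower one. Zero-vote cells are legitimate zero
#' incomes and are included by default.
#'
#' @inheritParams hough_accumulate
#' @param include_zeros Include zero-count accumulator cells (default
#'   `TRUE`).
#' @param per_theta If `TRUE`, return the mean of per-orientation-column
#'   Gini indices instead of the index of the full flattened accumulator.
#' @return Scalar in `[0, 1)`.
#' @export
hough_gini_feature <- function(edges, theta_bins = 180L, rho_resolution = 1,
                               include_zeros = TRUE, per_theta = FALSE) {
  acc <- hough_accumulate(edges, theta_bins, rho_resolution)
  score <- function(v) {
    if (!include_zeros) v <- v[v > 0]
    gini_index(v)
  }
  if (per_theta) {
    mean(apply(acc$counts, 2, score))
  } else {
    score(as.vector(acc$counts))
  }
}
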