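#' Histogram of oriented gradients descriptor
#'
#' Computes a compact HOG descriptor on a resized copy of the image:
#' bilinear resize to `resize_to x resize_to` (default 25), centered-
#' difference gradients `[-1, 0, 1]` in x and y (replicate borders),
#' unsigned orientation over `[0, 180)` degrees quantized into `bins`
#' orientation bins (default 6, i.e. 30 degrees per bin) with
#' magnitude-weighted linear interpolation between the two nearest bins
#' (wrapping at 180), `cell_size x cell_size` pixel cells (default 3) on the
#' full-cell grid (the final partial pixel row/column is dropped:
#' 25 px / 3 px -> 8 x 8 cells), per-cell L2 normalization with epsilon
#' 1e-6, and row-major concatenation. Defaults give a 8 x 8 x 6 = 384-long
#' vector.
#'
#' @param img A [radiograph] or numeric matrix.
#' @param resize_to Side length of the working image (default 25).
#' @param cell_size Cell side in pixels (default 3).
#' @param bins Orientation bin count over 180 degrees (default 6).
#' @return A `hog_descriptor`: list with `vector` (length
#'   `cells^2 * bins`), `cells`, `bins`, `cell_size`.
#' @export
compute_hog <- function(img, resize_to = 25L, cell_size = 3L, bins = 6L) {
  px <- as_pixels(img)
  if (length(px) < 1L) stop("empty image", call. = FALSE)
  m <- resize_bilinear(px, resize_to, resize_to)
  p <- pad_replicate(m, 1L)
  n <- resize_to
  gx <- p[2:(n + 1), 3:(n + 2)] - p[2:(n + 1), 1:n]   # d/dx (columns)
  gy <- p[3:(n + 2), 2:(n + 1)] - p[1:n, 2:(n + 1)]   # d/dy (rows)
  mag <- sqrt(gx^2 + gy^2)
  ang <- atan2(gy, gx) * 180 / pi
  ang <- ang %% 180                                    # unsigned [0, 180)

  bin_width <- 180 / bins
  # soft assignment between the two bins whose centers bracket the angle
  pos <- ang / bin_width - 0.5
  b_lo <- floor(pos)
  w_hi <- pos - b_lo
  b_lo <- b_lo %% bins
  b_hi <- (b_lo + 1) %% bins

  n_cells <- n %/% cell_size
  used <- n_cells * cell_size
  cell_of <- function(ix) (ix - 1L) %/% cell_size + 1L
  rows <- matrix(seq_len(n), n, n)[1:used, 1:used]
  cols <- matrix(seq_len(n), n, n, byrow = TRUE)[1:used, 1:used]
  cr <- cell_of(rows); cc <- cell_of(cols)
  sub <- function(m) m[1:used, 1:used]

  hist_key <- function(bin_idx)
    (cr - 1L) * n_cells * bins + (cc - 1L) * bins + bin_idx + 1L
  acc <- numeric(n_cells * n_cells * bins)
  k_lo <- hist_key(sub(b_lo)); k_hi <- hist_key(sub(b_hi))
  v_lo <- sub(mag * (1 - w_hi)); v_hi <- sub(mag * w_hi)
  for (chunk in list(cbind(as.vector(k_lo), as.vector(v_lo)),
                     cbind(as.vector(k_hi), as.vector(v_hi)))) {
    s <- rowsum(chunk[, 2], group = chunk[, 1])
    acc[as.integer(rownames(s))] <- acc[as.integer(rownames(s))] + s[, 1]
  }

  # per-cell L2 normalization
  desc <- acc
  dim(desc) <- c(bins, n_cells * n_cells)
  norms <- sqrt(colSums(desc^2)) + 1e-6
  desc <- sweep(desc, 2, norms, "/")
  structure(list(vector = as.vector(desc), cells = c(n_cells, n_cells),
                 bins = as.integer(bins), cell_size = as.integer(cell_size)),
            class = "hog_descriptor")
}

#' @export
print.hog_descriptor <- function(x, ...) {
  cat(sprintf("<hog_descriptor> %d x %d cells x %d bins = %d values\n",
              x$cells[1], x$cells[2], x$bins, length(x$vector)))
  invisible(x)
}

#' Scalar HOG summary
#'
#' The arithmetic mean of the descriptor entries, used when a single
#' per-image number is needed (e.g. box-plot summaries); classification uses
#' the full vector.
#'
#' @param desc A `hog_descriptor` from [compute_hog()] or numeric vector.
#' @return Scalar mean.
#' @export
hog_summary <- function(desc) {
  v <- if (inherits(desc, "hog_descriptor")) desc$vector else desc
  mean(v)
}
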