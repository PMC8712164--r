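#' Gray-level co-occurrence matrix
#'
#' Quantizes intensities into `levels` equal-width bins over `[0, 255]` and
#' counts co-occurring level pairs at the given pixel offsets. For a
#' distance `d`, the angle set maps to offsets (rows increase downward):
#' 0 deg -> (0, d), 45 deg -> (-d, d), 90 deg -> (-d, 0),
#' 135 deg -> (-d, -d). Counts are accumulated over all requested angles,
#' optionally symmetrized (count each pair in both directions), and
#' normalized to sum to one.
#'
#' @param img A [radiograph] or numeric matrix with values in `[0, 255]`.
#' @param levels Number of gray levels `Ng >= 2` (default 64).
#' @param distance Offset length in pixels (default 1).
#' @param angles Subset of `c(0, 45, 90, 135)` degrees (default all four).
#' @param symmetric Count each pair in both directions (default `TRUE`).
#' @return A `glcm` object: list with the `Ng x Ng` probability matrix `A`
#'   and the quantization metadata.
#' @export
compute_glcm <- function(img, levels = 64L, distance = 1L,
                         angles = c(0, 45, 90, 135), symmetric = TRUE) {
  px <- as_pixels(img)
  if (levels < 2L) stop("`levels` must be >= 2", call. = FALSE)
  if (distance < 1L) stop("`distance` must be >= 1", call. = FALSE)
  if (!all(angles %in% c(0, 45, 90, 135)) || length(angles) == 0L)
    stop("`angles` must be a non-empty subset of {0, 45, 90, 135}",
         call. = FALSE)
  d <- as.integer(distance)
  q <- quantize_levels(px, levels)
  nr <- nrow(q); nc <- ncol(q)
  offsets <- list(`0` = c(0L, d), `45` = c(-d, d),
                  `90` = c(-d, 0L), `135` = c(-d, -d))
  counts <- numeric(levels * levels)
  for (a in as.character(angles)) {
    off <- offsets[[a]]
    if (nr <= abs(off[1]) || nc <= abs(off[2]))
      stop("image smaller than the GLCM offset", call. = FALSE)
    r1 <- max(1L, 1L - off[1]):min(nr, nr - off[1])
    c1 <- max(1L, 1L - off[2]):min(nc, nc - off[2])
    i <- q[r1, c1, drop = FALSE]
    j <- q[r1 + off[1], c1 + off[2], drop = FALSE]
    counts <- counts + tabulate(i * levels + j + 1L, nbins = levels * levels)
  }
  A <- matrix(counts, levels, levels, byrow = TRUE) # row = i, col = j
  if (symmetric) A <- A + t(A)
  total <- sum(A)
  if (total == 0) stop("no co-occurring pairs counted", call. = FALSE)
  structure(list(A = A / total, levels = as.integer(levels), distance = d,
                 angles = angles, symmetric = symmetric),
            class = "glcm")
}

quantize_levels <- function(px, levels) {
  q <- floor(px * levels / 256)
  q[q > levels - 1L] <- levels - 1L   # guard pixel value exactly 255+
  q
}

#' @export
print.glcm <- function(x, ...) {
  cat(sprintf("<glcm> %d levels, distance %d, angles {%s}%s\n",
              x$levels, x$distance, paste(x$angles, collapse = ", "),
              if (x$symmetric) ", symmetric" else ""))
  invisible(x)
}

# Accept a glcm object or a bare normalized matrix.
as_glcm_matrix <- function(glcm) {
  A <- if (inherits(glcm, "glcm")) glcm$A else glcm
  stopifnot(is.matrix(A), nrow(A) == ncol(A))
  if (any(A < 0) || abs(sum(A) - 1) > 1e-8)
    stop("GLCM must be normalized: entries >= 0 summing to 1", call. = FALSE)
  A
}

# 0-based level index grids for an Ng x Ng GLCM.
glcm_index_grids <- function(A) {
  ng <- nrow(A)
  list(i = matrix(0:(ng - 1), ng, ng),
       j = matrix(0:(ng - 1), ng, ng, byrow = TRUE))
}

#' GLCM contrast
#'
#' Local intensity variation: `sum (i - j)^2 A_ij`. Zero iff all
#' co-occurrence mass lies on the diagonal (locally constant image).
#'
#' @param glcm A `glcm` object or normalized co-occurrence matrix.
#' @return Non-negative scalar.
#' @export
glcm_contrast <- function(glcm) {
  A <- as_glcm_matrix(glcm)
  g <- glcm_index_grids(A)
  sum((g$i - g$j)^2 * A)
}

#' GLCM correlation
#'
#' Linear dependence of co-occurring levels:
#' `sum (i - mu_i)(j - mu_j) A_ij / (sigma_i sigma_j)`, with means and
#' standard deviations of the row/column marginals. Lies in `[-1, 1]`.
#' For a degenerate GLCM with zero marginal variance (constant image) the
#' value is defined as 0, with a warning.
#'
#' @inheritParams glcm_contrast
#' @return Scalar in `[-1, 1]`.
#' @export
glcm_correlation <- function(glcm) {
  A <- as_glcm_matrix(glcm)
  g <- glcm_index_grids(A)
  pi_ <- rowSums(A); pj <- colSums(A)
  lv <- 0:(nrow(A) - 1)
  mu_i <- sum(lv * pi_); mu_j <- sum(lv * pj)
  sd_i <- sqrt(sum((lv - mu_i)^2 * pi_))
  sd_j <- sqrt(sum((lv - mu_j)^2 * pj))
  if (sd_i == 0 || sd_j == 0) {
    warning("zero marginal variance; correlation defined as 0")
    return(0)
  }
  sum((g$i - mu_i) * (g$j - mu_j) * A) / (sd_i * sd_j)
}

#' GLCM energy (angular second moment)
#'
#' `sum A_ij^2`; 1 for a single occupied cell, small for diffuse textures.
#'
#' @inheritParams glcm_contrast
#' @return Scalar in `(0, 1]`.
#' @export
glcm_energy <- function(glcm) {
  A <- as_glcm_matrix(glcm)
  sum(A^2)
}

#' GLCM homogeneity (inverse difference)
#'
#' `sum A_ij / (1 + |i - j|)`; 1 when all mass is on the diagonal.
#'
#' @inheritParams glcm_contrast
#' @return Scalar in `(0, 1]`.
#' @export
glcm_homogeneity <- function(glcm) {
  A <- as_glcm_matrix(glcm)
  g <- glcm_index_grids(A)
  sum(A / (1 + abs(g$i - g$j)))
}
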