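#' First-order intensity statistics
#'
#' Population variance and standard deviation of the pixel intensities:
#' `Var = (1/n) sum (X_i - mu)^2`, `Std = sqrt(Var)`.
#'
#' @param img A [radiograph] or numeric matrix.
#' @return A non-negative scalar.
#' @export
intensity_variance <- function(img) {
  px <- as_pixels(img)
  if (length(px) < 1L) stop("empty image", call. = FALSE)
  mu <- mean(px)
  mean((px - mu)^2)
}

#' @rdname intensity_variance
#' @export
intensity_std <- function(img) sqrt(intensity_variance(img))

#' Histogram skewness of pixel intensities
#'
#' Asymmetry of the gray-value distribution, computed over the gray-level
#' histogram: `sum_s (GL_s - mu)^3 count_s / ((N - 1) sigma^3)` with `N` the
#' pixel count and `sigma` the population standard deviation. Negative for
#' distributions with a heavy low tail, positive for a heavy high tail; a
#' constant image (sigma = 0) is defined as 0 with a warning.
#'
#' The denominator is configurable: `"n1"` (the default, `(N-1) sigma^3`,
#' which keeps the statistic scale-free) or `"n1cubed"` (`(N-1)^3 sigma^3`).
#'
#' @param img A [radiograph] or numeric matrix.
#' @param denominator `"n1"` or `"n1cubed"`.
#' @return A dimensionless scalar.
#' @export
intensity_skewness <- function(img, denominator = c("n1", "n1cubed")) {
  denominator <- match.arg(denominator)
  px <- as_pixels(img)
  n <- length(px)
  if (n < 2L) stop("skewness needs at least 2 pixels", call. = FALSE)
  sigma <- intensity_std(px)
  if (sigma == 0) {
    warning("constant image: skewness defined as 0")
    return(0)
  }
  tab <- table(px)
  gl <- as.numeric(names(tab))
  cnt <- as.numeric(tab)
  mu <- mean(px)
  num <- sum((gl - mu)^3 * cnt)
  den <- switch(denominator,
                n1 = (n - 1) * sigma^3,
                n1cubed = (n - 1)^3 * sigma^3)
  num / den
}

#' Shannon entropy of the gray-value histogram
#'
#' `E(X) = -sum_y p(y) log2 p(y)` over the gray values present, with
#' `p(y) = k_y / n` the relative frequency of value `y` (rounded to the
#' nearest integer). With `protocol = TRUE` (the pipeline default) the image
#' is first resized to `resize_to x resize_to` pixels (bilinear, rounded to
#' integers) and rotated by `rotate_deg` degrees with nearest-neighbor
#' sampling; the padding introduced by the rotation carries no image content
#' and is excluded from the histogram. With `protocol = FALSE` the histogram
#' is taken over the raw pixels, which gives closed-form values on simple
#' fixtures.
#'
#' @param img A [radiograph] or numeric matrix.
#' @param protocol Apply the resize-and-rotate protocol (default `TRUE`).
#' @param resize_to Side length of the resized image (default 70).
#' @param rotate_deg Rotation angle in degrees (default 35).
#' @return Entropy in bits, in `[0, 8]` for 8-bit data.
#' @export
shannon_entropy <- function(img, protocol = TRUE, resize_to = 70,
                            rotate_deg = 35) {
  vals <- entropy_pixel_set(img, protocol, resize_to, rotate_deg)
  p <- tabulate(match(vals, unique(vals)))
  p <- p / sum(p)
  -sum(p * log2(p))
}

# The pixel multiset over which the entropy histogram (and the sigma used by
# the weighted entropy) is taken.
entropy_pixel_set <- function(img, protocol, resize_to, rotate_deg) {
  px <- as_pixels(img)
  if (length(px) < 1L) stop("empty image", call. = FALSE)
  if (protocol) {
    px <- round(resize_bilinear(px, resize_to, resize_to))
    px <- rotate_nn(px, rotate_deg)
    as.vector(px[!is.na(px)])
  } else {
    as.vector(round(px))
  }
}

#' Standard-deviation-weighted entropy
#'
#' `D(X) = E(X) * sigma(X)`, the Shannon entropy scaled by the standard
#' deviation of the same pixel set, so that homogeneous-but-dispersed and
#' heterogeneous-but-tight textures score differently.
#'
#' @inheritParams shannon_entropy
#' @return Scalar in bits times intensity units.
#' @export
weighted_entropy <- function(img, protocol = TRUE, resize_to = 70,
                             rotate_deg = 35) {
  vals <- entropy_pixel_set(img, protocol, resize_to, rotate_deg)
  p <- tabulate(match(vals, unique(vals)))
  p <- p / sum(p)
  ent <- -sum(p * log2(p))
  n <- length(vals)
  sigma <- if (n < 2L) 0 else stats::sd(vals) * sqrt((n - 1) / n)
  ent * sigma
}

#' Entropy product feature
#'
#' `E(X) * D(X) = E(X)^2 * sigma(X)`, the scalar entered in the feature
#' vector alongside the four co-occurrence statistics.
#'
#' @inheritParams shannon_entropy
#' @return Non-negative scalar.
#' @export
entropy_product <- function(img, protocol = TRUE, resize_to = 70,
                            rotate_deg = 35) {
  shannon_entropy(img, protocol, resize_to, rotate_deg) *
    weighted_entropy(img, protocol, resize_to, rotate_deg)
}
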