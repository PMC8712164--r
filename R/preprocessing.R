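#' 3x3 median filter
#'
#' Replaces every pixel by the median of its 3x3 neighborhood, the standard
#' first step for removing impulse ("salt") noise from radiographs while
#' preserving edges. Borders are handled by edge replication.
#'
#' @param img A [radiograph] or numeric matrix.
#' @return The filtered image, same type and shape as the input.
#' @export
median_filter_3x3 <- function(img) {
  px <- as_pixels(img)
  if (nrow(px) < 3L || ncol(px) < 3L)
    stop("median_filter_3x3 requires an image of at least 3 x 3 pixels",
         call. = FALSE)
  rewrap(stack_median(shift_stack_3x3(px)), img)
}

#' Unsharp-mask sharpening
#'
#' Sharpens by adding back a scaled high-pass residual:
#' `out = clip(img + amount * (img - blur(img, sigma)), 0, 255)`.
#' With `amount = 0` the image is returned unchanged.
#'
#' @param img A [radiograph] or numeric matrix.
#' @param amount Non-negative strength of the high-pass boost (default 1).
#' @param sigma Standard deviation, in pixels, of the Gaussian blur that
#'   defines the low-pass reference (default 1).
#' @return The sharpened image, clipped to `[0, 255]`.
#' @export
sharpen <- function(img, amount = 1, sigma = 1) {
  if (!is.numeric(amount) || length(amount) != 1L || amount < 0)
    stop("`amount` must be a single non-negative number", call. = FALSE)
  px <- as_pixels(img)
  if (amount == 0) return(rewrap(px, img))
  rewrap(clip255(px + amount * (px - gaussian_blur(px, sigma))), img)
}

#' Standard preprocessing: median denoise then sharpen
#'
#' @param img A [radiograph] or numeric matrix.
#' @param median Apply the 3x3 median filter first (default `TRUE`).
#' @param amount,sigma Passed to [sharpen()]; `amount = 0` disables
#'   sharpening.
#' @return The preprocessed image.
#' @export
preprocess <- function(img, median = TRUE, amount = 1, sigma = 1) {
  out <- if (median) median_filter_3x3(img) else img
  sharpen(out, amount = amount, sigma = sigma)
}
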