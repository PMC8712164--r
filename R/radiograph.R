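#' Radiograph image container
#'
#' A `radiograph` is a plain list holding a 2-D matrix of gray intensities on
#' the 8-bit scale (0--255, stored as doubles so filters can work in real
#' arithmetic), an optional class label, and a source identifier.
#'
#' @param pixels Numeric matrix of intensities in `[0, 255]`.
#' @param label Optional class tag, one of `"cancerous"`, `"healthy"` or `NA`.
#' @param source_id Character identifier for provenance (file path, phantom
#'   id, ...).
#' @return An object of class `radiograph` with elements `pixels`, `label`
#'   and `source_id`.
#' @examples
#' img <- radiograph(matrix(128, 4, 4))
#' dim(img$pixels)
#' @export
radiograph <- function(pixels, label = NA_character_, source_id = "memory") {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  if (nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop("image has zero area", call. = FALSE)
  if (anyNA(pixels))
    stop("image contains missing values", call. = FALSE)
  if (min(pixels) < 0 || max(pixels) > 255)
    stop("intensities must lie within [0, 255]", call. = FALSE)
  if (!is.na(label) && !label %in% c("cancerous", "healthy"))
    stop("label must be 'cancerous', 'healthy' or NA", call. = FALSE)
  structure(
    list(pixels = unname(pixels * 1.0), label = label,
         source_id = as.character(source_id)),
    class = "radiograph")
}

#' @export
print.radiograph <- function(x, ...) {
  cat(sprintf("<radiograph> %d x %d px, label: %s, source: %s\n",
              nrow(x$pixels), ncol(x$pixels),
              ifelse(is.na(x$label), "<none>", x$label), x$source_id))
  invisible(x)
}

#' @export
dim.radiograph <- function(x) dim(x$pixels)

# Accepts either a radiograph or a bare matrix; returns the pixel matrix.
as_pixels <- function(img) {
  if (inherits(img, "radiograph")) return(img$pixels)
  if (is.matrix(img) && is.numeric(img)) return(img)
  stop("expected a radiograph or a numeric matrix", call. = FALSE)
}

# Rewrap a pixel matrix, carrying over metadata from a template radiograph.
rewrap <- function(pixels, template) {
  if (inherits(template, "radiograph")) {
    out <- template
    out$pixels <- pixels
    out
  } else {
    pixels
  }
}

#' Load a radiograph from PNG, TIFF or JPEG
#'
#' Reads an image file and converts it to a single-channel 8-bit-scale
#' radiograph. RGB(A) images are converted to luminance with the ITU-R 601
#' weights (0.299, 0.587, 0.114); the readers return intensities in `[0, 1]`
#' regardless of bit depth, so both 8- and 16-bit sources are mapped linearly
#' onto `[0, 255]` (a 16-bit value of 65535 becomes 255).
#'
#' @param path Path to a `.png`, `.tif(f)`, `.jpg` or `.jpeg` file.
#' @param label Optional class label to attach.
#' @return A [radiograph].
#' @export
load_image <- function(path, label = NA_character_) {
  if (!file.exists(path))
    stop(sprintf("cannot read image: '%s' does not exist", path), call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    jpg  = ,
    jpeg = jpeg::readJPEG(path),
    stop(sprintf("unsupported image format '.%s' for '%s'", ext, path),
         call. = FALSE))
  px <- to_gray01(arr) * 255
  radiograph(px, label = label, source_id = path)
}

# Collapse an array as returned by readPNG/readTIFF/readJPEG to a single
# [0,1] channel. Alpha (4th channel) is ignored.
to_gray01 <- function(arr) {
  if (length(dim(arr)) == 2L) return(arr)
  if (length(dim(arr)) == 3L) {
    nc <- dim(arr)[3]
    if (nc == 1L) return(arr[, , 1L])
    if (nc %in% c(2L, 4L)) arr <- arr[, , seq_len(nc - 1L), drop = FALSE]
    if (dim(arr)[3] == 1L) return(arr[, , 1L])
    return(0.299 * arr[, , 1L] + 0.587 * arr[, , 2L] + 0.114 * arr[, , 3L])
  }
  stop("unsupported image array layout", call. = FALSE)
}

#' Write a radiograph as an 8-bit grayscale PNG
#'
#' @param img A [radiograph] or numeric matrix in `[0, 255]`.
#' @param path Output path ending in `.png`.
#' @return The path, invisibly.
#' @export
save_image <- function(img, path) {
  px <- as_pixels(img)
  png::writePNG(pmin(pmax(round(px) / 255, 0), 1), target = path)
  invisible(path)
}
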