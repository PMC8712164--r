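#' Pipeline configuration
#'
#' Collects every tunable parameter of the feature pipeline in one list, so
#' that a run is fully described by (images, config, seed). Defaults follow
#' conventional texture-analysis practice where a parameter is not pinned by
#' the method itself.
#'
#' @param median Apply the 3x3 median filter during preprocessing.
#' @param sharpen_amount,sharpen_sigma Unsharp-mask parameters
#'   ([sharpen()]); `sharpen_amount = 0` disables sharpening.
#' @param edge_method Edge detector for segmentation: `"canny"`, `"sobel"`
#'   or `"prewitt"`.
#' @param canny_sigma,canny_low,canny_high Canny parameters
#'   ([detect_edges()]).
#' @param edge_threshold Gradient-fraction threshold for Sobel/Prewitt.
#' @param use_roi Crop to the largest-edge-component bounding box before
#'   feature extraction; when no edges are found the full image is used with
#'   a warning.
#' @param glcm_levels,glcm_distance,glcm_angles,glcm_symmetric GLCM
#'   parameters ([compute_glcm()]).
#' @param entropy_protocol,entropy_resize,entropy_rotate Entropy protocol
#'   ([shannon_entropy()]).
#' @param skewness_denominator `"n1"` or `"n1cubed"`
#'   ([intensity_skewness()]).
#' @param hough_theta_bins,hough_rho_resolution,gini_include_zeros,
#'   gini_per_theta Hough-Gini parameters ([hough_gini_feature()]).
#' @param hog_resize,hog_cell,hog_bins HOG parameters ([compute_hog()]).
#' @return A named list of class `otex_config`.
#' @export
otex_config <- function(median = TRUE, sharpen_amount = 1, sharpen_sigma = 1,
                        edge_method = "canny", canny_sigma = 1,
                        canny_low = 0.1, canny_high = 0.2,
                        edge_threshold = 0.25, use_roi = TRUE,
                        glcm_levels = 64L, glcm_distance = 1L,
                        glcm_angles = c(0, 45, 90, 135),
                        glcm_symmetric = TRUE,
                        entropy_protocol = TRUE, entropy_resize = 70,
                        entropy_rotate = 35,
                        skewness_denominator = "n1",
                        hough_theta_bins = 180L, hough_rho_resolution = 1,
                        gini_include_zeros = TRUE, gini_per_theta = FALSE,
                        hog_resize = 25L, hog_cell = 3L, hog_bins = 6L) {
  cfg <- as.list(environment())
  class(cfg) <- "otex_config"
  cfg
}

#' Names of the eight scalar texture features, in canonical order
#' @export
FEATURE_NAMES <- c("entropy", "energy", "gini", "skewness", "contrast",
                   "correlation", "homogeneity", "entropy_product")

#' Extract the texture feature vector from one radiograph
#'
#' Runs the full pipeline: preprocessing (median filter + unsharp mask),
#' edge detection, ROI crop to the largest edge component (optional), then
#' the eight scalar texture features and, with `with_hog = TRUE`, the
#' 384-long HOG block. On degenerate inputs with an empty edge map the
#' features are computed on the full image and the Hough-Gini feature,
#' which is undefined without edges, falls back to 0 with a warning.
#'
#' @param img A [radiograph] or numeric matrix.
#' @param with_hog Append the HOG block (default `TRUE`).
#' @param config An [otex_config()].
#' @return Named numeric vector: the eight scalars in the order of
#'   [FEATURE_NAMES], then `hog_1 ... hog_384` when requested.
#' @export
extract_features <- function(img, with_hog = TRUE, config = otex_config()) {
  cfg <- config
  pre <- preprocess(img, median = cfg$median, amount = cfg$sharpen_amount,
                    sigma = cfg$sharpen_sigma)
  edges <- detect_edges(pre, method = cfg$edge_method,
                        sigma = cfg$canny_sigma, low = cfg$canny_low,
                        high = cfg$canny_high,
                        threshold = cfg$edge_threshold)
  have_edges <- any(edges$mask)
  region <- pre
  edge_region <- edges
  if (!have_edges) {
    warning("no edges found; computing features on the full image")
  } else if (cfg$use_roi) {
    box <- extract_roi(edges)
    region <- crop(pre, box)
    edge_region <- edges
    edge_region$mask <- edges$mask[(box$row_min + 1L):box$row_max,
                                   (box$col_min + 1L):box$col_max,
                                   drop = FALSE]
  }

  glcm <- compute_glcm(region, levels = cfg$glcm_levels,
                       distance = cfg$glcm_distance,
                       angles = cfg$glcm_angles,
                       symmetric = cfg$glcm_symmetric)
  ent <- shannon_entropy(region, protocol = cfg$entropy_protocol,
                         resize_to = cfg$entropy_resize,
                         rotate_deg = cfg$entropy_rotate)
  went <- weighted_entropy(region, protocol = cfg$entropy_protocol,
                           resize_to = cfg$entropy_resize,
                           rotate_deg = cfg$entropy_rotate)
  gini <- if (have_edges && any(edge_region$mask)) {
    hough_gini_feature(edge_region, theta_bins = cfg$hough_theta_bins,
                       rho_resolution = cfg$hough_rho_resolution,
                       include_zeros = cfg$gini_include_zeros,
                       per_theta = cfg$gini_per_theta)
  } else {
    if (have_edges) warning("ROI contains no edges; gini feature set to 0")
    0
  }
  scalars <- c(
    entropy = ent,
    energy = glcm_energy(glcm),
    gini = gini,
    skewness = suppressWarnings(
      intensity_skewness(region, denominator = cfg$skewness_denominator)),
    contrast = glcm_contrast(glcm),
    correlation = suppressWarnings(glcm_correlation(glcm)),
    homogeneity = glcm_homogeneity(glcm),
    entropy_product = ent * went)
  if (!with_hog) return(scalars)
  hog <- compute_hog(region, resize_to = cfg$hog_resize,
                     cell_size = cfg$hog_cell, bins = cfg$hog_bins)
  hv <- hog$vector
  names(hv) <- paste0("hog_", seq_along(hv))
  c(scalars, hv)
}

#' Extract a feature table from a set of radiographs
#'
#' @param imgs List of [radiograph] objects (or matrices).
#' @param with_hog Include the HOG block.
#' @param config An [otex_config()].
#' @return A data.frame with one row per image: `id`, `label`, the eight
#'   scalar features and (optionally) the HOG columns.
#' @export
extract_feature_table <- function(imgs, with_hog = TRUE,
                                  config = otex_config()) {
  stopifnot(length(imgs) >= 1L)
  rows <- lapply(seq_along(imgs), function(i) {
    img <- imgs[[i]]
    f <- extract_features(img, with_hog = with_hog, config = config)
    id <- if (inherits(img, "radiograph")) img$source_id else sprintf("img%03d", i)
    lab <- if (inherits(img, "radiograph")) img$label else NA_character_
    cbind(data.frame(id = id, label = lab, stringsAsFactors = FALSE),
          as.data.frame(as.list(f)))
  })
  do.call(rbind, rows)
}

#' Write a feature table to CSV
#'
#' Plain `write.csv` with full double precision (15 significant digits) and
#' no row names, so that identical runs produce byte-identical files.
#'
#' @param features Data.frame from [extract_feature_table()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_features_csv <- function(features, path) {
  num <- vapply(features, is.numeric, TRUE)
  out <- features
  out[num] <- lapply(out[num], function(x) sprintf("%.15g", x))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
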