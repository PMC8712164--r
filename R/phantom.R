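#' Specification of a synthetic bone phantom
#'
#' Describes one synthetic long-bone radiograph: a bright vertical shaft
#' with rounded ends (a capsule) and regular trabecular banding over a dark
#' background, plus Gaussian sensor noise. Cancerous phantoms additionally
#' carry an elliptical lytic lesion centred in the shaft whose boundary is
#' perturbed by radial noise (`lesion_raggedness`) and whose interior is
#' drawn from a few dominant gray levels well below the bone level -- a
#' region whose pixel values are widely scattered (high variance) yet
#' concentrated on few levels (low entropy), the texture contrast the
#' classifier is meant to pick up.
#'
#' @param label `"cancerous"` or `"healthy"`.
#' @param image_size Side length in pixels (default 256).
#' @param shaft_width Caliber of the imaged bone in pixels (default 90);
#'   the film is a zoomed crop filled by trabecular bone, and this value
#'   scales the lesion size.
#' @param background_level Marrow/soft-tissue intensity floor that a
#'   lucent region can reach (default 30).
#' @param bone_level Mean trabecular bone intensity (default 180).
#' @param banding_amplitude Amplitude of the trabecular banding texture
#'   inside the bone (default 12 intensity units).
#' @param banding_period Banding period in pixels (default 11).
#' @param texture_sd Standard deviation of the smooth (spatially
#'   correlated) trabecular texture field inside the bone (default 7);
#'   this is what gives healthy bone its rich, high-entropy texture.
#' @param lesion_raggedness Radial perturbation of the lesion boundary in
#'   `[0, 1]` (default 0.5).
#' @param lesion_gray_levels Number of dominant gray levels filling the
#'   lesion (default 3); fewer levels mean lower in-lesion entropy.
#' @param lesion_grain Side length, in pixels, of the patches on which
#'   lesion gray levels are drawn (default 3). Patch-scale mottling
#'   survives median filtering, unlike single-pixel salt noise.
#' @param lesion_contrast Intensity drop from `bone_level` to the darkest
#'   lesion level (default 80).
#' @param lesion_speckle_sd Within-level speckle standard deviation
#'   (default 1).
#' @param lesion_scale Lesion semi-axes as a fraction of their default size
#'   (default 1).
#' @param lesion_style `"mottled"` (default): the interior is rebuilt
#'   entirely from a few dominant gray levels -- a purely texture-driven
#'   presentation. `"lucent"`: the interior is darkened uniformly with a
#'   sharp step at the (typically ragged) margin, and a mottled component
#'   is blended in at fraction `lesion_blend` -- the presentation whose
#'   first-order statistics resemble a benign lucency, so that margin
#'   shape carries most of the class information.
#' @param lesion_blend For `"lucent"` lesions: fraction in `[0, 1]` of the
#'   few-level mottled component blended into the darkened interior
#'   (default 0.35). Controls how far in-lesion entropy drops below the
#'   healthy trabecular texture.
#' @param benign_contrast Depth of the benign lucent region drawn in
#'   healthy phantoms (default 25; 0 disables it). Healthy bone frequently
#'   shows benign lucencies (cysts, fibrous dysplasia) that are mottled
#'   like a tumour but have a smooth, well-defined margin and retain more
#'   gray-level diversity -- radiologically, margin definition is the key
#'   malignant/benign discriminator. Drawing one keeps the two classes
#'   morphologically similar so classification must rely on margin shape
#'   and texture statistics, not the mere presence of a dark region.
#' @param illumination_amp Peak-to-peak amplitude of a smooth linear
#'   illumination ramp across the field of view (default 0); emulates the
#'   anode heel effect and non-uniform exposure. A ramp of a few tens of
#'   gray levels visibly shifts histogram-based statistics while adding a
#'   negligible per-pixel gradient.
#' @param noise_sd Sensor noise standard deviation (default 2).
#' @param gain Global exposure gain applied multiplicatively to the whole
#'   image (default 1); emulates acquisition-to-acquisition exposure
#'   differences between sources.
#' @param gamma Tone-curve exponent applied on the normalized `[0, 1]`
#'   scale (default 1); emulates detector/display response differences.
#' @param seed Integer seed; identical spec (including seed) gives a
#'   bit-identical image.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(label = c("cancerous", "healthy"),
                         image_size = 256L, shaft_width = 90,
                         background_level = 30, bone_level = 180,
                         banding_amplitude = 12, banding_period = 11,
                         texture_sd = 7,
                         lesion_raggedness = 0.5, lesion_gray_levels = 3L,
                         lesion_grain = 3L,
                         lesion_contrast = 80, lesion_speckle_sd = 1,
                         lesion_scale = 1,
                         lesion_style = c("mottled", "lucent"),
                         lesion_blend = 0.35,
                         benign_contrast = 25,
                         illumination_amp = 0,
                         noise_sd = 2, gain = 1, gamma = 1, seed = 42L) {
  label <- match.arg(label)
  lesion_style <- match.arg(lesion_style)
  spec <- as.list(environment())
  lv <- c(background_level, bone_level)
  if (any(lv < 0 | lv > 255))
    stop("intensity levels must lie in [0, 255]", call. = FALSE)
  if (lesion_raggedness < 0 || lesion_raggedness > 1)
    stop("`lesion_raggedness` must lie in [0, 1]", call. = FALSE)
  if (image_size < 32L) stop("`image_size` must be >= 32", call. = FALSE)
  if (lesion_gray_levels < 1L)
    stop("`lesion_gray_levels` must be >= 1", call. = FALSE)
  if (noise_sd < 0 || lesion_speckle_sd < 0)
    stop("noise standard deviations must be >= 0", call. = FALSE)
  class(spec) <- "phantom_spec"
  spec
}

#' Generate one synthetic bone phantom
#'
#' @param spec A [phantom_spec()].
#' @return A [radiograph] with integer-rounded pixels; the element
#'   `lesion_mask` marks the lesion region (for healthy phantoms, the
#'   region where a lesion would sit, enabling region-matched comparisons)
#'   and `spec` stores the generating spec.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  n <- spec$image_size
  rad <- spec$shaft_width / 2
  cx <- (n + 1) / 2
  rr <- matrix(seq_len(n), n, n)
  cc <- matrix(seq_len(n), n, n, byrow = TRUE)

  # zoomed diaphysis film: trabecular bone fills the frame, the way
  # pre-cropped bone-radiograph datasets are framed; regular banding plus a
  # spatially correlated texture field give healthy bone its rich,
  # many-valued texture
  band <- spec$banding_amplitude *
    (0.7 * sin(2 * pi * rr / spec$banding_period) +
     0.3 * sin(2 * pi * cc / (2.1 * spec$banding_period)))
  trab <- if (spec$texture_sd > 0) {
    field <- gaussian_blur(matrix(stats::rnorm(n * n), n, n), 2)
    field / stats::sd(field) * spec$texture_sd
  } else 0
  img <- spec$bone_level + band + trab

  # lesion geometry (used by both classes: malignant lesion or benign
  # lucency); sized relative to the visible bone caliber (shaft_width)
  a_col <- 0.8 * rad * spec$lesion_scale
  a_row <- min(2 * a_col, 0.3 * n)
  cy_les <- (n + 1) / 2
  phi <- atan2(rr - cy_les, cc - cx)
  u <- sqrt(((rr - cy_les) / a_row)^2 + ((cc - cx) / a_col)^2)
  harm <- 2:6
  coef_a <- stats::rnorm(length(harm)) / harm
  coef_b <- stats::rnorm(length(harm)) / harm
  ragged_field <- 0.45 * Reduce(`+`, lapply(seq_along(harm), function(k)
    coef_a[k] * cos(harm[k] * phi) + coef_b[k] * sin(harm[k] * phi)))

  # mottled fill: one gray level per grain x grain patch, plus speckle
  mottle <- function(mask, lv, w) {
    gs <- max(1L, as.integer(spec$lesion_grain))
    ncell <- ceiling(n / gs)
    cell_lv <- matrix(lv[sample.int(length(lv), ncell * ncell,
                                    replace = TRUE, prob = w)],
                      ncell, ncell)
    patch <- cell_lv[cbind((rr[mask] - 1L) %/% gs + 1L,
                           (cc[mask] - 1L) %/% gs + 1L)]
    patch + stats::rnorm(sum(mask), sd = spec$lesion_speckle_sd)
  }

  if (spec$label == "cancerous") {
    # malignant: ragged ("moth-eaten") margin
    lesion_mask <- u < 1 + spec$lesion_raggedness * ragged_field
    if (spec$lesion_style == "mottled") {
      # texture-dominant: interior rebuilt from few dominant dark levels
      nl <- spec$lesion_gray_levels
      lv <- if (nl == 1L) spec$bone_level - spec$lesion_contrast
            else seq(spec$bone_level - spec$lesion_contrast, spec$bone_level,
                     length.out = nl)
      w <- 2^-(seq_len(nl) - 1)        # darkest level dominates
      img[lesion_mask] <- mottle(lesion_mask, lv, w / sum(w))
    } else {
      # margin-dominant: uniform darkening with a sharp step along the
      # ragged margin, plus a partial few-level mottled component that
      # nudges the first-order statistics (lower entropy, more scatter)
      # without dominating them
      base <- pmax(img[lesion_mask] - spec$lesion_contrast,
                   spec$background_level)
      f <- min(max(spec$lesion_blend, 0), 1)
      if (f > 0) {
        ctr <- spec$bone_level - spec$lesion_contrast
        lv <- pmax(ctr + c(-0.45, 0, 0.45) * spec$lesion_contrast,
                   spec$background_level)
        w <- c(0.5, 0.3, 0.2)
        img[lesion_mask] <- (1 - f) * base + f * mottle(lesion_mask, lv, w)
      } else {
        img[lesion_mask] <- base
      }
    }
  } else {
    # benign lucency: same sharp-stepped lucent region as the
    # margin-dominant malignant presentation, but with a smooth,
    # well-defined margin; the trabecular texture shows through, so the
    # region keeps its gray-level diversity (high entropy)
    lesion_mask <- u < 1 + 0.1 * ragged_field
    if (spec$benign_contrast > 0)
      img[lesion_mask] <- pmax(img[lesion_mask] - spec$benign_contrast,
                               spec$background_level)
  }

  if (spec$illumination_amp > 0) {
    dir_th <- stats::runif(1, 0, 2 * pi)
    ramp <- (cos(dir_th) * (cc - cx) + sin(dir_th) * (rr - (n + 1) / 2)) / n
    img <- img + spec$illumination_amp * ramp
  }
  img <- spec$gain * img
  if (spec$gamma != 1) img <- 255 * (clip255(img) / 255)^spec$gamma
  img <- img + stats::rnorm(n * n, sd = spec$noise_sd)
  out <- radiograph(round(clip255(img)), label = spec$label,
                    source_id = sprintf("phantom-%s-seed%d", spec$label,
                                        spec$seed))
  out$lesion_mask <- lesion_mask
  out$spec <- spec
  out
}

# Multipliers applied to the class-separating lesion parameters.
effect_multiplier <- function(effect_size) {
  if (is.numeric(effect_size)) return(effect_size)
  switch(match.arg(effect_size, c("low", "default", "high")),
         low = 0.5, default = 1, high = 2)
}

#' Generate a labelled phantom dataset
#'
#' Produces `n_cancerous + n_healthy` phantoms with per-image seeds derived
#' from the master seed and realistic per-image nuisance variation (bone
#' and background levels, shaft width, banding, lesion size and contrast
#' jittered image to image), plus a manifest recording every draw. The
#' `effect_size` dial scales the lesion contrast and raggedness: `"low"`
#' (0.5x), `"default"` (1x) or `"high"` (2x), or any positive number.
#'
#' @param n_cancerous,n_healthy Class counts (default 65 and 40).
#' @param spec_overrides Named list of [phantom_spec()] arguments applied to
#'   every image (after nuisance jitter).
#' @param seed Master integer seed.
#' @param effect_size `"low"`, `"default"`, `"high"` or a positive number.
#' @return List with `images` (list of [radiograph]s) and `manifest`
#'   (data.frame: id, label, seed and the jittered parameters).
#' @export
generate_dataset <- function(n_cancerous = 65L, n_healthy = 40L,
                             spec_overrides = list(), seed = 42L,
                             effect_size = "default") {
  stopifnot(n_cancerous >= 1L, n_healthy >= 1L)
  eff <- effect_multiplier(effect_size)
  labels <- c(rep("cancerous", n_cancerous), rep("healthy", n_healthy))
  n_total <- length(labels)
  images <- vector("list", n_total)
  rows <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    seed_i <- (as.numeric(seed) * 2003 + 2 * i) %% 2147483647
    set.seed(seed_i + 1)               # nuisance-parameter stream
    # malignant lesions present as partially mottled lucencies whose
    # ragged "moth-eaten" margin is the dominant cue; their depth
    # distribution matches the benign lucencies, so classification rests
    # on margin shape plus the milder texture-statistic shifts
    args <- list(
      lesion_style = "lucent",
      lesion_blend = pmin(1, 0.35 * eff),
      label = labels[i],
      bone_level = 180 + stats::runif(1, -38, 33),
      background_level = stats::runif(1, 15, 58),
      shaft_width = 90 + stats::runif(1, -15, 15),
      banding_amplitude = 12 * stats::runif(1, 0.4, 1.6),
      banding_period = 11 * stats::runif(1, 0.8, 1.25),
      lesion_contrast = pmin(150, eff * stats::runif(1, 30, 70)),
      lesion_raggedness = pmin(1, eff * stats::runif(1, 0.8, 1)),
      lesion_scale = stats::runif(1, 0.95, 1.25),
      benign_contrast = stats::runif(1, 30, 70),
      illumination_amp = stats::runif(1, 10, 45),
      texture_sd = stats::runif(1, 5, 10),
      noise_sd = stats::runif(1, 1, 2.5),
      gain = stats::runif(1, 0.8, 1.2),
      gamma = stats::runif(1, 0.6, 1.5),
      seed = as.integer(seed_i))
    args[names(spec_overrides)] <- spec_overrides
    sp <- do.call(phantom_spec, args)
    images[[i]] <- generate_phantom(sp)
    images[[i]]$source_id <- sprintf("phantom-%03d", i)
    rows[[i]] <- data.frame(
      id = images[[i]]$source_id, label = labels[i], seed = as.integer(seed_i),
      bone_level = args$bone_level, background_level = args$background_level,
      shaft_width = args$shaft_width, lesion_contrast = args$lesion_contrast,
      lesion_raggedness = args$lesion_raggedness,
      lesion_scale = args$lesion_scale, stringsAsFactors = FALSE)
  }
  list(images = images, manifest = do.call(rbind, rows))
}
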