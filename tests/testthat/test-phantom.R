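test_that("phantom generation is bit-identical for identical specs", {
  s <- phantom_spec("cancerous", seed = 42)
  p1 <- generate_phantom(s)
  p2 <- generate_phantom(s)
  expect_identical(p1$pixels, p2$pixels)
  expect_identical(p1$lesion_mask, p2$lesion_mask)
  p3 <- generate_phantom(phantom_spec("cancerous", seed = 43))
  expect_false(identical(p1$pixels, p3$pixels))
})

test_that("pixels stay within [0, 255] for extreme settings", {
  for (seed in 1:4) {
    p <- generate_phantom(phantom_spec("cancerous", seed = seed,
                                       bone_level = 250, noise_sd = 30,
                                       lesion_contrast = 150, gain = 1.3))
    expect_gte(min(p$pixels), 0)
    expect_lte(max(p$pixels), 255)
  }
})

test_that("degenerate settings give a constant mottle-free lesion", {
  p <- generate_phantom(phantom_spec(
    "cancerous", seed = 1, lesion_raggedness = 0, lesion_speckle_sd = 0,
    lesion_gray_levels = 1, noise_sd = 0, texture_sd = 0,
    banding_amplitude = 0))
  inside <- p$pixels[p$lesion_mask]
  expect_equal(length(unique(inside)), 1)
  expect_equal(unique(inside), 180 - 80)   # bone_level - lesion_contrast
  # the margin is a pure ellipse when raggedness is 0
  expect_true(sum(p$lesion_mask) > 0)
})

test_that("invalid specs are rejected", {
  expect_error(phantom_spec(bone_level = 300), "0, 255")
  expect_error(phantom_spec(lesion_raggedness = 2), "raggedness")
  expect_error(phantom_spec(lesion_gray_levels = 0), "gray_levels")
  expect_error(phantom_spec(noise_sd = -1), "deviations")
})

test_that("datasets have the requested composition and reproducibility", {
  d1 <- generate_dataset(6, 4, seed = 42)
  expect_length(d1$images, 10)
  expect_equal(sum(d1$manifest$label == "cancerous"), 6)
  expect_equal(nrow(d1$manifest), 10)
  d2 <- generate_dataset(6, 4, seed = 42)
  expect_identical(d1$manifest, d2$manifest)
  expect_identical(d1$images[[7]]$pixels, d2$images[[7]]$pixels)
  d3 <- generate_dataset(6, 4, seed = 43)
  expect_false(identical(d1$images[[1]]$pixels, d3$images[[1]]$pixels))
})

test_that("class-conditional feature directions match the domain claims", {
  # region-matched one-sided comparisons over 50 phantoms per class at the
  # generator's default effect size: lesions have lower in-region entropy,
  # and cancerous images have lower skewness
  ds <- generate_dataset(50, 50, seed = 77)
  ec <- eh <- sc <- sh <- numeric(50)
  for (i in 1:50) {
    pc <- ds$images[[i]]
    ph <- ds$images[[50 + i]]
    ec[i] <- shannon_entropy(matrix(pc$pixels[pc$lesion_mask], ncol = 1),
                             protocol = FALSE)
    eh[i] <- shannon_entropy(matrix(ph$pixels[ph$lesion_mask], ncol = 1),
                             protocol = FALSE)
    sc[i] <- suppressWarnings(intensity_skewness(preprocess(pc)))
    sh[i] <- suppressWarnings(intensity_skewness(preprocess(ph)))
  }
  expect_lt(mean(ec), mean(eh))
  expect_lt(mean(sc), mean(sh))
})

test_that("at spec defaults the lesion is scattered yet low-entropy", {
  # the default single-phantom spec draws the fully mottled presentation:
  # wider intensity scatter but fewer distinct levels than healthy texture
  vc <- ec <- vh <- eh <- numeric(20)
  for (i in 1:20) {
    pc <- generate_phantom(phantom_spec("cancerous", seed = 600 + i))
    ph <- generate_phantom(phantom_spec("healthy", seed = 600 + i))
    vc[i] <- stats::var(pc$pixels[pc$lesion_mask])
    vh[i] <- stats::var(ph$pixels[ph$lesion_mask])
    ec[i] <- shannon_entropy(matrix(pc$pixels[pc$lesion_mask], ncol = 1),
                             protocol = FALSE)
    eh[i] <- shannon_entropy(matrix(ph$pixels[ph$lesion_mask], ncol = 1),
                             protocol = FALSE)
  }
  expect_gt(mean(vc), mean(vh))        # more scattered intensities
  expect_lt(mean(ec), mean(eh))        # fewer distinct gray levels
})
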