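test_that("variance and std follow the population formulas", {
  expect_equal(intensity_variance(matrix(5, 4, 4)), 0)
  expect_equal(intensity_std(matrix(5, 4, 4)), 0)
  half <- matrix(c(0, 255), 4, 4)      # equal mix of 0 and 255
  expect_equal(intensity_variance(half), 16256.25)
  expect_equal(intensity_std(half), 127.5)
  for (seed in 1:4) {
    m <- rand_img(5, 5, seed)
    mu <- mean(m)
    expect_equal(intensity_variance(m), mean((m - mu)^2))
    expect_equal(intensity_std(m)^2, intensity_variance(m))
  }
})

test_that("skewness has the right sign, symmetry and oracle value", {
  sym <- matrix(c(100, 150), 4, 4)
  expect_equal(intensity_skewness(sym), 0)
  expect_warning(s0 <- intensity_skewness(matrix(9, 3, 3)), "constant")
  expect_equal(s0, 0)
  # one bright pixel among 99 dark: positive, equal to the direct formula
  m <- matrix(0, 10, 10); m[1, 1] <- 255
  s <- intensity_skewness(m)
  n <- 100; mu <- mean(m); sig <- sqrt(mean((m - mu)^2))
  expect_equal(s, sum((m - mu)^3) / ((n - 1) * sig^3))
  expect_gt(s, 0)
  # reflecting intensities about the mean flips the sign
  m2 <- 2 * mean(m) - m
  expect_equal(intensity_skewness(matrix(m2, 10, 10)), -s)
  # alternative denominator is (N-1)^3 sigma^3
  expect_equal(intensity_skewness(m, denominator = "n1cubed"),
               s / (n - 1)^2)
})

test_that("entropy matches closed forms with the protocol disabled", {
  expect_equal(shannon_entropy(matrix(7, 5, 5), protocol = FALSE), 0)
  fair <- matrix(c(100, 150), 4, 4)
  expect_equal(shannon_entropy(fair, protocol = FALSE), 1.0)
  for (seed in 1:5) {
    m <- rand_img(8, 8, seed, max_val = 31)
    expect_equal(shannon_entropy(m, protocol = FALSE),
                 entropy_oracle(as.vector(m)), tolerance = 1e-12)
  }
})

test_that("the resize-and-rotate protocol is histogram-consistent", {
  # protocol on a constant image is still 0 bits (padding excluded)
  expect_equal(shannon_entropy(matrix(44, 30, 30)), 0)
  # protocol path equals an oracle over the same transformed pixel set
  m <- rand_img(40, 40, 6)
  vals <- osteotex:::entropy_pixel_set(m, TRUE, 70, 35)
  expect_equal(shannon_entropy(m), entropy_oracle(vals), tolerance = 1e-12)
  # entropy never exceeds 8 bits for 8-bit data
  for (seed in 7:12)
    expect_lte(shannon_entropy(rand_img(30, 30, seed)), 8)
  # invariant to permutations of pixel positions (histogram-based)
  set.seed(1)
  m <- rand_img(16, 16, 13)
  mp <- matrix(sample(m), 16, 16)
  expect_equal(shannon_entropy(m, protocol = FALSE),
               shannon_entropy(mp, protocol = FALSE))
})

test_that("weighted entropy is exactly E(X) times sigma of the same pixels", {
  expect_equal(weighted_entropy(matrix(3, 10, 10)), 0)
  fair <- matrix(c(0, 255), 4, 4)
  expect_equal(weighted_entropy(fair, protocol = FALSE), 127.5)
  expect_equal(entropy_product(fair, protocol = FALSE), 127.5)
  for (seed in 1:8) {
    m <- rand_img(12, 12, seed)
    e <- shannon_entropy(m)
    d <- weighted_entropy(m)
    if (e > 0) {
      vals <- osteotex:::entropy_pixel_set(m, TRUE, 70, 35)
      sig <- sqrt(mean((vals - mean(vals))^2))
      expect_equal(d / e, sig, tolerance = 1e-10)
    }
    expect_equal(entropy_product(m), e * d, tolerance = 1e-10)
  }
})
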