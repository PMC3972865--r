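test_that("quantization maps ranges linearly onto 0..G-1", {
  expect_true(all(quantize(matrix(3.7, 6, 6), 8) == 0))
  two <- quantize(matrix(c(0, 255, 255, 0), 2, 2), 2)
  expect_equal(sort(unique(as.vector(two))), c(0L, 1L))
  ramp <- matrix(0:63, 8, 8)
  expect_equal(quantize(ramp, 64), matrix(0:63, 8, 8), ignore_attr = TRUE)
  expect_error(quantize(matrix(1, 4, 4), 1), class = "mttex_validation_error")
})

test_that("co-occurrence counting matches hand-enumerated pairs", {
  m <- matrix(c(0L, 1L, 0L, 1L), 2, 2)  # [[0,0],[1,1]] in row-major reading
  g0 <- compute_glcm(m, distance = 1, direction = 0, levels = 2)
  expect_equal(g0$probabilities,
               matrix(c(0.5, 0, 0, 0.5), 2, 2))
  expect_identical(g0$pair_count, 4L)   # 2 ordered pairs counted both ways
  g90 <- compute_glcm(m, distance = 1, direction = 90, levels = 2)
  expect_equal(g90$probabilities, matrix(c(0, 0.5, 0.5, 0), 2, 2))

  cst <- compute_glcm(matrix(0L, 4, 4), distance = 1, direction = 45,
                      levels = 4)
  expect_equal(cst$probabilities[1, 1], 1)
  expect_equal(sum(cst$probabilities), 1)
})

test_that("matrices are normalized, symmetric and validated", {
  set.seed(13)
  q <- matrix(sample(0:7, 100, replace = TRUE), 10, 10)
  for (th in c(0, 45, 90, 135)) {
    g <- compute_glcm(q, distance = 2, direction = th, levels = 8)
    expect_lt(abs(sum(g$probabilities) - 1), 1e-12)
    expect_identical(g$probabilities, t(g$probabilities))
    expect_true(all(g$probabilities >= 0))
  }
  asym <- compute_glcm(q, distance = 2, direction = 0, symmetric = FALSE,
                       levels = 8)
  expect_lt(abs(sum(asym$probabilities) - 1), 1e-12)
  expect_error(compute_glcm(q, distance = 10, direction = 0, levels = 8),
               class = "mttex_validation_error")
  expect_error(compute_glcm(matrix(0.5, 4, 4), 1, 0),
               class = "mttex_validation_error")
})

test_that("feature formulas agree with closed forms on simple distributions", {
  # degenerate: all mass on one diagonal cell
  P1 <- matrix(0, 4, 4); P1[1, 1] <- 1
  expect_equal(glcm_asm(P1), 1)
  expect_equal(glcm_entropy(P1), 0)
  expect_equal(glcm_idm(P1), 1)
  expect_equal(glcm_variance(P1), 0)
  expect_equal(glcm_contrast(P1), 0)

  # uniform over all cells
  G <- 8
  Pu <- matrix(1 / G^2, G, G)
  expect_equal(glcm_asm(Pu), 1 / G^2)
  expect_equal(glcm_entropy(Pu), 2 * log2(G))

  # fair coin on two off-diagonal cells
  P2 <- matrix(0, 2, 2); P2[1, 2] <- 0.5; P2[2, 1] <- 0.5
  expect_equal(glcm_entropy(P2), 1)
  expect_equal(glcm_idm(P2), 0.5)
  expect_equal(glcm_variance(P2), 0.25)  # Bernoulli(1/2) row mean

  # ASM of the hand-counted two-level example
  P3 <- matrix(c(0.5, 0, 0, 0.5), 2, 2)
  expect_equal(glcm_asm(P3), 0.5)
})

test_that("features match the brute-force oracle on random images", {
  set.seed(29)
  for (trial in 1:25) {
    q <- matrix(sample(0:7, 64, replace = TRUE), 8, 8)
    d <- sample(1:3, 1)
    th <- sample(c(0, 45, 90, 135), 1)
    g <- compute_glcm(q, distance = d, direction = th, levels = 8)
    o <- glcm_oracle(q, d, th, TRUE, 8)
    expect_equal(g$probabilities * g$pair_count, o$counts,
                 ignore_attr = TRUE)
    got <- c(asm = glcm_asm(g), entropy = glcm_entropy(g), idm = glcm_idm(g),
             variance = glcm_variance(g), contrast = glcm_contrast(g))
    expect_equal(got, features_oracle(o$P), tolerance = 1e-14)
  }
})

test_that("single-pixel checkerboard has the analytic contrast and IDM", {
  G <- 64
  cb <- generate_checkerboard(8, 1, low = 0, high = G - 1)
  q <- quantize(cb, G)
  g <- compute_glcm(q, distance = 1, direction = 0, levels = G)
  # every horizontal neighbour pair alternates between the two extreme levels
  expect_equal(glcm_contrast(g), (G - 1)^2)
  expect_equal(glcm_idm(g), 1 / (1 + (G - 1)^2))
  expect_equal(glcm_entropy(g), 1)  # two equiprobable cells
})

test_that("feature bounds hold on random and structured images", {
  set.seed(31)
  for (trial in 1:20) {
    G <- sample(c(4, 8, 16), 1)
    q <- matrix(sample(0:(G - 1), 144, replace = TRUE), 12, 12)
    f <- extract_features(q, glcm_config(levels = G, distance = 2))
    tab <- f$by_direction
    expect_true(all(tab$asm > 0 & tab$asm <= 1))
    expect_true(all(tab$idm > 0 & tab$idm <= 1))
    expect_true(all(tab$entropy >= 0 & tab$entropy <= 2 * log2(G) + 1e-12))
    expect_true(all(tab$contrast >= 0 & tab$contrast <= (G - 1)^2))
    expect_true(all(tab$variance >= 0 & tab$variance <= (G - 1)^2))
  }
})

test_that("constant image yields the degenerate feature vector", {
  f <- extract_features(matrix(4, 16, 16))
  expect_equal(unname(f$mean),
               c(1, 0, 1, 0, 0), tolerance = 1e-12)
  expect_true(all(f$by_direction$asm == 1))
  expect_true(all(f$by_direction$entropy == 0))
})

test_that("features transport exactly under quarter rotations", {
  set.seed(37)
  cfg <- glcm_config(levels = 8, distance = 2)
  for (trial in 1:20) {
    x <- matrix(sample(0:7, 15 * 11, replace = TRUE), 15, 11)
    fx <- extract_features(x, cfg)$by_direction
    fr <- extract_features(rot90ccw(x), cfg)$by_direction
    # 0 <-> 90 and 45 <-> 135 swap under a quarter turn
    expect_equal(fx[fx$direction == 0, -1], fr[fr$direction == 90, -1],
                 ignore_attr = TRUE)
    expect_equal(fx[fx$direction == 90, -1], fr[fr$direction == 0, -1],
                 ignore_attr = TRUE)
    expect_equal(fx[fx$direction == 45, -1], fr[fr$direction == 135, -1],
                 ignore_attr = TRUE)
  }
})

test_that("Gaussian blurring never increases contrast at distance 1", {
  for (s in 1:10) {
    img <- generate_fiber_image(fiber_params(height = 96, width = 96,
                                             orientation_mode = "disordered",
                                             seed = 60 + s))
    cfg <- glcm_config(distance = 1)
    c0 <- mean(extract_features(img, cfg)$by_direction$contrast)
    cb <- mean(extract_features(mttex:::gaussian_blur(img, 2), cfg)$by_direction$contrast)
    expect_lte(cb, c0)
  }
})
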