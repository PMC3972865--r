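test_that("strict 8-neighbour extrema match an exhaustive scan", {
  # degenerate cases
  none <- detect_extrema(matrix(5, 8, 8))
  expect_identical(nrow(none$maxima), 0L)
  expect_identical(nrow(none$minima), 0L)

  x <- matrix(0, 12, 12)
  x[6, 6] <- 3
  one <- detect_extrema(x)
  expect_equal(as.numeric(one$maxima[1, ]), c(6, 6, 3))
  expect_identical(nrow(one$maxima), 1L)
  expect_identical(nrow(one$minima), 0L)  # background is a plateau

  # random integer images (plateau-rich) against the brute-force oracle
  set.seed(7)
  for (trial in 1:100) {
    y <- matrix(sample(0:9, 256, replace = TRUE), 16, 16)
    got <- detect_extrema(y)
    want <- extrema_oracle(y)
    canon <- function(m) {
      m <- unname(as.matrix(m))
      m[order(m[, 1], m[, 2]), , drop = FALSE]
    }
    expect_equal(canon(got$maxima[, 1:2]), canon(want$maxima))
    expect_equal(canon(got$minima[, 1:2]), canon(want$minima))
  }

  # separable sinusoid: oracle agreement away from degenerate plateaus
  s <- outer(1:16, 1:16, function(r, c) sin(2 * pi * r / 8) * sin(2 * pi * c / 8))
  got <- detect_extrema(s)
  want <- extrema_oracle(s)
  expect_equal(nrow(got$maxima), nrow(want$maxima))
  expect_equal(nrow(got$minima), nrow(want$minima))
})

test_that("envelope interpolation passes through the data", {
  corners <- data.frame(row = c(1, 1, 32, 32), col = c(1, 32, 1, 32), value = 5)
  for (m in c("thin_plate_rbf", "triangulated_linear")) {
    env <- interpolate_envelope(corners, c(32, 32), m)
    expect_equal(max(abs(env - 5)), 0, tolerance = 1e-9)
  }

  set.seed(3)
  pts <- expand.grid(row = seq(2, 30, 4), col = seq(2, 30, 4))
  pts$value <- rnorm(nrow(pts))
  for (m in c("thin_plate_rbf", "triangulated_linear")) {
    env <- interpolate_envelope(pts, c(32, 32), m)
    expect_equal(env[cbind(pts$row, pts$col)], pts$value, tolerance = 1e-9)
    expect_true(all(is.finite(env)))
  }
})

test_that("thin-plate envelopes reproduce affine surfaces", {
  set.seed(11)
  pts <- data.frame(row = sample(1:40, 15), col = sample(1:40, 15))
  pts$value <- 2 * pts$row + 3 * pts$col + 1
  env <- interpolate_envelope(pts, c(40, 40), "thin_plate_rbf")
  plane <- outer(1:40, 1:40, function(r, c) 2 * r + 3 * c + 1)
  expect_lt(max(abs(env - plane)), 1e-6)

  # triangulated linear also reproduces the plane, up to the deterministic
  # vertex jitter, on pixels well inside the data hull
  dense <- expand.grid(row = seq(1, 40, 3), col = seq(1, 40, 3))
  dense$value <- 2 * dense$row + 3 * dense$col + 1
  env2 <- interpolate_envelope(dense, c(40, 40), "triangulated_linear")
  expect_lt(max(abs(env2 - plane)[4:37, 4:37]), 0.01)
})

test_that("degenerate envelope geometry is rejected", {
  expect_error(
    interpolate_envelope(data.frame(row = 1:2, col = 1:2, value = 0), c(8, 8)),
    class = "mttex_degenerate_geometry")
  collinear <- data.frame(row = 1:6, col = 2 * (1:6) + 1, value = rnorm(6))
  expect_error(interpolate_envelope(collinear, c(16, 16)),
               class = "mttex_degenerate_geometry")
  dup <- data.frame(row = c(1, 1, 4, 8), col = c(2, 2, 5, 1), value = 1:4)
  expect_error(interpolate_envelope(dup, c(8, 8)),
               class = "mttex_degenerate_geometry")
})

test_that("a pure 2-D sinusoid sifts to itself in one iteration", {
  s <- outer(1:64, 1:64, function(r, c) sin(2 * pi * r / 8) * sin(2 * pi * c / 8))
  res <- sift_one_imf(s)
  expect_identical(res$iterations, 1L)
  expect_identical(res$stop, "sd_converged")
  expect_gt(cor(as.vector(res$imf), as.vector(s)), 0.99)
})

test_that("sifting a constant image stops with a zero IMF", {
  res <- sift_one_imf(matrix(7, 16, 16))
  expect_identical(res$stop, "too_few_extrema")
  expect_identical(res$iterations, 0L)
  expect_true(all(res$imf == 0))
})

test_that("sift iteration counts respect the hard cap", {
  set.seed(5)
  for (K in c(1L, 3L)) {
    x <- smooth_random_image(32, sigma = 1.5, seed = K)
    res <- sift_one_imf(x, sift_config(sd_threshold = 1e-9,
                                       max_iterations_per_imf = K))
    expect_lte(res$iterations, K)
  }
})

test_that("decomposition reconstructs the input and orders frequencies", {
  # constant image: no IMFs, residue is the input
  cst <- matrix(2.5, 16, 16)
  dc <- bemd(cst)
  expect_length(dc$imfs, 0)
  expect_equal(dc$residue, cst)
  expect_identical(dc$stop_reason, "too_few_extrema")
  expect_equal(bemd_reconstruct(dc), cst)

  x <- smooth_random_image(64, sigma = 2, seed = 9)
  d <- bemd(x)
  expect_gt(length(d$imfs), 0)
  expect_lte(length(d$imfs), 4)
  expect_true(all(d$iterations_used <= sift_config()$max_iterations_per_imf))
  expect_lt(max(abs(bemd_reconstruct(d) - x)), 1e-8)

  # two-scale fixture: IMF1 follows the fine grating, and the local
  # oscillation density (extrema per pixel) never increases with depth
  tex <- generate_multiscale_texture(128, c(8, 64), c(1, 1), seed = 3)
  comp <- attr(tex, "components")
  dt <- bemd(tex)
  expect_gte(length(dt$imfs), 2)
  expect_gt(cor(as.vector(dt$imfs[[1]]), as.vector(comp[[1]])), 0.8)
  expect_gt(abs(cor(as.vector(dt$imfs[[1]]), as.vector(comp[[1]]))),
            abs(cor(as.vector(dt$imfs[[1]]), as.vector(comp[[2]]))))
  dens <- vapply(dt$imfs, function(m) {
    e <- detect_extrema(m); (nrow(e$maxima) + nrow(e$minima)) / length(m)
  }, numeric(1))
  expect_true(all(diff(dens) <= 0))
})

test_that("decomposition is deterministic", {
  x <- smooth_random_image(48, sigma = 2, seed = 21)
  d1 <- bemd(x)
  d2 <- bemd(x)
  expect_identical(d1, d2)
})

test_that("reconstruction validates shapes and handles edge cases", {
  x <- matrix(rnorm(64), 8, 8)
  expect_equal(bemd_reconstruct(list(imfs = list(), residue = x)), x)
  z <- bemd_reconstruct(list(imfs = list(x, -x), residue = matrix(0, 8, 8)))
  expect_true(all(z == 0))
  expect_error(
    bemd_reconstruct(list(imfs = list(matrix(0, 4, 4)), residue = x)),
    class = "mttex_validation_error")
})
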