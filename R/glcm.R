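#' Grey-level co-occurrence configuration
#'
#' @param levels number of grey levels G (2..256).  The default 64 keeps
#'   8-bit micrograph structure while a 1024 x 1024 image still populates the
#'   G x G matrix densely.
#' @param distance pixel offset d between co-occurring pixels; the default 4
#'   is the working distance for microtubule micrographs.
#' @param directions subset of `c(0, 45, 90, 135)` degrees; default all four.
#' @param symmetric count each pair in both orders (Haralick's original
#'   convention, gives an exactly symmetric matrix); default `TRUE`.
#' @param log_base base for the entropy logarithm: 2 (bits, default) or
#'   `exp(1)` (nats).
#' @return object of class `glcm_config`.
#' @export
glcm_config <- function(levels = 64L, distance = 4L,
                        directions = c(0, 45, 90, 135),
                        symmetric = TRUE, log_base = 2) {
  if (levels < 2 || levels > 256) stop_validation("levels must be in 2..256")
  if (distance < 1) stop_validation("distance must be >= 1")
  if (!all(directions %in% c(0, 45, 90, 135)))
    stop_validation("directions must be from {0, 45, 90, 135}")
  if (!log_base %in% c(2, exp(1)))
    stop_validation("log_base must be 2 or exp(1)")
  structure(list(levels = as.integer(levels), distance = as.integer(distance),
                 directions = as.numeric(directions),
                 symmetric = isTRUE(symmetric), log_base = log_base),
            class = "glcm_config")
}

#' Quantize an image to discrete grey levels
#'
#' Global linear min-max map: `floor((v - min) / (max - min) * G)` clipped to
#' `G - 1`.  A constant image maps to all zeros.  Signed real rasters (IMFs)
#' and integer micrographs are handled uniformly.
#'
#' @param image numeric matrix, finite.
#' @param levels number of levels G >= 2.
#' @return matrix of integers in `0..levels-1`.
#' @export
quantize <- function(image, levels = 64L) {
  image <- as_gray_image(image)
  if (levels < 2) stop_validation("levels must be >= 2")
  rng <- range(image)
  if (rng[2] == rng[1]) return(matrix(0L, nrow(image), ncol(image)))
  q <- floor((image - rng[1]) / (rng[2] - rng[1]) * levels)
  q[q > levels - 1] <- levels - 1
  storage.mode(q) <- "integer"
  q
}

# displacement (drow, dcol) for each direction at distance d;
# 0 deg looks right, 45 up-right, 90 up, 135 up-left
direction_offset <- function(direction, d) {
  switch(as.character(direction),
         "0"   = c(0L, d),
         "45"  = c(-d, d),
         "90"  = c(-d, 0L),
         "135" = c(-d, -d),
         stop_validation("direction must be one of 0, 45, 90, 135"))
}

#' Compute a normalized grey-level co-occurrence matrix
#'
#' Counts ordered pairs `(x[r, c], x[r + dr, c + dc])` over all in-bounds
#' pixels, where the displacement is `distance` pixels along `direction`.
#' With `symmetric = TRUE` the transpose is added before normalization, so
#' each unordered pair is counted in both orders.  Entries are normalized to
#' probabilities `P(i, j)` summing to 1.
#'
#' @param image integer-valued matrix with levels in `0..levels-1`
#'   (see [quantize()]).
#' @param distance offset d in pixels; must fit inside the image.
#' @param direction one of 0, 45, 90, 135 (degrees).
#' @param symmetric add the transpose before normalizing.
#' @param levels number of grey levels G; default `max(image) + 1`.
#' @return object of class `glcm`: list with `probabilities` (G x G matrix),
#'   `pair_count`, and the parameters used.
#' @export
compute_glcm <- function(image, distance = 4L, direction = 0,
                         symmetric = TRUE, levels = NULL) {
  if (!is.matrix(image) || !is.numeric(image))
    stop_validation("image must be a numeric matrix")
  if (any(image != floor(image)) || min(image) < 0)
    stop_validation("image must be integer-valued and non-negative; quantize() first")
  if (is.null(levels)) levels <- as.integer(max(image) + 1)
  G <- as.integer(levels)
  if (max(image) > G - 1) stop_validation("image has levels >= `levels`")
  off <- direction_offset(direction, as.integer(distance))
  h <- nrow(image); w <- ncol(image)
  if (h - abs(off[1L]) < 1L || w - abs(off[2L]) < 1L)
    stop_validation("distance ", distance, " does not fit a ", h, " x ", w,
                    " image along direction ", direction)
  rs <- max(1L, 1L - off[1L]):min(h, h - off[1L])
  cs <- max(1L, 1L - off[2L]):min(w, w - off[2L])
  i <- as.vector(image[rs, cs, drop = FALSE])
  j <- as.vector(image[rs + off[1L], cs + off[2L], drop = FALSE])
  counts <- tabulate(i * G + j + 1L, nbins = G * G)
  C <- matrix(counts, nrow = G, ncol = G, byrow = TRUE)   # row = i, col = j
  if (symmetric) C <- C + t(C)
  pair_count <- sum(C)
  structure(list(probabilities = C / pair_count,
                 pair_count = pair_count,
                 distance = as.integer(distance), direction = direction,
                 symmetric = symmetric, levels = G),
            class = "glcm")
}

prob_matrix <- function(P) {
  if (inherits(P, "glcm")) P$probabilities
  else if (is.matrix(P)) P
  else stop_validation("expected a glcm object or probability matrix")
}

#' Angular second moment (energy) of a co-occurrence matrix
#'
#' `sum(P^2)`: 1 for a degenerate (single-cell) distribution, `1/G^2` for a
#' uniform one.  High values indicate a smooth, uniform texture.
#'
#' @param P a `glcm` object or normalized probability matrix.
#' @return scalar in (0, 1].
#' @export
glcm_asm <- function(P) sum(prob_matrix(P)^2)

#' Entropy of a co-occurrence matrix
#'
#' `-sum(P * log(P))` with the convention `0 * log 0 = 0`.  Measures texture
#' complexity; 0 for a degenerate distribution, up to `2 log(G)` for the
#' uniform one.
#'
#' @param P a `glcm` object or normalized probability matrix.
#' @param base logarithm base; 2 (bits, default) or `exp(1)` (nats).
#' @return non-negative scalar.
#' @export
glcm_entropy <- function(P, base = 2) {
  p <- prob_matrix(P)
  p <- p[p > 0]
  -sum(p * log(p, base = base))
}

#' Inverse difference moment (local homogeneity)
#'
#' `sum(P(i, j) / (1 + (i - j)^2))`: weight concentrates on the diagonal, so
#' regular textures whose co-occurring levels agree score close to 1.
#'
#' @param P a `glcm` object or normalized probability matrix.
#' @return scalar in (0, 1].
#' @export
glcm_idm <- function(P) {
  p <- prob_matrix(P)
  G <- nrow(p)
  D <- outer(0:(G - 1), 0:(G - 1), "-")
  sum(p / (1 + D^2))
}

#' Grey-level variance of a co-occurrence matrix
#'
#' `sum((i - mu)^2 * P(i, j))` with `mu = sum(i * P(i, j))`, the row-index
#' mean (for a symmetric matrix the row and column means coincide).  Reflects
#' the spread of grey levels taking part in co-occurrences, in squared index
#' units.
#'
#' @param P a `glcm` object or normalized probability matrix.
#' @return non-negative scalar.
#' @export
glcm_variance <- function(P) {
  p <- prob_matrix(P)
  G <- nrow(p)
  pi_ <- rowSums(p)
  mu <- sum((0:(G - 1)) * pi_)
  sum(((0:(G - 1)) - mu)^2 * pi_)
}

#' Contrast of a co-occurrence matrix
#'
#' `sum(n^2 * P(|i - j| = n))`, i.e. the `(i - j)^2`-weighted probability
#' mass.  Proxies image sharpness: it is the criterion used to rank
#' decomposition products in [select_enhanced_image()].
#'
#' @param P a `glcm` object or normalized probability matrix.
#' @return scalar in `[0, (G-1)^2]`.
#' @export
glcm_contrast <- function(P) {
  p <- prob_matrix(P)
  G <- nrow(p)
  D <- outer(0:(G - 1), 0:(G - 1), "-")
  sum(D^2 * p)
}

#' Extract the five texture features in each direction
#'
#' Quantizes the image to `config$levels` grey levels, computes one
#' co-occurrence matrix per direction at `config$distance`, and evaluates the
#' five features (ASM, entropy, IDM, variance, contrast) on each, plus their
#' across-direction means.
#'
#' @param image numeric matrix; both extents must exceed `config$distance`.
#' @param config a [glcm_config()].
#' @return object of class `texture_features`: list with `by_direction`
#'   (data frame, one row per direction), `mean` (named vector of
#'   across-direction means) and `config`.
#' @export
extract_features <- function(image, config = glcm_config()) {
  image <- as_gray_image(image)
  if (min(dim(image)) <= config$distance)
    stop_validation("image extent must exceed the co-occurrence distance")
  q <- quantize(image, config$levels)
  rows <- lapply(config$directions, function(theta) {
    g <- compute_glcm(q, distance = config$distance, direction = theta,
                      symmetric = config$symmetric, levels = config$levels)
    data.frame(direction = theta,
               asm = glcm_asm(g),
               entropy = glcm_entropy(g, base = config$log_base),
               idm = glcm_idm(g),
               variance = glcm_variance(g),
               contrast = glcm_contrast(g))
  })
  tab <- do.call(rbind, rows)
  structure(list(by_direction = tab,
                 mean = colMeans(tab[, -1L, drop = FALSE]),
                 config = config),
            class = "texture_features")
}

#' @export
print.texture_features <- function(x, ...) {
  cat("GLCM texture features (G =", x$config$levels,
      ", d =", x$config$distance, ")\n")
  print(x$by_direction, row.names = FALSE)
  cat("direction means:\n")
  print(round(x$mean, 6))
  invisible(x)
}

#' @export
print.glcm <- function(x, ...) {
  cat("GLCM: G =", x$levels, ", d =", x$distance, ", direction =",
      x$direction, "deg,", if (x$symmetric) "symmetric," else "asymmetric,",
      x$pair_count, "pairs\n")
  invisible(x)
}
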