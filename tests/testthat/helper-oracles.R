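# Independent brute-force oracles and fixture builders used across the suite.
# The oracles deliberately share no code with the package internals: plain
# double loops over pixels and matrix cells.

# exhaustive pair-enumeration co-occurrence oracle
glcm_oracle <- function(img, d, direction, symmetric = TRUE, G) {
  off <- switch(as.character(direction),
                "0" = c(0, d), "45" = c(-d, d),
                "90" = c(-d, 0), "135" = c(-d, -d))
  C <- matrix(0L, G, G)
  h <- nrow(img); w <- ncol(img)
  for (r in seq_len(h)) {
    for (cc in seq_len(w)) {
      r2 <- r + off[1]; c2 <- cc + off[2]
      if (r2 >= 1 && r2 <= h && c2 >= 1 && c2 <= w) {
        i <- img[r, cc]; j <- img[r2, c2]
        C[i + 1, j + 1] <- C[i + 1, j + 1] + 1L
      }
    }
  }
  if (symmetric) C <- C + t(C)
  list(counts = C, P = C / sum(C))
}

# double-loop evaluation of the five features from a probability matrix
features_oracle <- function(P, base = 2) {
  G <- nrow(P)
  asm <- 0; ent <- 0; idm <- 0; mu <- 0
  for (i in 0:(G - 1)) {
    for (j in 0:(G - 1)) {
      p <- P[i + 1, j + 1]
      asm <- asm + p^2
      if (p > 0) ent <- ent - p * log(p, base)
      idm <- idm + p / (1 + (i - j)^2)
      mu <- mu + i * p
    }
  }
  va <- 0; con <- 0
  for (i in 0:(G - 1)) {
    for (j in 0:(G - 1)) {
      p <- P[i + 1, j + 1]
      va <- va + (i - mu)^2 * p
      con <- con + (i - j)^2 * p
    }
  }
  c(asm = asm, entropy = ent, idm = idm, variance = va, contrast = con)
}

# exhaustive strict 8-neighbour extrema scan
extrema_oracle <- function(x) {
  h <- nrow(x); w <- ncol(x)
  mx <- NULL; mn <- NULL
  for (r in seq_len(h)) {
    for (cc in seq_len(w)) {
      is_max <- TRUE; is_min <- TRUE
      for (dr in -1:1) {
        for (dc in -1:1) {
          if (dr == 0 && dc == 0) next
          r2 <- r + dr; c2 <- cc + dc
          if (r2 < 1 || r2 > h || c2 < 1 || c2 > w) next
          if (x[r2, c2] >= x[r, cc]) is_max <- FALSE
          if (x[r2, c2] <= x[r, cc]) is_min <- FALSE
        }
      }
      if (is_max) mx <- rbind(mx, c(r, cc))
      if (is_min) mn <- rbind(mn, c(r, cc))
    }
  }
  list(maxima = mx, minima = mn)
}

# smooth random field: white noise blurred at the given scale
smooth_random_image <- function(n, sigma = 3, seed = 1) {
  set.seed(seed)
  mttex:::gaussian_blur(matrix(rnorm(n * n), n, n), sigma)
}

# counter-clockwise quarter-turn
rot90ccw <- function(m) t(m)[ncol(m):1, , drop = FALSE]
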