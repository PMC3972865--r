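#' Sifting configuration for bidimensional empirical mode decomposition
#'
#' Controls the inner sifting loop and the outer decomposition loop of
#' [bemd()].  The stopping rule is the classic Cauchy-type criterion on the
#' normalised squared change between successive sift iterates,
#' `SD = sum((h_k - h_{k-1})^2) / sum(h_{k-1}^2)`, with a hard per-IMF
#' iteration cap as a safety net.
#'
#' @param sd_threshold convergence threshold on SD, in (0, 1]; default 0.2,
#'   the standard empirical-mode-decomposition choice.
#' @param max_iterations_per_imf hard cap K on sift iterations per IMF.
#' @param max_imfs maximum number L of intrinsic mode functions; the default 4
#'   matches the typical depth at which micrographs reduce to a smooth residue.
#' @param min_extrema minimum count of maxima (and of minima) required to
#'   attempt an envelope; below it the remainder is declared the residue.
#' @param interpolation envelope surface method: `"auto"` (default; thin-plate
#'   spline up to 400 extrema, triangulated linear beyond, keeping large
#'   images tractable), `"thin_plate_rbf"`, or `"triangulated_linear"`.
#' @param boundary boundary handling; only `"mirror"` (mirror-pad by 10% of
#'   each dimension, at least 8 px, before extrema detection, then crop the
#'   envelopes back) is implemented.  Padding suppresses the envelope flaring
#'   at image borders that plagues empirical mode decomposition.
#' @return an object of class `sift_config`.
#' @export
sift_config <- function(sd_threshold = 0.2,
                        max_iterations_per_imf = 10L,
                        max_imfs = 4L,
                        min_extrema = 3L,
                        interpolation = c("auto", "thin_plate_rbf",
                                          "triangulated_linear"),
                        boundary = "mirror") {
  if (!is.numeric(sd_threshold) || sd_threshold <= 0 || sd_threshold > 1)
    stop_validation("sd_threshold must be in (0, 1]")
  if (max_iterations_per_imf < 1) stop_validation("max_iterations_per_imf >= 1")
  if (max_imfs < 1) stop_validation("max_imfs >= 1")
  if (min_extrema < 1) stop_validation("min_extrema >= 1")
  interpolation <- match.arg(interpolation)
  boundary <- match.arg(boundary, "mirror")
  structure(list(sd_threshold = sd_threshold,
                 max_iterations_per_imf = as.integer(max_iterations_per_imf),
                 max_imfs = as.integer(max_imfs),
                 min_extrema = as.integer(min_extrema),
                 interpolation = interpolation,
                 boundary = boundary),
            class = "sift_config")
}

#' Detect strict local extrema over the 8-neighbourhood
#'
#' A pixel is a maximum iff it is strictly greater than every in-bounds
#' neighbour among its (up to) 8 neighbours; minima dually.  Plateau pixels
#' (equal to some neighbour) are never extrema, so the two lists are disjoint
#' and a constant image has none.
#'
#' @param image numeric matrix, at least 8 x 8.
#' @return an object of class `extrema_map`: list with data frames `maxima`
#'   and `minima`, each with columns `row`, `col`, `value` (1-based indices).
#' @export
detect_extrema <- function(image) {
  x <- as_gray_image(image, min_dim = 8L)
  h <- nrow(x); w <- ncol(x)
  nb_max <- matrix(-Inf, h, w)
  nb_min <- matrix(Inf, h, w)
  for (dr in -1:1) {
    for (dc in -1:1) {
      if (dr == 0L && dc == 0L) next
      rs <- max(1L, 1L + dr):min(h, h + dr)   # destination rows
      cs <- max(1L, 1L + dc):min(w, w + dc)
      src <- x[rs - dr, cs - dc, drop = FALSE]
      nb_max[rs, cs] <- pmax(nb_max[rs, cs, drop = FALSE], src)
      nb_min[rs, cs] <- pmin(nb_min[rs, cs, drop = FALSE], src)
    }
  }
  idx_max <- which(x > nb_max, arr.ind = TRUE)
  idx_min <- which(x < nb_min, arr.ind = TRUE)
  structure(list(
    maxima = data.frame(row = idx_max[, 1L], col = idx_max[, 2L],
                        value = x[idx_max]),
    minima = data.frame(row = idx_min[, 1L], col = idx_min[, 2L],
                        value = x[idx_min])),
    class = "extrema_map")
}

# mirror (symmetric) padding by pad_r rows / pad_c cols on each side
mirror_pad <- function(x, pad_r, pad_c) {
  h <- nrow(x); w <- ncol(x)
  rows <- c(pad_r:1, 1:h, h:(h - pad_r + 1L))
  cols <- c(pad_c:1, 1:w, w:(w - pad_c + 1L))
  x[rows, cols, drop = FALSE]
}

pad_amount <- function(n) max(8L, as.integer(ceiling(0.1 * n)))

#' Interpolate a smooth envelope surface through scattered extrema
#'
#' Fits an interpolating (not approximating) surface through the supplied
#' points and evaluates it at every pixel of the requested shape.
#' `"thin_plate_rbf"` is an exact thin-plate spline (reproduces affine
#' surfaces; cost grows cubically in the point count).  `"triangulated_linear"`
#' triangulates the points (Delaunay) and interpolates linearly with
#' nearest-point extension outside the convex hull; it scales to the tens of
#' thousands of extrema a noisy micrograph produces.  `"auto"` switches
#' between them at 400 points.
#'
#' @param points data frame or matrix with columns `row`, `col`, `value`
#'   (1-based pixel coordinates).
#' @param shape integer vector `c(height, width)` of the output raster.
#' @param method interpolation method, see above.
#' @return numeric `height x width` matrix equal to `value` at every supplied
#'   pixel.
#' @export
interpolate_envelope <- function(points, shape,
                                 method = c("auto", "thin_plate_rbf",
                                            "triangulated_linear")) {
  method <- match.arg(method)
  pts <- as.data.frame(points)
  if (!all(c("row", "col", "value") %in% names(pts))) {
    if (ncol(pts) >= 3L) names(pts)[1:3] <- c("row", "col", "value")
    else stop_validation("points needs columns row, col, value")
  }
  n <- nrow(pts)
  if (n < 3L) stop_degenerate("need at least 3 envelope points, got ", n)
  if (anyDuplicated(pts[c("row", "col")]))
    stop_degenerate("duplicate envelope point coordinates")
  if (qr(cbind(1, pts$row, pts$col))$rank < 3L)
    stop_degenerate("envelope points are collinear")
  h <- as.integer(shape[1L]); w <- as.integer(shape[2L])
  if (method == "auto") {
    # exact TPS where its dense solve and O(npixels * n) evaluation are
    # cheap; triangulated linear keeps large noisy images tractable
    method <- if (n <= 400L && as.numeric(h) * w * n <= 2e6)
      "thin_plate_rbf" else "triangulated_linear"
  }
  env <- if (method == "thin_plate_rbf") {
    fit <- tps_fit(pts$row - 1, pts$col - 1, pts$value)
    cpp_tps_eval(pts$row - 1, pts$col - 1, fit$w, fit$a, h, w)
  } else {
    cpp_tri_interp(pts$row - 1, pts$col - 1, pts$value, h, w)
  }
  # re-impose exact data values at in-range pixels (interpolation condition)
  ok <- pts$row >= 1 & pts$row <= h & pts$col >= 1 & pts$col <= w
  env[cbind(pts$row[ok], pts$col[ok])] <- pts$value[ok]
  env
}

# dense thin-plate spline fit; kernel U(d) = d^2 log d
tps_fit <- function(r, c, v) {
  n <- length(r)
  d2 <- outer(r, r, "-")^2 + outer(c, c, "-")^2
  K <- ifelse(d2 > 0, 0.5 * d2 * log(d2), 0)
  P <- cbind(1, r, c)
  M <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3, 3)))
  sol <- solve(M, c(v, 0, 0, 0))
  list(w = sol[1:n], a = sol[n + 1:3])
}

# mean of upper and lower envelopes of h, computed on the mirror-padded
# domain and cropped back; NULL when too few extrema or degenerate geometry
envelope_mean <- function(h, config) {
  pr <- pad_amount(nrow(h)); pc <- pad_amount(ncol(h))
  hp <- mirror_pad(h, pr, pc)
  ex <- detect_extrema(hp)
  if (nrow(ex$maxima) < config$min_extrema ||
      nrow(ex$minima) < config$min_extrema) return(NULL)
  shape <- dim(hp)
  m <- tryCatch({
    up <- interpolate_envelope(ex$maxima, shape, config$interpolation)
    lo <- interpolate_envelope(ex$minima, shape, config$interpolation)
    (up + lo) / 2
  }, mttex_degenerate_geometry = function(e) NULL)
  if (is.null(m)) return(NULL)
  m[pr + seq_len(nrow(h)), pc + seq_len(ncol(h)), drop = FALSE]
}

#' Extract one intrinsic mode function by sifting
#'
#' Repeatedly subtracts the mean of the upper (maxima-interpolated) and lower
#' (minima-interpolated) envelope surfaces from the working image until the
#' normalised squared change SD between iterates drops below
#' `config$sd_threshold`, or the iteration cap is reached.  A denominator
#' below 1e-12 (numerically zero iterate) counts as converged.
#'
#' @param image numeric matrix, at least 8 x 8, all values finite.
#' @param config a [sift_config()].
#' @return list with `imf` (matrix), `iterations` (count of envelope
#'   subtractions performed) and `stop` (one of `"sd_converged"`,
#'   `"max_iterations"`, `"too_few_extrema"`).  Too few extrema on entry
#'   yields a zero `imf` and 0 iterations.
#' @export
sift_one_imf <- function(image, config = sift_config()) {
  h_prev <- as_gray_image(image, min_dim = 8L)
  K <- config$max_iterations_per_imf
  for (k in seq_len(K)) {
    m <- envelope_mean(h_prev, config)
    if (is.null(m)) {
      if (k == 1L)
        return(list(imf = matrix(0, nrow(h_prev), ncol(h_prev)),
                    iterations = 0L, stop = "too_few_extrema"))
      return(list(imf = h_prev, iterations = k - 1L, stop = "too_few_extrema"))
    }
    h <- h_prev - m
    denom <- sum(h_prev^2)
    if (denom < 1e-12)
      return(list(imf = h, iterations = k, stop = "sd_converged"))
    sd_k <- sum((h - h_prev)^2) / denom
    h_prev <- h
    if (sd_k < config$sd_threshold)
      return(list(imf = h, iterations = k, stop = "sd_converged"))
  }
  list(imf = h_prev, iterations = K, stop = "max_iterations")
}

#' Bidimensional empirical mode decomposition
#'
#' Splits an image `x` into intrinsic mode functions `c_1 .. c_L` (highest
#' spatial frequency first) and a smooth residue `r_L` such that
#' `x = sum(c_l) + r_L` holds to floating-point accuracy: each IMF is obtained
#' by [sift_one_imf()] and subtracted from the running signal, so the sum
#' telescopes back to the input exactly.  Decomposition stops at
#' `config$max_imfs`, or earlier once the remainder has fewer than
#' `config$min_extrema` maxima or minima and is declared the residue.
#'
#' The module is fully deterministic: identical inputs and configuration give
#' bit-identical decompositions.
#'
#' @param image numeric matrix, at least 8 x 8, finite.
#' @param config a [sift_config()].
#' @return object of class `bemd_result`: list with `imfs` (list of matrices,
#'   possibly empty), `residue` (matrix), `iterations_used` (integer vector),
#'   `imf_stops` (per-IMF sift stop reasons) and `stop_reason`
#'   (`"max_imfs"` or `"too_few_extrema"`).
#' @seealso [bemd_reconstruct()], [select_enhanced_image()]
#' @export
bemd <- function(image, config = sift_config()) {
  r <- as_gray_image(image, min_dim = 8L)
  imfs <- list()
  iters <- integer(0)
  stops <- character(0)
  stop_reason <- "max_imfs"
  for (l in seq_len(config$max_imfs)) {
    ex <- detect_extrema(r)
    if (nrow(ex$maxima) < config$min_extrema ||
        nrow(ex$minima) < config$min_extrema) {
      stop_reason <- "too_few_extrema"
      break
    }
    s <- sift_one_imf(r, config)
    if (s$stop == "too_few_extrema" && s$iterations == 0L) {
      stop_reason <- "too_few_extrema"
      break
    }
    imfs[[l]] <- s$imf
    iters[l] <- s$iterations
    stops[l] <- s$stop
    r <- r - s$imf
  }
  structure(list(imfs = imfs, residue = r, iterations_used = iters,
                 imf_stops = stops, stop_reason = stop_reason),
            class = "bemd_result")
}

#' Reconstruct an image from its decomposition
#'
#' Elementwise sum of all intrinsic mode functions and the residue; inverse of
#' [bemd()] up to floating-point rounding.
#'
#' @param result a `bemd_result`, or any list with `imfs` and `residue`.
#' @return numeric matrix.
#' @export
bemd_reconstruct <- function(result) {
  if (is.null(result$residue)) stop_validation("result has no residue")
  out <- result$residue
  for (imf in result$imfs) {
    if (!identical(dim(imf), dim(out)))
      stop_validation("IMF/residue shape mismatch")
    out <- out + imf
  }
  out
}

#' @export
print.bemd_result <- function(x, ...) {
  cat("BEMD decomposition: ", length(x$imfs), " IMF(s) + residue (",
      nrow(x$residue), " x ", ncol(x$residue), ")\n", sep = "")
  if (length(x$imfs))
    cat("  sift iterations:", paste(x$iterations_used, collapse = ", "), "\n")
  cat("  stop reason:", x$stop_reason, "\n")
  invisible(x)
}

#' @export
print.extrema_map <- function(x, ...) {
  cat("Extrema map:", nrow(x$maxima), "maxima,", nrow(x$minima), "minima\n")
  invisible(x)
}
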