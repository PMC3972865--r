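#' Parameters for the synthetic fiber-image generator
#'
#' Describes a field of bright curvilinear filaments on a dark background,
#' emulating a fluorescence micrograph of cortical microtubules: anti-aliased
#' line segments, an isotropic Gaussian point-spread function, a constant
#' background and additive Gaussian read noise.  Orientation structure is the
#' single experimental knob: fiber angles are von Mises distributed with
#' concentration `angle_concentration` (kappa), 8 in the `"ordered"` regime
#' (tightly aligned array) and 0 in the `"disordered"` regime (uniform
#' orientations), so ordered and disordered images differ only in kappa.
#'
#' @param height,width image size in pixels.
#' @param n_fibers number of filaments drawn.
#' @param orientation_mode `"ordered"` or `"disordered"`; sets the default
#'   kappa (8 resp. 0).
#' @param mean_angle mean fiber orientation in degrees (0 = horizontal),
#'   used in ordered mode.
#' @param angle_concentration von Mises kappa >= 0; overrides the mode
#'   default when given.
#' @param fiber_length_mean,fiber_length_sd fiber length distribution in
#'   pixels (Gaussian truncated to positive values).
#' @param fiber_intensity peak intensity of a fiber, arbitrary units.
#' @param fiber_width Gaussian half-width of the drawn line profile in pixels
#'   (sub-pixel: anti-aliasing).
#' @param psf_sigma point-spread-function standard deviation in pixels.
#' @param noise_sigma additive Gaussian noise SD, in units of
#'   `fiber_intensity`.
#' @param background constant background offset.
#' @param seed integer seed; identical seed and parameters give bit-identical
#'   images, and the caller's RNG state is left untouched.
#' @return object of class `fiber_params`.
#' @export
fiber_params <- function(height = 256L, width = 256L, n_fibers = 60L,
                         orientation_mode = c("ordered", "disordered"),
                         mean_angle = 0, angle_concentration = NULL,
                         fiber_length_mean = 250, fiber_length_sd = 60,
                         fiber_intensity = 1, fiber_width = 1.5,
                         psf_sigma = 1.5, noise_sigma = 0.1,
                         background = 0.1, seed = NULL) {
  orientation_mode <- match.arg(orientation_mode)
  if (is.null(angle_concentration))
    angle_concentration <- if (orientation_mode == "ordered") 8 else 0
  if (height < 1 || width < 1 || n_fibers < 0)
    stop_validation("dimensions must be positive, n_fibers >= 0")
  if (angle_concentration < 0) stop_validation("angle_concentration >= 0")
  if (noise_sigma < 0) stop_validation("noise_sigma >= 0")
  structure(list(height = as.integer(height), width = as.integer(width),
                 n_fibers = as.integer(n_fibers),
                 orientation_mode = orientation_mode,
                 mean_angle = mean_angle,
                 angle_concentration = angle_concentration,
                 fiber_length_mean = fiber_length_mean,
                 fiber_length_sd = fiber_length_sd,
                 fiber_intensity = fiber_intensity,
                 fiber_width = fiber_width,
                 psf_sigma = psf_sigma, noise_sigma = noise_sigma,
                 background = background, seed = seed),
            class = "fiber_params")
}

# von Mises sampler (Best & Fisher rejection scheme); kappa ~ 0 -> uniform
rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-8) return(runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
      out[i] <- (mu + sign(u[3] - 0.5) * acos(f)) %% (2 * pi)
      i <- i + 1L
    }
  }
  out
}

# separable Gaussian blur with mirrored boundary
gaussian_blur <- function(x, sigma) {
  if (sigma <= 0) return(x)
  rad <- max(1L, as.integer(ceiling(4 * sigma)))
  k <- exp(-((-rad):rad)^2 / (2 * sigma^2))
  k <- k / sum(k)
  # mirrored border indices, clamped to edge replication when rad exceeds
  # the extent
  mirror_idx <- function(n) {
    idx <- c(rad:1, 1:n, n:(n - rad + 1L))
    idx[idx < 1L] <- 1L; idx[idx > n] <- n
    idx
  }
  conv1 <- function(m) {            # along rows (filter down each column)
    mp <- m[mirror_idx(nrow(m)), , drop = FALSE]
    f <- stats::filter(mp, k, sides = 2)
    matrix(f[rad + seq_len(nrow(m)), ], nrow(m), ncol(m))
  }
  t(conv1(t(conv1(x))))
}

#' Generate a synthetic microtubule-like fiber image
#'
#' Draws `n_fibers` anti-aliased straight segments with centers uniform in
#' the frame, orientations von Mises distributed, and lengths Gaussian
#' truncated to positive; convolves with an isotropic Gaussian PSF; adds the
#' constant background and Gaussian noise; clips at zero.
#'
#' @param params a [fiber_params()]; individual fields may be overridden via
#'   `...` for convenience.
#' @param ... overrides passed to [fiber_params()] when `params` is missing.
#' @return numeric `height x width` matrix, finite and non-negative.
#' @export
generate_fiber_image <- function(params = fiber_params(...), ...) {
  p <- params
  with_local_seed(p$seed, {
    img <- matrix(0, p$height, p$width)
    if (p$n_fibers > 0) {
      ang <- rvonmises(p$n_fibers, p$mean_angle * pi / 180,
                       p$angle_concentration)
      len <- numeric(p$n_fibers)
      for (i in seq_len(p$n_fibers)) {
        repeat {
          l <- rnorm(1, p$fiber_length_mean, p$fiber_length_sd)
          if (l > 0) break
        }
        len[i] <- l
      }
      cy <- runif(p$n_fibers, 1, p$height)
      cx <- runif(p$n_fibers, 1, p$width)
      margin <- ceiling(3 * p$fiber_width)
      for (i in seq_len(p$n_fibers)) {
        dx <- cos(ang[i]) * len[i] / 2
        dy <- sin(ang[i]) * len[i] / 2
        x0 <- cx[i] - dx; x1 <- cx[i] + dx
        y0 <- cy[i] - dy; y1 <- cy[i] + dy
        rs <- max(1L, floor(min(y0, y1) - margin)):
              min(p$height, ceiling(max(y0, y1) + margin))
        cs <- max(1L, floor(min(x0, x1) - margin)):
              min(p$width, ceiling(max(x0, x1) + margin))
        if (length(rs) < 1L || length(cs) < 1L || min(rs) > max(rs)) next
        py <- matrix(rs, length(rs), length(cs))
        px <- matrix(cs, length(rs), length(cs), byrow = TRUE)
        # distance from each pixel to the segment
        vx <- x1 - x0; vy <- y1 - y0
        L2 <- vx * vx + vy * vy
        tt <- if (L2 > 0) pmin(1, pmax(0, ((px - x0) * vx + (py - y0) * vy) / L2)) else 0
        ddx <- px - (x0 + tt * vx); ddy <- py - (y0 + tt * vy)
        d2 <- ddx * ddx + ddy * ddy
        img[rs, cs] <- img[rs, cs] +
          p$fiber_intensity * exp(-d2 / (2 * p$fiber_width^2))
      }
    }
    img <- gaussian_blur(img, p$psf_sigma)
    img <- img + p$background
    if (p$noise_sigma > 0)
      img <- img + matrix(rnorm(length(img), 0,
                                p$noise_sigma * p$fiber_intensity),
                          p$height, p$width)
    img[img < 0] <- 0
    img
  })
}

#' Generate a checkerboard test image
#'
#' Alternating `low`/`high` square blocks of side `period`; an analytic
#' fixture whose co-occurrence statistics are enumerable by hand.
#'
#' @param size image side in pixels; must be divisible by `2 * period`.
#' @param period block side in pixels.
#' @param low,high the two intensity values.
#' @return `size x size` matrix containing exactly the two values.
#' @export
generate_checkerboard <- function(size, period, low = 0, high = 1) {
  if (size %% (2 * period) != 0)
    stop_validation("size must be divisible by 2 * period")
  r <- floor((seq_len(size) - 1) / period)
  parity <- outer(r, r, "+") %% 2
  matrix(ifelse(parity == 0, low, high), size, size)
}

#' Generate a multiscale sinusoidal texture
#'
#' Sum of 2-D sinusoidal gratings, one per entry of `periods` (strictly
#' increasing), each with a random orientation and phase, plus a smooth
#' low-order polynomial trend playing the role of the residue.  The known
#' band-limited addends make this the fixture for frequency-ordering and
#' contrast-ordering checks on the decomposition.
#'
#' @param size image side in pixels.
#' @param periods strictly increasing grating periods in pixels (>= 2 of them).
#' @param amplitudes one amplitude per period.
#' @param trend_amplitude peak absolute value of the polynomial trend.
#' @param seed integer seed (RNG state restored on exit).
#' @return `size x size` matrix with attribute `components`: list of the
#'   individual gratings and `trend`, in the order generated.
#' @export
generate_multiscale_texture <- function(size = 256L, periods = c(8, 64),
                                        amplitudes = c(1, 1),
                                        trend_amplitude = mean(amplitudes),
                                        seed = NULL) {
  if (length(periods) != length(amplitudes) || length(periods) < 2L)
    stop_validation("need >= 2 periods with matching amplitudes")
  if (any(diff(periods) <= 0))
    stop_validation("periods must be strictly increasing")
  with_local_seed(seed, {
    u <- matrix(seq_len(size) - 1, size, size, byrow = TRUE)  # col coordinate
    v <- matrix(seq_len(size) - 1, size, size)                # row coordinate
    comps <- vector("list", length(periods))
    out <- matrix(0, size, size)
    for (i in seq_along(periods)) {
      phi <- runif(1, 0, pi)
      phase <- runif(1, 0, 2 * pi)
      g <- amplitudes[i] *
        sin(2 * pi * (u * cos(phi) + v * sin(phi)) / periods[i] + phase)
      comps[[i]] <- g
      out <- out + g
    }
    un <- 2 * u / (size - 1) - 1
    vn <- 2 * v / (size - 1) - 1
    co <- runif(6, -1, 1)
    trend <- co[1] + co[2] * un + co[3] * vn +
      co[4] * un^2 + co[5] * un * vn + co[6] * vn^2
    m <- max(abs(trend))
    if (m > 0 && trend_amplitude > 0) trend <- trend / m * trend_amplitude
    else trend <- trend * 0
    out <- out + trend
    attr(out, "components") <- c(comps, list(trend = trend))
    out
  })
}
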