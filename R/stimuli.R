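new_stimulus_movie <- function(frames, frame_rate, geometry, meta) {
  m <- list(frames = frames, frame_rate = frame_rate,
            geometry = geometry, meta = meta)
  class(m) <- "stimulus_movie"
  m
}

#' @export
print.stimulus_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<stimulus_movie> %s: %d x %d px, %d frames @ %g Hz\n",
              x$meta$kind, d[2], d[1], d[3], x$frame_rate))
  invisible(x)
}

n_frames_for <- function(duration, frame_rate) {
  # nearest-integer rounding; protocol durations are exact multiples anyway
  as.integer(round(duration * frame_rate))
}

check_nyquist <- function(sf, geometry, min_samples = 4) {
  if (sf > 0 && 1 / (sf * geometry$deg_per_px) < min_samples)
    stop("spatial frequency ", sf, " cpd undersampled at ",
         signif(geometry$deg_per_px, 3), " deg/px (need >= ", min_samples,
         " samples per cycle)")
}

#' Drifting sinusoidal grating
#'
#' Luminance is `0.5 + 0.5 * contrast * cos(2*pi*(sf*u - tf*t) + phase)`,
#' where `u` is the spatial coordinate along the drift direction, so the
#' pattern drifts toward `direction`. Direction convention: 0 degrees is
#' rightward drift, angles increase counter-clockwise (90 = upward).
#'
#' @param direction drift direction, degrees in [0, 360).
#' @param sf spatial frequency, cycles/degree.
#' @param tf temporal (drift) frequency, Hz.
#' @param contrast Michelson contrast in [0, 1].
#' @param duration stimulus duration, seconds.
#' @param frame_rate display refresh, Hz.
#' @param geometry a [display_geometry()].
#' @param phase spatial phase offset at the display centre, radians.
#' @return a `stimulus_movie` with frames in `[0, 1]` (0.5 = mid-gray),
#'   dimension `(ny, nx, n_frames)`.
#' @export
make_grating <- function(direction, sf, tf, contrast = 1, duration = 1.5,
                         frame_rate = 60, geometry = display_geometry(),
                         phase = 0) {
  if (duration <= 0 || frame_rate <= 0)
    stop("duration and frame_rate must be positive")
  stopifnot(sf > 0, tf >= 0, contrast >= 0, contrast <= 1)
  direction <- direction %% 360
  check_nyquist(sf, geometry)
  nt <- n_frames_for(duration, frame_rate)
  th <- direction * pi / 180
  # u(x, y) along the drift direction; y_deg increases upward
  u <- outer(geometry$y_deg * sin(th), geometry$x_deg * cos(th), `+`)
  t <- (seq_len(nt) - 1) / frame_rate
  frames <- array(0, dim = c(geometry$ny, geometry$nx, nt))
  for (k in seq_len(nt))
    frames[, , k] <- 0.5 + 0.5 * contrast *
      cos(2 * pi * (sf * u - tf * t[k]) + phase)
  new_stimulus_movie(frames, frame_rate, geometry,
                     list(kind = "grating", direction = direction, sf = sf,
                          tf = tf, contrast = contrast))
}

#' Drifting plaid (two superimposed gratings)
#'
#' Superposition is additive in contrast around mid-gray: the plaid frame
#' minus 0.5 equals the sum of the two component frames minus 0.5 each. The
#' two components drift at `pattern_direction +/- cross_angle/2`. With the
#' protocol defaults (cross angle 120 degrees, half-contrast components) the
#' plaid has full total contrast.
#'
#' @param pattern_direction global (pattern) drift direction, degrees.
#' @param cross_angle angular separation of the two components, degrees in
#'   [0, 180).
#' @param component_contrast contrast of each component grating.
#' @inheritParams make_grating
#' @return a `stimulus_movie`; luminance values clipped to `[0, 1]` with a
#'   warning if the summed contrast exceeds the displayable range.
#' @export
make_plaid <- function(pattern_direction, cross_angle = 120,
                       component_contrast = 0.5, sf = 0.02, tf = 2,
                       duration = 1.5, frame_rate = 60,
                       geometry = display_geometry(), phase = 0) {
  if (cross_angle < 0 || cross_angle >= 180)
    stop("cross_angle must be in [0, 180)")
  g1 <- make_grating(pattern_direction - cross_angle / 2, sf, tf,
                     component_contrast, duration, frame_rate, geometry, phase)
  g2 <- make_grating(pattern_direction + cross_angle / 2, sf, tf,
                     component_contrast, duration, frame_rate, geometry, phase)
  frames <- 0.5 + (g1$frames - 0.5) + (g2$frames - 0.5)
  rng <- range(frames)
  if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9) {
    warning("plaid luminance exceeds displayable range; clipping to [0, 1]")
    frames[frames < 0] <- 0
    frames[frames > 1] <- 1
  }
  new_stimulus_movie(frames, frame_rate, geometry,
                     list(kind = "plaid",
                          direction = pattern_direction %% 360,
                          sf = sf, tf = tf,
                          contrast = 2 * component_contrast,
                          cross_angle = cross_angle))
}

#' Spatiotemporally correlated, contrast-modulated noise movie
#'
#' Gaussian white noise is filtered to the requested correlation scales —
#' recursively in time (exponential autocorrelation `exp(-dt/temporal_corr)`)
#' and by Gaussian low-pass filtering in space (autocorrelation half-width at
#' half maximum equal to `spatial_corr`) — then multiplied by a slow
#' sinusoidal contrast envelope, clipped at three standard deviations and
#' mapped affinely into `[0, 1]` around mid-gray. Identical seeds give
#' bit-identical movies.
#'
#' @param seed integer seed; required so movies can be regenerated on demand
#'   instead of stored.
#' @param duration seconds (protocol default 60).
#' @param frame_rate Hz (protocol default 30).
#' @param spatial_corr spatial correlation scale, degrees: the half-width at
#'   half maximum of the spatial autocorrelation.
#' @param temporal_corr temporal correlation time constant, seconds.
#' @param contrast_mod_period period of the sinusoidal contrast envelope,
#'   seconds.
#' @param contrast_mod_depth modulation depth in [0, 1); the envelope swings
#'   between `1 - depth` and `1`.
#' @param geometry a [display_geometry()].
#' @return a `stimulus_movie` of kind `"noise"`.
#' @export
make_noise_movie <- function(seed, duration = 60, frame_rate = 30,
                             spatial_corr = 6, temporal_corr = 0.05,
                             contrast_mod_period = 10,
                             contrast_mod_depth = 0.8,
                             geometry = display_geometry()) {
  if (missing(seed) || is.null(seed)) stop("seed is required")
  stopifnot(spatial_corr > 0, temporal_corr > 0, contrast_mod_period > 0,
            duration > 0, frame_rate > 0)
  if (spatial_corr > min(geometry$azimuth_extent, geometry$elevation_extent))
    stop("spatial_corr exceeds the display extent")
  nt <- n_frames_for(duration, frame_rate)
  ny <- geometry$ny; nx <- geometry$nx
  dt <- 1 / frame_rate

  # Gaussian spatial kernel sigma giving autocorrelation HWHM = spatial_corr:
  # smoothing white noise with a Gaussian of sd s gives a Gaussian
  # autocorrelation of sd s*sqrt(2), whose HWHM is 2*s*sqrt(log(2)).
  sigma_px <- spatial_corr / (2 * sqrt(log(2))) / geometry$deg_per_px
  fy <- c(0:(floor(ny / 2)), -((ceiling(ny / 2) - 1):1)) / ny
  fx <- c(0:(floor(nx / 2)), -((ceiling(nx / 2) - 1):1)) / nx
  H <- exp(-2 * pi^2 * sigma_px^2 * outer(fy^2, fx^2, `+`))

  a <- exp(-dt / temporal_corr)  # AR(1) coefficient
  b <- sqrt(1 - a^2)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed %% .Machine$integer.max))

  frames <- array(0, dim = c(ny, nx, nt))
  prev <- matrix(stats::rnorm(ny * nx), ny, nx)
  for (k in seq_len(nt)) {
    if (k > 1)
      prev <- a * prev + b * matrix(stats::rnorm(ny * nx), ny, nx)
    sm <- Re(stats::fft(stats::fft(prev) * H, inverse = TRUE)) / (ny * nx)
    frames[, , k] <- sm
  }
  # normalise the filtered field to unit variance before the envelope
  frames <- frames / stats::sd(frames)
  t <- (seq_len(nt) - 1) * dt
  env <- 1 - contrast_mod_depth / 2 +
    (contrast_mod_depth / 2) * sin(2 * pi * t / contrast_mod_period)
  frames <- sweep(frames, 3, env, `*`)
  frames[frames > 3] <- 3
  frames[frames < -3] <- -3
  frames <- 0.5 + frames / 6

  new_stimulus_movie(frames, frame_rate, geometry,
                     list(kind = "noise", seed = seed,
                          spatial_corr = spatial_corr,
                          temporal_corr = temporal_corr,
                          contrast_mod_period = contrast_mod_period,
                          contrast_mod_depth = contrast_mod_depth))
}

# save/restore the global RNG state so seeded generators do not perturb the
# caller's random stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old))
    assign(".Random.seed", old, envir = globalenv())
}

#' Contrast frames of a movie
#'
#' Returns luminance minus mid-gray as an `(n_pixels, n_frames)` matrix,
#' the representation used by the filtering and STA code.
#' @param movie a `stimulus_movie`.
#' @return matrix with `ny * nx` rows (column-major pixel order) and one
#'   column per frame.
#' @export
contrast_matrix <- function(movie) {
  d <- dim(movie$frames)
  matrix(movie$frames - 0.5, d[1] * d[2], d[3])
}

#' The 12-direction protocol grid
#' @return numeric vector `c(0, 30, ..., 330)`.
#' @export
protocol_directions <- function() seq(0, 330, by = 30)
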