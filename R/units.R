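#' Space-time drifting Gabor filter
#'
#' A spatial Gabor whose carrier phase advances across time lags at the
#' temporal frequency `tf`, i.e. an edge detector oriented in space-time and
#' hence direction selective. The envelope is elliptical: `aspect_ratio` is
#' the ratio of its extent along the orientation axis (parallel to the edge)
#' to its extent across it (along the drift direction). High aspect ratios
#' give elongated, sharply direction-tuned filters; low aspect ratios give
#' "blobby" filters — short, compact subfields with broad orientation and
#' spatial-frequency bandwidth. `envelope_sigma` is the sigma across the edge
#' (along the drift direction); the sigma along the edge is
#' `aspect_ratio * envelope_sigma`.
#'
#' Lags are ordered from spike time backwards: lag k spans
#' `(k-1)*lag_step` seconds before the response. A raised-cosine temporal
#' envelope peaking at `peak_lag` windows the carrier so that recent frames
#' dominate. With `tf = 0` the filter is identical at every lag (space-time
#' separable, not direction selective).
#'
#' @param pref_direction preferred drift direction, degrees (0 = rightward,
#'   counter-clockwise positive).
#' @param sf carrier spatial frequency, cycles/degree.
#' @param tf preferred temporal frequency, Hz (rate of phase advance across
#'   lags).
#' @param aspect_ratio envelope elongation along the edge axis (> 0).
#' @param envelope_sigma envelope sigma across the edge, degrees.
#' @param n_lags number of time lags (default 10).
#' @param lag_step lag spacing, seconds (default one noise frame, 1/30 s).
#' @param geometry a [display_geometry()].
#' @param phase carrier phase at the envelope centre for lag 1, radians.
#' @param center optional RF centre `c(x, y)` in degrees (default display
#'   centre).
#' @param peak_lag lag (seconds) at which the temporal envelope peaks.
#' @return a `space_time_filter`: list with `weights` array `(ny, nx, n_lags)`
#'   normalised to unit L2 norm, `lag_step`, `n_lags`, `geometry` and the
#'   construction parameters.
#' @export
make_drifting_gabor_filter <- function(pref_direction, sf = 0.02, tf = 2,
                                       aspect_ratio = 3, envelope_sigma = 8,
                                       n_lags = 10, lag_step = 1 / 30,
                                       geometry = display_geometry(),
                                       phase = 0, center = c(0, 0),
                                       peak_lag = 0.1) {
  stopifnot(aspect_ratio > 0, sf > 0, tf >= 0, envelope_sigma > 0,
            n_lags >= 1, lag_step > 0)
  sigma_along <- envelope_sigma * aspect_ratio  # parallel to the edge
  sigma_across <- envelope_sigma                # along the drift direction
  if (4 * max(sigma_along, sigma_across) >
      max(geometry$azimuth_extent, geometry$elevation_extent))
    stop("filter envelope exceeds the display extent")
  th <- (pref_direction %% 360) * pi / 180
  X <- outer(rep(1, geometry$ny), geometry$x_deg - center[1])
  Y <- outer(geometry$y_deg - center[2], rep(1, geometry$nx))
  u <- X * cos(th) + Y * sin(th)   # across the edge, along drift
  v <- -X * sin(th) + Y * cos(th)  # along the edge
  env <- exp(-(u^2 / (2 * sigma_across^2) + v^2 / (2 * sigma_along^2)))
  lag_t <- (seq_len(n_lags) - 1) * lag_step
  # raised-cosine temporal window over the lag span, peaking at peak_lag
  span <- max(lag_t[n_lags], lag_step)
  tw <- 0.5 * (1 + cos(pi * pmin(abs(lag_t - peak_lag) / (0.75 * span), 1)))
  w <- array(0, dim = c(geometry$ny, geometry$nx, n_lags))
  for (k in seq_len(n_lags))
    w[, , k] <- tw[k] * env * cos(2 * pi * sf * u + phase +
                                    2 * pi * tf * lag_t[k])
  w <- w / sqrt(sum(w^2))
  f <- list(weights = w, lag_step = lag_step, n_lags = n_lags,
            geometry = geometry,
            params = list(pref_direction = pref_direction %% 360, sf = sf,
                          tf = tf, aspect_ratio = aspect_ratio,
                          envelope_sigma = envelope_sigma, phase = phase,
                          center = center, peak_lag = peak_lag))
  class(f) <- "space_time_filter"
  f
}

rectify_power <- function(x, exponent = 1, threshold = 0) {
  pmax(x - threshold, 0)^exponent
}

#' Drive of a space-time filter to a movie
#'
#' Linear stage of the LN cascade: for each movie frame t, the sum over lags
#' and pixels of filter weights times contrast (luminance minus 0.5) of the
#' frame nearest to `t - (k-1)*lag_step`. Frames before stimulus onset are
#' treated as mid-gray (zero contrast).
#'
#' @param filter a `space_time_filter` (or plain weights array with matching
#'   geometry).
#' @param movie a `stimulus_movie` with the same geometry.
#' @return numeric vector, one drive value per frame.
#' @export
filter_drive <- function(filter, movie) {
  if (!same_geometry(filter$geometry, movie$geometry))
    stop("filter and movie geometry differ")
  C <- contrast_matrix(movie)
  nt <- ncol(C)
  npix <- nrow(C)
  W <- matrix(filter$weights, npix, filter$n_lags)
  # lag k reaches back round((k-1)*lag_step*frame_rate) movie frames
  lag_frames <- round((seq_len(filter$n_lags) - 1) *
                        filter$lag_step * movie$frame_rate)
  drive <- numeric(nt)
  for (k in seq_len(filter$n_lags)) {
    L <- lag_frames[k]
    if (L >= nt) next
    idx <- seq_len(nt - L)
    drive[idx + L] <- drive[idx + L] + crossprod(W[, k], C[, idx, drop = FALSE])
  }
  drive
}

#' Construct a synthetic model neuron
#'
#' Four kinds are available, each with a known ground-truth mechanism:
#' \describe{
#'   \item{`ln_component`}{a single high-aspect-ratio drifting Gabor filter
#'     followed by a rectifying nonlinearity: a classical direction-selective
#'     edge detector expected to show component behaviour.}
#'   \item{`ln_blobby`}{the same LN cascade with a low-aspect-ratio (blobby)
#'     filter, whose broad tuning merges the two plaid peaks and mimics
#'     pattern behaviour despite being purely linear.}
#'   \item{`energy_complex`}{sum of squared outputs of a quadrature pair of
#'     Gabor filters: phase-invariant (complex-like) responses.}
#'   \item{`pooled_pattern`}{a genuinely nonlinear motion integrator: two
#'     phase-invariant (quadrature-energy) component channels at the plaid
#'     component directions (preferred direction +/- cross_angle/2) combined
#'     multiplicatively (geometric mean of the two energy envelopes — a
#'     coincidence detector for the joint presence of both components), plus
#'     a direct channel at the preferred direction whose contrast threshold
#'     is set so that it responds to full-contrast gratings but much less to
#'     half-contrast plaid components; the direct channel carries the
#'     grating tuning, the coincidence channel the plaid tuning, and both
#'     peak at the preferred direction. Subunit spatial phases are
#'     randomised, so no single linear filter summarises the unit.}
#' }
#'
#' The output gain is calibrated so that the time-averaged response to the
#' unit's preferred full-contrast grating is `target_peak_rate` above
#' baseline. Units additionally carry a noise-adapted operating point
#' (contrast adaptation): when driven by correlated noise movies — whose
#' drive fluctuations are more than an order of magnitude weaker than a
#' matched full-contrast grating — the rectification threshold is set
#' relative to the noise drive SD and the gain is recalibrated so the mean
#' noise-evoked rate is `target_noise_rate`. This mirrors the contrast gain
#' control of real visual neurons and keeps both the tuning battery and the
#' reverse-correlation stimulation in a realistic firing regime.
#'
#' @param kind one of `"ln_component"`, `"ln_blobby"`, `"energy_complex"`,
#'   `"pooled_pattern"`.
#' @param pref_direction preferred direction, degrees.
#' @param sf,tf preferred spatial (cpd) and temporal (Hz) frequency.
#' @param aspect_ratio filter aspect ratio; defaults: 3 for component-type
#'   filters, 0.3 for `ln_blobby`.
#' @param envelope_sigma envelope scale in degrees (see
#'   [make_drifting_gabor_filter()]).
#' @param geometry a [display_geometry()].
#' @param exponent rectification exponent of the output nonlinearity
#'   (default 2: an expansive half-squaring power law, the standard model of
#'   the cortical spike threshold).
#' @param threshold_frac rectification threshold of LN units as a fraction of
#'   the peak drive to the preferred full-contrast grating (iceberg effect;
#'   default 0.2).
#' @param baseline_rate spontaneous rate, spikes/s.
#' @param target_peak_rate calibrated mean evoked rate at the preferred
#'   grating, spikes/s above baseline.
#' @param pooling for `pooled_pattern`: list with `cross_angle` (deg),
#'   `center_gain` (weight of the direct channel), `center_threshold_frac`
#'   (contrast threshold of the direct channel as a fraction of its peak
#'   drive to the preferred full-contrast grating, so half-contrast plaid
#'   components barely drive it) and `plaid_to_grating_ratio` (the weight of
#'   the coincidence channel is calibrated so the preferred-plaid response
#'   is this fraction of the preferred-grating response, giving the mild
#'   cross-orientation suppression typical of real units).
#' @param seed integer seed controlling the randomised subunit phases.
#' @param unit_id optional identifier.
#' @param target_noise_rate mean evoked rate on reference noise, spikes/s.
#' @param noise_threshold_sd noise-regime rectification threshold in units
#'   of the noise drive SD.
#' @param noise_reference_movie a noise `stimulus_movie` used to calibrate
#'   the noise operating point (a default 10-s movie is generated when
#'   omitted).
#' @return a `model_unit` object.
#' @export
make_unit <- function(kind = c("ln_component", "ln_blobby", "energy_complex",
                               "pooled_pattern"),
                      pref_direction = 0, sf = 0.02, tf = 2,
                      aspect_ratio = NULL, envelope_sigma = 8,
                      geometry = display_geometry(),
                      exponent = 2, threshold_frac = 0.2,
                      baseline_rate = 2, target_peak_rate = 30,
                      pooling = list(cross_angle = 120, center_gain = 3,
                                     center_threshold_frac = 0.4,
                                     plaid_to_grating_ratio = 0.8),
                      seed = 1, unit_id = NULL,
                      target_noise_rate = 10, noise_threshold_sd = 0.5,
                      noise_reference_movie = NULL) {
  kind <- match.arg(kind)
  if (is.null(aspect_ratio))
    aspect_ratio <- if (kind == "ln_blobby") 0.5 else 3
  # a blobby RF must be compact relative to its carrier wavelength, so its
  # envelope scales with 1/sf (8 degrees at 0.02 cpd)
  if (kind == "ln_blobby" && missing(envelope_sigma))
    envelope_sigma <- 0.2 / sf
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed %% .Machine$integer.max))

  mk <- function(dir, phase)
    make_drifting_gabor_filter(dir, sf, tf, aspect_ratio, envelope_sigma,
                               geometry = geometry, phase = phase)
  filters <- switch(kind,
    ln_component = ,
    ln_blobby = list(mk(pref_direction, 0)),
    energy_complex = list(mk(pref_direction, 0), mk(pref_direction, pi / 2)),
    pooled_pattern = {
      ca <- pooling$cross_angle
      phm <- stats::runif(1, 0, 2 * pi)
      php <- stats::runif(1, 0, 2 * pi)
      list(minus = mk(pref_direction - ca / 2, phm),
           minus_q = mk(pref_direction - ca / 2, phm + pi / 2),
           center = mk(pref_direction, stats::runif(1, 0, 2 * pi)),
           plus = mk(pref_direction + ca / 2, php),
           plus_q = mk(pref_direction + ca / 2, php + pi / 2))
    })

  pref <- make_grating(pref_direction, sf, tf, 1, 1.5, 60, geometry)
  threshold <- 0
  if (kind %in% c("ln_component", "ln_blobby"))
    threshold <- threshold_frac * max(filter_drive(filters[[1]], pref))
  if (kind == "pooled_pattern") {
    pooling$center_threshold <- (pooling$center_threshold_frac %||% 0.4) *
      max(filter_drive(filters$center, pref))
    # calibrate the coincidence-channel weight so the preferred plaid evokes
    # plaid_to_grating_ratio of the preferred-grating response
    pref_plaid <- make_plaid(pref_direction, pooling$cross_angle, 0.5,
                             sf, tf, 1.5, 60, geometry)
    e_and <- mean(sqrt(
      (filter_drive(filters$minus, pref_plaid)^2 +
         filter_drive(filters$minus_q, pref_plaid)^2) *
        (filter_drive(filters$plus, pref_plaid)^2 +
           filter_drive(filters$plus_q, pref_plaid)^2)))
    g_resp <- (pooling$center_gain %||% 3) *
      mean(rectify_power(filter_drive(filters$center, pref),
                         exponent, pooling$center_threshold))
    ratio <- pooling$plaid_to_grating_ratio %||% 0.8
    pooling$and_gain <- if (e_and > 0) ratio * g_resp / e_and else 1
  }
  unit <- list(unit_id = unit_id %||% paste0(kind, "_", seed),
               kind = kind, filters = filters,
               nonlinearity = list(exponent = exponent, threshold = threshold),
               pooling = if (kind == "pooled_pattern") pooling else NULL,
               gain = 1, baseline_rate = baseline_rate,
               geometry = geometry,
               ground_truth_label = switch(kind,
                 ln_component = "component", ln_blobby = "blobby_linear",
                 energy_complex = "complex", pooled_pattern = "pattern"),
               params = list(pref_direction = pref_direction %% 360, sf = sf,
                             tf = tf, aspect_ratio = aspect_ratio,
                             envelope_sigma = envelope_sigma, seed = seed))
  class(unit) <- "model_unit"

  # calibrate the gain on the preferred full-contrast grating
  drive <- unit_drive(unit, pref)
  m <- mean(drive)
  unit$gain <- if (m > 0) target_peak_rate / m else 1

  # noise-adapted operating point (contrast adaptation)
  if (is.null(noise_reference_movie))
    noise_reference_movie <- make_noise_movie(seed = 777, duration = 10,
                                              frame_rate = 30,
                                              geometry = geometry)
  drv <- lapply(unit$filters, filter_drive, movie = noise_reference_movie)
  unit$noise_thresholds <- vapply(drv, function(d)
    noise_threshold_sd * stats::sd(d), numeric(1))
  unit$noise_gain <- 1
  mn <- mean(unit_drive(unit, noise_reference_movie, regime = "noise"))
  unit$noise_gain <- if (mn > 0) target_noise_rate / mn else 1
  unit
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.model_unit <- function(x, ...) {
  cat(sprintf("<model_unit> %s (%s), pref %g deg, sf %g cpd, tf %g Hz\n",
              x$unit_id, x$kind, x$params$pref_direction, x$params$sf,
              x$params$tf))
  invisible(x)
}

# nonlinear drive (before gain and baseline), one value per frame;
# regime "noise" uses the noise-adapted thresholds
unit_drive <- function(unit, movie, regime = c("parametric", "noise")) {
  regime <- match.arg(regime)
  nl <- unit$nonlinearity
  thr <- function(k) {
    if (regime == "noise") return(unit$noise_thresholds[k] %||% 0)
    if (unit$kind == "pooled_pattern") return(0)
    nl$threshold
  }
  N <- function(x, k) rectify_power(x, nl$exponent, thr(k))
  D <- lapply(unit$filters, filter_drive, movie = movie)
  switch(unit$kind,
    ln_component = ,
    ln_blobby = N(D[[1]], 1),
    energy_complex = D[[1]]^2 + D[[2]]^2,
    pooled_pattern = {
      e_minus <- D[[1]]^2 + D[[2]]^2
      e_plus <- D[[4]]^2 + D[[5]]^2
      ctr_thr <- if (regime == "noise") unit$noise_thresholds[3] %||% 0
                 else unit$pooling$center_threshold
      unit$pooling$and_gain * sqrt(e_minus * e_plus) +
        unit$pooling$center_gain *
          rectify_power(D[[3]], nl$exponent, ctr_thr)
    })
}

#' Instantaneous firing rate of a model unit for a movie
#'
#' `rate(t) = baseline_rate + gain * drive(t)` where the drive is the unit's
#' nonlinear function of its filter outputs; rates are non-negative by
#' construction.
#'
#' @param unit a `model_unit`.
#' @param movie a `stimulus_movie` with matching geometry.
#' @return numeric vector of rates (spikes/s), one per movie frame.
#' @export
simulate_rate <- function(unit, movie) {
  if (!same_geometry(unit$geometry, movie$geometry))
    stop("unit and movie geometry differ")
  noise <- identical(movie$meta$kind, "noise")
  gain <- if (noise) unit$noise_gain %||% unit$gain else unit$gain
  unit$baseline_rate +
    gain * unit_drive(unit, movie, if (noise) "noise" else "parametric")
}

#' Poisson spike trains from a rate trace
#'
#' Inhomogeneous Poisson process, piecewise constant over frames: per trial
#' and frame, a Poisson count with mean `rate * dt` is drawn and spike times
#' are placed uniformly within the frame. Trials are independent.
#'
#' @param rate_trace rates, spikes/s per frame (non-negative).
#' @param frame_rate Hz of the rate trace.
#' @param n_trials number of independent repetitions.
#' @param seed integer seed; a fixed seed gives identical spike sets.
#' @return list of numeric vectors of spike times (seconds from trace onset),
#'   one per trial.
#' @export
generate_spikes <- function(rate_trace, frame_rate, n_trials = 20, seed = 1) {
  if (any(rate_trace < 0)) stop("rates must be non-negative")
  stopifnot(n_trials >= 1)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed %% .Machine$integer.max))
  dt <- 1 / frame_rate
  nt <- length(rate_trace)
  lapply(seq_len(n_trials), function(i) {
    counts <- stats::rpois(nt, rate_trace * dt)
    if (sum(counts) == 0) return(numeric(0))
    sort(rep((seq_len(nt) - 1) * dt, counts) +
           stats::runif(sum(counts), 0, dt))
  })
}
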