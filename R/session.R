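#' Default stimulation protocol
#'
#' The full battery: 20 trials of 1.5-s full-contrast gratings and
#' half-contrast-component 120-degree plaids at 2 SFs x 2 TFs x 12
#' directions (60 Hz refresh), plus 20 distinct 60-s correlated noise movies
#' at 30 Hz, all randomly interleaved with 1-s interstimulus intervals.
#' Arguments override individual fields for reduced (test-scale) runs.
#'
#' @param n_trials repetitions per parametric condition.
#' @param sfs spatial frequencies, cycles/degree.
#' @param tfs temporal frequencies, Hz.
#' @param duration parametric stimulus duration, seconds.
#' @param frame_rate parametric stimulus refresh, Hz.
#' @param cross_angle plaid cross angle, degrees.
#' @param isi interstimulus interval, seconds.
#' @param n_noise number of noise movies.
#' @param noise_duration seconds per noise movie.
#' @param noise_frame_rate Hz.
#' @param noise_params list passed to [make_noise_movie()]
#'   (`spatial_corr`, `temporal_corr`, `contrast_mod_period`,
#'   `contrast_mod_depth`).
#' @return list of protocol parameters.
#' @export
default_protocol <- function(n_trials = 20, sfs = c(0.02, 0.04),
                             tfs = c(2, 6), duration = 1.5, frame_rate = 60,
                             cross_angle = 120, isi = 1,
                             n_noise = 20, noise_duration = 60,
                             noise_frame_rate = 30,
                             noise_params = list(spatial_corr = 6,
                                                 temporal_corr = 0.05,
                                                 contrast_mod_period = 10,
                                                 contrast_mod_depth = 0.8)) {
  list(n_trials = n_trials, sfs = sfs, tfs = tfs, duration = duration,
       frame_rate = frame_rate, cross_angle = cross_angle, isi = isi,
       n_noise = n_noise, noise_duration = noise_duration,
       noise_frame_rate = noise_frame_rate, noise_params = noise_params)
}

#' Default synthetic population
#'
#' Counts per unit kind plus shared unit parameters. Preferred directions
#' tile the 12-direction grid; each unit's preferred SF and TF are drawn
#' from the protocol grid.
#'
#' @param n_component,n_blobby,n_pattern,n_complex unit counts.
#' @param baseline_rate spontaneous rate, spikes/s.
#' @param target_peak_rate calibrated preferred-grating rate, spikes/s.
#' @return list describing the population.
#' @export
default_population <- function(n_component = 20, n_blobby = 10,
                               n_pattern = 10, n_complex = 10,
                               baseline_rate = 2, target_peak_rate = 30) {
  list(n_component = n_component, n_blobby = n_blobby,
       n_pattern = n_pattern, n_complex = n_complex,
       baseline_rate = baseline_rate, target_peak_rate = target_peak_rate)
}

# drive of many filters to one movie at once (BLAS-batched over filters);
# returns (n_filters x n_frames)
batch_filter_drive <- function(filters, movie) {
  C <- contrast_matrix(movie)
  nt <- ncol(C); npix <- nrow(C)
  nf <- length(filters)
  n_lags <- filters[[1]]$n_lags
  lag_frames <- round((seq_len(n_lags) - 1) *
                        filters[[1]]$lag_step * movie$frame_rate)
  drives <- matrix(0, nf, nt)
  for (k in seq_len(n_lags)) {
    W <- vapply(filters, function(f) as.numeric(f$weights[, , k]),
                numeric(npix))
    L <- lag_frames[k]
    if (L >= nt) next
    idx <- seq_len(nt - L)
    drives[, idx + L] <- drives[, idx + L] +
      crossprod(W, C[, idx, drop = FALSE])
  }
  drives
}

# rates for every unit on one movie, via one batched drive computation
population_rates <- function(units, movie) {
  filters <- list(); owner <- integer(0)
  for (i in seq_along(units)) {
    fs <- units[[i]]$filters
    filters <- c(filters, unname(fs))
    owner <- c(owner, rep(i, length(fs)))
  }
  D <- batch_filter_drive(filters, movie)
  noise <- identical(movie$meta$kind, "noise")
  rates <- matrix(0, length(units), ncol(D))
  for (i in seq_along(units)) {
    u <- units[[i]]
    rows <- which(owner == i)
    nl <- u$nonlinearity
    thr <- function(k) {
      if (noise) return(u$noise_thresholds[k] %||% 0)
      if (u$kind == "pooled_pattern") return(0)
      nl$threshold
    }
    N <- function(x, k) rectify_power(x, nl$exponent, thr(k))
    drive <- switch(u$kind,
      ln_component = , ln_blobby = N(D[rows[1], ], 1),
      energy_complex = D[rows[1], ]^2 + D[rows[2], ]^2,
      pooled_pattern = {
        e_minus <- D[rows[1], ]^2 + D[rows[2], ]^2
        e_plus <- D[rows[4], ]^2 + D[rows[5], ]^2
        ctr_thr <- if (noise) u$noise_thresholds[3] %||% 0
                   else u$pooling$center_threshold
        u$pooling$and_gain * sqrt(e_minus * e_plus) +
          u$pooling$center_gain *
            rectify_power(D[rows[3], ], nl$exponent, ctr_thr)
      })
    gain <- if (noise) u$noise_gain %||% u$gain else u$gain
    rates[i, ] <- u$baseline_rate + gain * drive
  }
  rates
}

#' Simulate a complete synthetic recording session
#'
#' Builds a population of model units, runs the full stimulation protocol
#' (gratings, plaids, noise movies in seeded random order with 1-s ISIs),
#' and draws inhomogeneous Poisson spike trains for every unit, plus
#' baseline spiking in the interstimulus intervals. The result carries the
#' ground-truth table needed to test classification recovery.
#'
#' @param population a [default_population()] list.
#' @param protocol a [default_protocol()] list.
#' @param geometry a [display_geometry()].
#' @param seed master seed; the whole session is a deterministic function of
#'   it.
#' @param noiseless_rates keep the per-condition noiseless rate traces in the
#'   result (used by ground-truth oracles).
#' @return a `session` object: list with `units`, `ground_truth`
#'   (data.frame), `trials` (data.frame with columns `trial_id`, `kind`,
#'   `direction`, `sf`, `tf`, `onset`, `offset`, `noise_seed`), `spikes`
#'   (list of absolute spike-time vectors per unit), `noise_seeds`,
#'   `protocol`, `geometry`, `seed`, and (optionally) `rates`.
#' @export
make_session <- function(population = default_population(),
                         protocol = default_protocol(),
                         geometry = display_geometry(),
                         seed = 1, noiseless_rates = TRUE) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed %% .Machine$integer.max))
  dirs <- protocol_directions()

  kinds <- rep(c("ln_component", "ln_blobby", "pooled_pattern",
                 "energy_complex"),
               c(population$n_component, population$n_blobby,
                 population$n_pattern, population$n_complex))
  n_units <- length(kinds)
  if (n_units == 0) stop("empty population")
  noise_ref <- do.call(make_noise_movie,
                       c(list(seed = 777, duration = 10,
                              frame_rate = protocol$noise_frame_rate,
                              geometry = geometry),
                         protocol$noise_params))
  units <- vector("list", n_units)
  for (i in seq_len(n_units)) {
    # blobby RFs are compact relative to their carrier wavelength and are
    # therefore modelled as low-SF-preferring
    sf_i <- if (kinds[i] == "ln_blobby") min(protocol$sfs)
            else sample(protocol$sfs, 1)
    units[[i]] <- make_unit(
      kinds[i],
      pref_direction = dirs[(i - 1) %% 12 + 1],
      sf = sf_i, tf = sample(protocol$tfs, 1),
      geometry = geometry,
      baseline_rate = population$baseline_rate,
      target_peak_rate = population$target_peak_rate,
      pooling = list(cross_angle = protocol$cross_angle, and_gain = 5,
                     center_gain = 3, center_threshold_frac = 0.4),
      seed = seed * 1000 + i,
      unit_id = sprintf("u%03d", i),
      noise_reference_movie = noise_ref)
  }
  ground_truth <- data.frame(
    unit_id = vapply(units, `[[`, character(1), "unit_id"),
    kind = kinds,
    ground_truth_label = vapply(units, `[[`, character(1),
                                "ground_truth_label"),
    pref_direction = vapply(units, function(u) u$params$pref_direction,
                            numeric(1)),
    sf = vapply(units, function(u) u$params$sf, numeric(1)),
    tf = vapply(units, function(u) u$params$tf, numeric(1)))

  # parametric conditions and noiseless rate traces
  conds <- expand.grid(kind = c("grating", "plaid"), sf = protocol$sfs,
                       tf = protocol$tfs, direction = dirs,
                       stringsAsFactors = FALSE)
  cond_key <- function(kind, sf, tf, direction)
    sprintf("%s_sf%g_tf%g_d%g", kind, sf, tf, direction)
  rates <- vector("list", nrow(conds))
  names(rates) <- with(conds, cond_key(kind, sf, tf, direction))
  for (j in seq_len(nrow(conds))) {
    m <- if (conds$kind[j] == "grating")
      make_grating(conds$direction[j], conds$sf[j], conds$tf[j], 1,
                   protocol$duration, protocol$frame_rate, geometry)
    else
      make_plaid(conds$direction[j], protocol$cross_angle, 0.5,
                 conds$sf[j], conds$tf[j], protocol$duration,
                 protocol$frame_rate, geometry)
    rates[[j]] <- population_rates(units, m)
  }

  # trial table: parametric trials + noise epochs, in seeded random order
  par_trials <- conds[rep(seq_len(nrow(conds)), each = protocol$n_trials), ]
  noise_seeds <- seed * 10000 + seq_len(protocol$n_noise)
  noise_trials <- if (protocol$n_noise > 0)
    data.frame(kind = "noise", sf = NA_real_, tf = NA_real_,
               direction = NA_real_, noise_seed = noise_seeds)
  else NULL
  par_trials$noise_seed <- NA_real_
  all_trials <- rbind(par_trials, noise_trials)
  all_trials <- all_trials[sample(nrow(all_trials)), ]
  dur <- ifelse(all_trials$kind == "noise", protocol$noise_duration,
                protocol$duration)
  all_trials$onset <- protocol$isi + c(0, cumsum(dur + protocol$isi))[seq_len(nrow(all_trials))]
  all_trials$offset <- all_trials$onset + dur
  all_trials$trial_id <- seq_len(nrow(all_trials))
  rownames(all_trials) <- NULL

  # spikes: parametric trials from cached rates, noise epochs from fresh
  # rate simulations, ISIs at baseline
  spikes <- vector("list", n_units)
  for (i in seq_len(n_units)) spikes[[i]] <- list()
  for (r in seq_len(nrow(all_trials))) {
    tr <- all_trials[r, ]
    if (tr$kind == "noise") next
    R <- rates[[cond_key(tr$kind, tr$sf, tr$tf, tr$direction)]]
    dt <- 1 / protocol$frame_rate
    for (i in seq_len(n_units)) {
      counts <- stats::rpois(ncol(R), R[i, ] * dt)
      ns <- sum(counts)
      if (ns > 0)
        spikes[[i]][[length(spikes[[i]]) + 1]] <-
          tr$onset + rep((seq_len(ncol(R)) - 1) * dt, counts) +
          stats::runif(ns, 0, dt)
    }
  }
  noise_rows <- which(all_trials$kind == "noise")
  for (r in noise_rows) {
    tr <- all_trials[r, ]
    m <- do.call(make_noise_movie,
                 c(list(seed = tr$noise_seed,
                        duration = protocol$noise_duration,
                        frame_rate = protocol$noise_frame_rate,
                        geometry = geometry),
                   protocol$noise_params))
    R <- population_rates(units, m)
    dt <- 1 / protocol$noise_frame_rate
    for (i in seq_len(n_units)) {
      counts <- stats::rpois(ncol(R), R[i, ] * dt)
      ns <- sum(counts)
      if (ns > 0)
        spikes[[i]][[length(spikes[[i]]) + 1]] <-
          tr$onset + rep((seq_len(ncol(R)) - 1) * dt, counts) +
          stats::runif(ns, 0, dt)
    }
  }
  # baseline spiking between stimuli (homogeneous Poisson in each ISI)
  total_end <- max(all_trials$offset) + protocol$isi
  gaps <- data.frame(start = c(0, all_trials$offset),
                     end = c(all_trials$onset, total_end))
  for (i in seq_len(n_units)) {
    br <- units[[i]]$baseline_rate
    for (gidx in seq_len(nrow(gaps))) {
      glen <- gaps$end[gidx] - gaps$start[gidx]
      if (glen <= 0 || br <= 0) next
      nsp <- stats::rpois(1, br * glen)
      if (nsp > 0)
        spikes[[i]][[length(spikes[[i]]) + 1]] <-
          gaps$start[gidx] + sort(stats::runif(nsp, 0, glen))
    }
    spikes[[i]] <- sort(unlist(spikes[[i]], use.names = FALSE)) %||% numeric(0)
  }

  s <- list(units = units, ground_truth = ground_truth,
            trials = all_trials, spikes = spikes,
            noise_seeds = noise_seeds, protocol = protocol,
            geometry = geometry, seed = seed,
            rates = if (noiseless_rates) rates else NULL)
  class(s) <- "session"
  s
}

#' @export
print.session <- function(x, ...) {
  cat(sprintf("<session> %d units, %d trials (%d noise), seed %s\n",
              length(x$units), nrow(x$trials),
              sum(x$trials$kind == "noise"), format(x$seed)))
  invisible(x)
}

#' Noiseless tuning curve of a model unit from cached session rates
#'
#' Ground-truth tuning (no Poisson noise): the time-averaged evoked rate per
#' direction from the rate traces stored in the session.
#'
#' @param session a `session` made with `noiseless_rates = TRUE`.
#' @param unit_index integer position of the unit.
#' @param stimulus_class `"grating"` or `"plaid"`.
#' @param sf,tf condition.
#' @return numeric 12-vector of evoked rates (spikes/s above baseline).
#' @export
noiseless_tuning <- function(session, unit_index, stimulus_class, sf, tf) {
  if (is.null(session$rates)) stop("session lacks cached rates")
  dirs <- protocol_directions()
  base <- session$units[[unit_index]]$baseline_rate
  vapply(dirs, function(d) {
    key <- sprintf("%s_sf%g_tf%g_d%g", stimulus_class, sf, tf, d)
    mean(session$rates[[key]][unit_index, ]) - base
  }, numeric(1))
}

#' Synthetic regressor bank of reference tuning curves
#'
#' A pool of idealised unit tuning curves used as predictors in linear
#' models of a neuron's direction tuning (a synthetic stand-in for the unit
#' pools of a pretrained motion network). Members are circular von
#' Mises-shaped grating curves with preferred directions tiling the
#' 12-direction grid and seeded random widths; plaid curves follow the
#' member's class: component members respond to the two plaid components
#' (peaks at +/- half the cross angle), pattern members share their grating
#' tuning, and "unclassified" members are heterogeneous mixtures constructed
#' to fail both classification criteria. Each member is a peak-normalised
#' 24-vector (12 grating + 12 plaid bins).
#'
#' @param n_units bank size (>= 12 for full direction coverage).
#' @param class `"component"`, `"pattern"` or `"unclassified"`.
#' @param seed integer seed.
#' @param cross_angle plaid cross angle, degrees.
#' @param noise_sd multiplicative response variability of the members.
#' @return a `regressor_bank`: list with `curves` (`n_units` x 24 matrix),
#'   `class`, `pref_directions`.
#' @export
make_regressor_bank <- function(n_units = 24,
                                class = c("component", "pattern",
                                          "unclassified"),
                                seed = 1, cross_angle = 120,
                                noise_sd = 0.05) {
  class <- match.arg(class)
  if (n_units < 12) stop("need at least 12 units for direction coverage")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed %% .Machine$integer.max))
  dirs <- protocol_directions()
  prefs <- dirs[(seq_len(n_units) - 1) %% 12 + 1]
  curves <- matrix(0, n_units, 24)
  vm <- function(theta0, kappa)
    exp(kappa * (cos((dirs - theta0) * pi / 180) - 1))
  for (i in seq_len(n_units)) {
    ok <- FALSE; attempt <- 0
    while (!ok) {
      attempt <- attempt + 1
      kappa <- stats::runif(1, 2.5, 5)
      g <- vm(prefs[i], kappa)
      p <- switch(class,
        component = vm(prefs[i] - cross_angle / 2, kappa) +
                    vm(prefs[i] + cross_angle / 2, kappa),
        pattern = g,
        unclassified = {
          w <- stats::runif(1, 0.35, 0.65)
          w * g + (1 - w) * (vm(prefs[i] - cross_angle / 2, kappa) +
                               vm(prefs[i] + cross_angle / 2, kappa)) / 2 +
            0.3 * vm(stats::runif(1, 0, 360), stats::runif(1, 1, 3))
        })
      g <- pmax(g * (1 + stats::rnorm(12, 0, noise_sd)), 0)
      p <- pmax(p * (1 + stats::rnorm(12, 0, noise_sd)), 0)
      lab <- classify_pair(g, p, cross_angle)$label
      ok <- switch(class, component = lab == "component",
                   pattern = lab == "pattern",
                   unclassified = lab == "unclassified")
      if (attempt > 50) stop("could not construct a ", class, " bank member")
    }
    m <- c(g, p)
    curves[i, ] <- m / max(m)
  }
  b <- list(curves = curves, class = class, pref_directions = prefs)
  class(b) <- "regressor_bank"
  b
}
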