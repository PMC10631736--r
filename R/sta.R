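#' Spike-triggered average from one noise movie
#'
#' For each of `n_lags` time lags, the average contrast frame (luminance
#' minus mid-gray) shown `(k-1)` noise frames before each spike. Spikes are
#' assigned to the frame on screen when they occurred; spikes too early for
#' a given lag are dropped from that lag's average.
#'
#' @param spikes spike times relative to movie onset, seconds.
#' @param movie a `stimulus_movie` (kind `"noise"` in normal use).
#' @param n_lags number of lags (default 10, spanning 0 to 300 ms at 30 Hz).
#' @return list with `sum` (array `(ny, nx, n_lags)` of summed contrast
#'   frames), `count` (spikes contributing per lag) and `mean` (the STA
#'   frames, `sum/count`).
#' @export
compute_sta <- function(spikes, movie, n_lags = 10) {
  d <- dim(movie$frames)
  nt <- d[3]
  f <- floor(spikes * movie$frame_rate) + 1
  f <- f[f >= 1 & f <= nt]
  counts <- tabulate(f, nbins = nt)
  M <- contrast_matrix(movie)
  sums <- array(0, dim = c(d[1], d[2], n_lags))
  nk <- integer(n_lags)
  for (k in seq_len(n_lags)) {
    ck <- c(counts[k:nt], rep(0, k - 1))  # spikes at frame j+k-1 see frame j
    nk[k] <- sum(counts[k:nt])
    sums[, , k] <- matrix(M %*% ck, d[1], d[2])
  }
  means <- sums
  for (k in seq_len(n_lags))
    means[, , k] <- if (nk[k] > 0) sums[, , k] / nk[k] else 0
  list(sum = sums, count = nk, mean = means)
}

#' Mean spatial power spectrum of a noise ensemble
#'
#' Average squared modulus of the 2-D FFT of the contrast frames, used to
#' decorrelate STA images.
#'
#' @param movie a `stimulus_movie`.
#' @return matrix `(ny, nx)` of mean power (unshifted FFT layout).
#' @export
stimulus_power_spectrum <- function(movie) {
  d <- dim(movie$frames)
  P <- matrix(0, d[1], d[2])
  for (k in seq_len(d[3]))
    P <- P + Mod(stats::fft(movie$frames[, , k] - 0.5))^2
  P / d[3]
}

#' Decorrelate an STA frame against the stimulus spectrum
#'
#' Spatial-frequency-domain whitening: the frame's spectrum is divided by
#' the stimulus power spectrum regularised by `ridge_fraction` times its
#' maximum, then transformed back. The whitening filter is normalised to
#' unit mean so a flat (white) stimulus spectrum leaves the frame unchanged.
#'
#' @param frame matrix (an STA image).
#' @param power stimulus power spectrum from [stimulus_power_spectrum()].
#' @param ridge_fraction regularisation, fraction of the peak power.
#' @return decorrelated frame, same dimensions.
#' @export
decorrelate_sta <- function(frame, power, ridge_fraction = 0.1) {
  if (max(power) <= 0) stop("degenerate stimulus power spectrum")
  W <- 1 / (power + ridge_fraction * max(power))
  W <- W / mean(W)
  Re(stats::fft(stats::fft(frame) * W, inverse = TRUE)) / length(frame)
}

noise_epochs <- function(session) {
  session$trials[session$trials$kind == "noise", , drop = FALSE]
}

regenerate_noise_movie <- function(session, noise_seed) {
  do.call(make_noise_movie,
          c(list(seed = noise_seed,
                 duration = session$protocol$noise_duration,
                 frame_rate = session$protocol$noise_frame_rate,
                 geometry = session$geometry),
            session$protocol$noise_params))
}

#' STA receptive-field estimation with permutation z-scoring
#'
#' The full linear-RF reconstruction for one unit of a session: raw STA over
#' all noise epochs, spatial decorrelation, and pixelwise z-scoring against
#' a permutation null in which the unit's spike count is redistributed
#' uniformly over the noise epochs. Because uniformly shuffled spike times
#' remain uniform after any lag shift, a single null ensemble is shared by
#' all lags. Each null STA receives the same decorrelation as the observed
#' one. Per-lag contrast indexes (CI) and the null CI distribution are
#' attached so downstream stages can gate on RF quality.
#'
#' @param session a `session` with noise epochs.
#' @param unit_index which unit.
#' @param n_lags number of STA lags (default 10).
#' @param n_perm permutations for the null (>= 100).
#' @param ridge_fraction decorrelation ridge (see [decorrelate_sta()]).
#' @param seed RNG seed for the permutations.
#' @param min_spikes flag the result low-confidence below this spike count.
#' @return an `sta_sequence`: list with `raw_frames`, `decorr_frames`,
#'   `z_frames` (arrays `(ny, nx, n_lags)`), `lag_times`, `ci_per_lag`,
#'   `null_ci` (per-permutation CI of null frames), `n_spikes`,
#'   `n_permutations`, `seed`, `low_confidence`, `geometry`, `lag_step`.
#' @export
sta_receptive_field <- function(session, unit_index, n_lags = 10,
                                n_perm = 200, ridge_fraction = 0.1,
                                seed = 1, min_spikes = 100) {
  sta_receptive_field_multi(session, unit_index, n_lags, n_perm,
                            ridge_fraction, seed, min_spikes)[[1]]
}

#' @rdname sta_receptive_field
#' @param unit_indices integer vector of units; the noise movies are
#'   regenerated once and shared across units, which is much faster than
#'   separate calls when analysing a whole session.
#' @export
sta_receptive_field_multi <- function(session, unit_indices, n_lags = 10,
                                      n_perm = 200, ridge_fraction = 0.1,
                                      seed = 1, min_spikes = 100) {
  if (n_perm < 100) stop("n_perm must be at least 100")
  ep <- noise_epochs(session)
  if (nrow(ep) == 0) stop("session has no noise epochs")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed %% .Machine$integer.max))
  g <- session$geometry
  npix <- g$ny * g$nx
  nu <- length(unit_indices)
  durs <- ep$offset - ep$onset

  per_epoch <- lapply(unit_indices, function(ui) {
    spk <- session$spikes[[ui]]
    lapply(seq_len(nrow(ep)), function(i)
      spk[spk >= ep$onset[i] & spk < ep$offset[i]] - ep$onset[i])
  })
  n_spikes <- vapply(per_epoch, function(pe) sum(lengths(pe)), numeric(1))
  # each unit's permutations redistribute its spike count uniformly in time
  alloc <- lapply(seq_len(nu), function(j)
    stats::rmultinom(n_perm, n_spikes[j], durs / sum(durs)))

  sums <- lapply(seq_len(nu), function(j)
    array(0, dim = c(g$ny, g$nx, n_lags)))
  nk <- matrix(0L, nu, n_lags)
  P <- matrix(0, g$ny, g$nx)
  null_sum <- lapply(seq_len(nu), function(j) matrix(0, npix, n_perm))
  n_frames_tot <- 0
  for (i in seq_len(nrow(ep))) {
    movie <- regenerate_noise_movie(session, ep$noise_seed[i])
    nf <- dim(movie$frames)[3]
    P <- P + stimulus_power_spectrum(movie) * nf
    n_frames_tot <- n_frames_tot + nf
    M <- contrast_matrix(movie)
    Cbig <- matrix(0, nf, nu * n_perm)
    for (j in seq_len(nu)) {
      st <- compute_sta(per_epoch[[j]][[i]], movie, n_lags)
      sums[[j]] <- sums[[j]] + st$sum
      nk[j, ] <- nk[j, ] + st$count
      for (p in seq_len(n_perm))
        if (alloc[[j]][i, p] > 0)
          Cbig[, (j - 1) * n_perm + p] <-
            stats::rmultinom(1, alloc[[j]][i, p], rep(1, nf))
    }
    NS <- M %*% Cbig
    for (j in seq_len(nu))
      null_sum[[j]] <- null_sum[[j]] +
        NS[, (j - 1) * n_perm + seq_len(n_perm), drop = FALSE]
  }
  P <- P / n_frames_tot

  out <- vector("list", nu)
  for (j in seq_len(nu)) {
    raw <- array(0, dim = c(g$ny, g$nx, n_lags))
    for (k in seq_len(n_lags))
      raw[, , k] <- if (nk[j, k] > 0) sums[[j]][, , k] / nk[j, k] else 0
    decorr <- raw
    for (k in seq_len(n_lags))
      decorr[, , k] <- decorrelate_sta(raw[, , k], P, ridge_fraction)
    null_mean_sta <- null_sum[[j]] / max(n_spikes[j], 1)
    null_dec <- matrix(0, npix, n_perm)
    for (p in seq_len(n_perm))
      null_dec[, p] <- decorrelate_sta(
        matrix(null_mean_sta[, p], g$ny, g$nx), P, ridge_fraction)

    mu <- rowMeans(null_dec)
    sdv <- apply(null_dec, 1, stats::sd)
    zero_sd <- sdv == 0
    if (any(zero_sd)) {
      warning(sum(zero_sd), " pixels with zero null SD; z set to 0")
      sdv[zero_sd] <- Inf
    }
    z <- array(0, dim = c(g$ny, g$nx, n_lags))
    for (k in seq_len(n_lags))
      z[, , k] <- (decorr[, , k] - matrix(mu, g$ny, g$nx)) /
        matrix(sdv, g$ny, g$nx)
    z_null <- (null_dec - mu) / sdv
    null_ci <- apply(z_null, 2, function(col)
      contrast_index(matrix(col, g$ny, g$nx)))

    res <- list(
      raw_frames = raw, decorr_frames = decorr, z_frames = z,
      lag_times = (seq_len(n_lags) - 1) /
        session$protocol$noise_frame_rate,
      ci_per_lag = apply(z, 3, contrast_index),
      null_ci = null_ci, n_spikes = n_spikes[j], n_permutations = n_perm,
      seed = seed, low_confidence = n_spikes[j] < min_spikes,
      geometry = g, lag_step = 1 / session$protocol$noise_frame_rate)
    class(res) <- "sta_sequence"
    out[[j]] <- res
  }
  out
}

#' @export
print.sta_sequence <- function(x, ...) {
  cat(sprintf(
    "<sta_sequence> %d lags, %d spikes, %d perms; best CI %.2f (lag %d)\n",
    dim(x$z_frames)[3], x$n_spikes, x$n_permutations,
    max(x$ci_per_lag), which.max(x$ci_per_lag)))
  invisible(x)
}

#' Contrast index of an STA frame
#'
#' Mean of the top `top_frac` fraction of absolute z-scores in the frame: a
#' robust summary of peak RF signal, monotone in filter signal-to-noise.
#'
#' @param z_frame matrix of pixel z-scores.
#' @param top_frac fraction of pixels averaged (default 0.01).
#' @return non-negative scalar.
#' @export
contrast_index <- function(z_frame, top_frac = 0.01) {
  a <- sort(abs(z_frame), decreasing = TRUE)
  n <- max(1L, ceiling(length(a) * top_frac))
  mean(a[seq_len(n)])
}

gabor_model <- function(p, X, Y) {
  th <- p["theta"]
  u <- (X - p["x0"]) * cos(th) + (Y - p["y0"]) * sin(th)
  v <- -(X - p["x0"]) * sin(th) + (Y - p["y0"]) * cos(th)
  p["amp"] * exp(-(u^2 / (2 * p["su"]^2) + v^2 / (2 * p["sv"]^2))) *
    cos(2 * pi * p["sf"] * u + p["phase"])
}

#' Fit a 2-D Gabor function to an STA frame
#'
#' Least-squares Gabor fit with 8 orientation-seeded multi-starts
#' (Levenberg-Marquardt); the goodness of fit `r2 = 1 - SS_res / SS_tot`
#' measures how well a linear, Gabor-like RF describes the frame.
#'
#' @param z_frame matrix (z-scored STA image).
#' @param geometry matching [display_geometry()].
#' @return a `gabor_fit`: list with `center` (deg), `orientation_deg` (of
#'   the carrier axis, in [0, 180)), `sf` (cpd), `phase`, `sigma_major`,
#'   `sigma_minor` (deg), `amplitude`, `r2`, `converged`.
#' @export
fit_gabor <- function(z_frame, geometry) {
  X <- outer(rep(1, geometry$ny), geometry$x_deg)
  Y <- outer(geometry$y_deg, rep(1, geometry$nx))
  zv <- as.numeric(z_frame)
  ss_tot <- sum((zv - mean(zv))^2)
  if (ss_tot == 0) return(list(r2 = NA_real_, converged = FALSE))
  imax <- which.max(abs(z_frame))
  x0 <- X[imax]; y0 <- Y[imax]
  amp0 <- z_frame[imax]
  half_nyq <- 1 / (4 * geometry$deg_per_px)
  lower <- c(amp = -10 * abs(amp0), x0 = min(geometry$x_deg),
             y0 = min(geometry$y_deg), theta = -pi, sf = 1e-4,
             phase = -2 * pi, su = geometry$deg_per_px,
             sv = geometry$deg_per_px)
  upper <- c(amp = 10 * abs(amp0), x0 = max(geometry$x_deg),
             y0 = max(geometry$y_deg), theta = 2 * pi, sf = half_nyq,
             phase = 2 * pi, su = geometry$azimuth_extent / 2,
             sv = geometry$azimuth_extent / 2)
  best <- NULL; best_ss <- Inf
  for (th0 in seq(0, pi * 7 / 8, by = pi / 8)) {
    start <- c(amp = amp0, x0 = x0, y0 = y0, theta = th0, sf = 0.02,
               phase = 0, su = 8, sv = 12)
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = start,
        lower = lower, upper = upper,
        fn = function(p, X, Y, z) as.numeric(gabor_model(p, X, Y)) - z,
        X = X, Y = Y, z = zv,
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      ss <- sum(fit$fvec^2)
      if (ss < best_ss) { best_ss <- ss; best <- fit }
    }
  }
  if (is.null(best)) return(list(r2 = NA_real_, converged = FALSE))
  p <- best$par
  list(center = c(x = unname(p["x0"]), y = unname(p["y0"])),
       orientation_deg = (unname(p["theta"]) * 180 / pi) %% 180,
       sf = unname(p["sf"]), phase = unname(p["phase"]),
       sigma_major = max(unname(p["su"]), unname(p["sv"])),
       sigma_minor = min(unname(p["su"]), unname(p["sv"])),
       amplitude = unname(p["amp"]),
       r2 = 1 - best_ss / ss_tot,
       converged = best$info %in% 1:4)
}

# sizes of 8-connected components of a logical matrix (igraph)
label_components_8 <- function(mask) {
  idx <- which(mask)
  if (length(idx) == 0) return(integer(0))
  ny <- nrow(mask); nx <- ncol(mask)
  pos <- arrayInd(idx, dim(mask))
  lut <- matrix(0L, ny, nx)
  lut[idx] <- seq_along(idx)
  from <- integer(0); to <- integer(0)
  for (dd in list(c(1, 0), c(0, 1), c(1, 1), c(1, -1))) {
    r2 <- pos[, 1] + dd[1]; c2 <- pos[, 2] + dd[2]
    ok <- r2 >= 1 & r2 <= ny & c2 >= 1 & c2 <= nx
    nb <- integer(length(idx))
    nb[ok] <- lut[cbind(r2[ok], c2[ok])]
    has <- nb > 0
    from <- c(from, which(has)); to <- c(to, nb[has])
  }
  gr <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(from) > 0)
    gr <- igraph::add_edges(gr, as.vector(rbind(from, to)))
  igraph::components(gr)$csize
}

#' Count RF lobes in an STA sequence
#'
#' On the frame with the largest contrast index, pixels with |z| above the
#' binarisation threshold are labelled (excitatory and inhibitory pixels
#' separately) into 8-connected components; components with at least
#' `min_area` pixels count as lobes. The threshold is `threshold` z units
#' (default 3.5) or, for very high signal-to-noise frames, half the peak
#' |z| — whichever is larger — so the lobe count reflects the dominant RF
#' subfields rather than the depth of the recording.
#'
#' @param z_frames array `(ny, nx, n_lags)` or an `sta_sequence`.
#' @param threshold binarisation threshold in z units.
#' @param min_area minimum lobe area, pixels.
#' @param relative_floor fraction of the peak |z| that the threshold never
#'   drops below.
#' @return list with `best_frame` (index) and `n_lobes`.
#' @export
count_lobes <- function(z_frames, threshold = 3.5, min_area = 4,
                        relative_floor = 0.5) {
  if (inherits(z_frames, "sta_sequence")) z_frames <- z_frames$z_frames
  ci <- apply(z_frames, 3, contrast_index)
  best <- which.max(ci)
  fr <- z_frames[, , best]
  thr <- max(threshold, relative_floor * max(abs(fr)))
  n <- 0L
  for (mask in list(fr > thr, fr < -thr)) {
    sizes <- label_components_8(mask)
    n <- n + sum(sizes >= min_area)
  }
  list(best_frame = best, n_lobes = n)
}

#' Dominant spatial frequency of an STA
#'
#' Radial frequency of the peak of the 2-D amplitude spectrum of the
#' best-CI frame (computed on a zero-padded square grid, DC excluded),
#' in cycles/degree.
#'
#' @param z_frames array or `sta_sequence`.
#' @param geometry matching [display_geometry()].
#' @return spatial frequency, cpd.
#' @export
sta_spatial_frequency <- function(z_frames,
                                  geometry = attr(z_frames, "geometry")) {
  if (inherits(z_frames, "sta_sequence")) {
    geometry <- z_frames$geometry
    z_frames <- z_frames$z_frames
  }
  ci <- apply(z_frames, 3, contrast_index)
  fr <- z_frames[, , which.max(ci)]
  ny <- nrow(fr); nx <- ncol(fr)
  # zero-pad to a square grid for an isotropic, finer frequency sampling
  n <- 2 * max(nx, ny)
  pad <- matrix(0, n, n)
  pad[seq_len(ny), seq_len(nx)] <- fr
  A <- Mod(stats::fft(pad))
  f1 <- c(0:(n / 2), -((n / 2 - 1):1)) / n
  fr_rad <- sqrt(outer(f1^2, f1^2, `+`)) / geometry$deg_per_px
  A[fr_rad == 0] <- 0  # exclude DC
  fr_rad[which.max(A)]
}
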