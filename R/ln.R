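#' Predict grating/plaid tuning curves from an STA-derived filter
#'
#' The central test of linearity: the reconstructed (z-scored, interpolated)
#' STA sequence is used as the input-stage filter of a classical LN model.
#' Each of the 12 gratings and 12 plaids of the prediction battery (SF 0.02
#' cpd by default — the spatial scale best matched by STA-estimated RFs) is
#' filtered, passed through a static rectifying nonlinearity and
#' time-averaged over the presentation window, giving predicted 12-point
#' tuning curves (peak-normalised).
#'
#' @param sta an `sta_sequence` from [sta_receptive_field()] (or a plain
#'   `(ny, nx, n_lags)` array plus `geometry` and `lag_step`).
#' @param sf prediction spatial frequency, cpd.
#' @param tf prediction temporal frequency, Hz (the unit's best TF in
#'   normal use).
#' @param cross_angle plaid cross angle, degrees.
#' @param duration,frame_rate prediction stimulus parameters.
#' @param upsample integer spatial upsampling factor applied to the STA
#'   frames (bilinear interpolation) before filtering; the prediction
#'   stimuli are generated at the upsampled resolution.
#' @param exponent rectification exponent of the prediction nonlinearity
#'   (default 2, matching the half-squaring spike-threshold nonlinearity of
#'   the synthetic units; with a purely linear rectifier a centred even
#'   filter cannot express pattern-like plaid tuning at all).
#' @param threshold_frac rectification threshold as a fraction of the
#'   filter's peak grating drive over the battery (default 0.3, the upper
#'   end of the range over which noiseless ground-truth filters reproduce
#'   their own observed classification).
#' @param geometry,lag_step needed only when `sta` is a bare array.
#' @return list with `grating`, `plaid` (peak-normalised 12-vectors),
#'   `directions`, `flat` (TRUE when the filter produced no tuned response,
#'   e.g. from an all-noise STA).
#' @export
ln_predict_tuning <- function(sta, sf = 0.02, tf = 2, cross_angle = 120,
                              duration = 1.5, frame_rate = 60, upsample = 2,
                              exponent = 2, threshold_frac = 0.3,
                              geometry = NULL, lag_step = NULL) {
  if (inherits(sta, "sta_sequence")) {
    geometry <- sta$geometry
    lag_step <- sta$lag_step
    frames <- sta$z_frames
  } else frames <- sta
  n_lags <- dim(frames)[3]
  up <- as.integer(upsample)
  if (up > 1) {
    gup <- display_geometry(geometry$azimuth_extent,
                            geometry$elevation_extent,
                            geometry$nx * up, geometry$ny * up)
    f2 <- array(0, dim = c(gup$ny, gup$nx, n_lags))
    for (k in seq_len(n_lags))
      f2[, , k] <- EBImage::resize(frames[, , k], w = gup$ny, h = gup$nx)
    frames <- f2
    geometry <- gup
  }
  nrm <- sqrt(sum(frames^2))
  if (nrm == 0)
    return(list(grating = rep(0, 12), plaid = rep(0, 12),
                directions = protocol_directions(), flat = TRUE))
  filt <- list(weights = frames / nrm, lag_step = lag_step,
               n_lags = n_lags, geometry = geometry)
  class(filt) <- "space_time_filter"
  dirs <- protocol_directions()
  drv <- function(kind) lapply(dirs, function(d) {
    m <- if (kind == "grating")
      make_grating(d, sf, tf, 1, duration, frame_rate, geometry)
    else
      make_plaid(d, cross_angle, 0.5, sf, tf, duration, frame_rate, geometry)
    filter_drive(filt, m)
  })
  gd <- drv("grating"); pd <- drv("plaid")
  thr <- threshold_frac * max(0, unlist(gd))
  gcv <- vapply(gd, function(x) mean(rectify_power(x, exponent, thr)),
                numeric(1))
  pcv <- vapply(pd, function(x) mean(rectify_power(x, exponent, thr)),
                numeric(1))
  pk <- max(gcv, pcv)
  flat <- pk <= 0 || stats::sd(c(gcv, pcv)) / max(pk, 1e-12) < 1e-6
  if (pk > 0) { gcv <- gcv / pk; pcv <- pcv / pk }
  list(grating = gcv, plaid = pcv, directions = dirs, flat = flat)
}

#' Reclassify a unit from its LN-predicted tuning curves
#'
#' Applies the Zp/Zc machinery verbatim to the predicted curves, yielding
#' Zc', Zp' and the predicted label.
#'
#' @param prediction result of [ln_predict_tuning()].
#' @param cross_angle plaid cross angle, degrees.
#' @param z_crit,dsi_crit classification thresholds (see [classify_zpzc()]).
#' @return list with `zc_prime`, `zp_prime`, `pi_prime`, `predicted_label`,
#'   `flat`.
#' @export
reclassify_from_prediction <- function(prediction, cross_angle = 120,
                                       z_crit = 1.28, dsi_crit = 0.33) {
  if (isTRUE(prediction$flat) || stats::sd(prediction$grating) == 0 ||
      stats::sd(prediction$plaid) == 0)
    return(list(zc_prime = NA_real_, zp_prime = NA_real_,
                pi_prime = NA_real_, predicted_label = "unclassified",
                flat = TRUE))
  cl <- classify_pair(prediction$grating, prediction$plaid, cross_angle,
                      z_crit, dsi_crit)
  list(zc_prime = cl$zc, zp_prime = cl$zp, pi_prime = cl$pi,
       predicted_label = cl$label, flat = FALSE)
}

#' Classification transitions under LN prediction
#'
#' For each observed class, the fraction of units that kept their label
#' ("to_same"), switched to the opposite class ("to_opposite": component to
#' pattern or vice versa; for observed-unclassified units, any classified
#' outcome), or landed unclassified ("to_unclassified"). The three fractions
#' sum to one per class.
#'
#' @param observed,predicted character vectors of paired labels.
#' @return data.frame with columns `observed_label`, `n`, `to_same`,
#'   `to_opposite`, `to_unclassified`; classes absent from `observed` get
#'   `NA` fractions.
#' @export
transition_summary <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted))
  classes <- c("component", "pattern", "unclassified")
  opposite <- c(component = "pattern", pattern = "component")
  out <- data.frame(observed_label = classes, n = 0L, to_same = NA_real_,
                    to_opposite = NA_real_, to_unclassified = NA_real_)
  for (i in seq_along(classes)) {
    cls <- classes[i]
    sel <- observed == cls
    n <- sum(sel)
    out$n[i] <- n
    if (n == 0) next
    pred <- predicted[sel]
    if (cls == "unclassified") {
      out$to_same[i] <- mean(pred == "unclassified")
      out$to_opposite[i] <- mean(pred != "unclassified")
      out$to_unclassified[i] <- out$to_same[i]
      # for observed-unclassified units "same" and "unclassified" coincide;
      # report the partition as same vs any-classified
      out$to_unclassified[i] <- 0
    } else {
      out$to_same[i] <- mean(pred == cls)
      out$to_opposite[i] <- mean(pred == opposite[[cls]])
      out$to_unclassified[i] <- mean(pred == "unclassified")
    }
  }
  out
}

#' Observed-versus-predicted classification for a whole session
#'
#' Runs the full LN-prediction pipeline over the units of a session:
#' observed classification at the best SF/TF (optionally requiring
#' consistent labels at both SFs), STA estimation, LN tuning prediction at
#' the unit's best TF, and reclassification. Units whose best-frame CI is
#' below the `ci_floor_quantile` of their permutation-null CI distribution
#' are excluded from prediction (flagged, kept in the table).
#'
#' @param session a `session` with noise epochs.
#' @param n_perm STA permutations.
#' @param seed RNG seed for the STA permutation nulls.
#' @param strict require the same observed label at both SFs (with the
#'   best TF); units failing it are marked inconsistent and excluded from
#'   transition summaries.
#' @param ci_floor_quantile quantile of the null CI used as RF-quality
#'   floor.
#' @param upsample,exponent,threshold_frac passed to
#'   [ln_predict_tuning()].
#' @return data.frame, one row per unit: observed and predicted indexes,
#'   labels, transition, `ci`, `excluded`.
#' @export
ln_prediction_table <- function(session, n_perm = 200, seed = 1,
                                strict = TRUE, ci_floor_quantile = 0.95,
                                upsample = 2, exponent = 2,
                                threshold_frac = 0.3) {
  n <- length(session$units)
  stas <- sta_receptive_field_multi(session, seq_len(n), n_perm = n_perm,
                                    seed = seed)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    obs <- classify_session_unit(session, i)
    sta <- stas[[i]]
    ci <- max(sta$ci_per_lag)
    ci_floor <- stats::quantile(sta$null_ci, ci_floor_quantile)
    excluded <- ci < ci_floor || sta$low_confidence
    zc_p <- zp_p <- NA_real_
    pred_label <- NA_character_
    if (!excluded) {
      pred <- ln_predict_tuning(sta, sf = min(session$protocol$sfs),
                                tf = obs$best_tf,
                                cross_angle = session$protocol$cross_angle,
                                upsample = upsample, exponent = exponent,
                                threshold_frac = threshold_frac)
      rc <- reclassify_from_prediction(pred,
                                       session$protocol$cross_angle)
      zc_p <- rc$zc_prime; zp_p <- rc$zp_prime
      pred_label <- rc$predicted_label
    }
    rows[[i]] <- data.frame(
      unit_id = session$units[[i]]$unit_id,
      kind = session$units[[i]]$kind,
      observed_label = obs$label, consistent = obs$consistent,
      zc = obs$zc, zp = obs$zp, zc_prime = zc_p, zp_prime = zp_p,
      predicted_label = pred_label, ci = ci, ci_floor = ci_floor,
      excluded = excluded, best_sf = obs$best_sf, best_tf = obs$best_tf,
      dsi = obs$dsi)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "stas") <- stas  # reusable by RF-structure analyses
  out
}
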