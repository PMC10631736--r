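#' Ideal component prediction of the plaid tuning curve
#'
#' A perfectly component-selective unit responds to each plaid as to the two
#' gratings it is made of, so its predicted plaid response at direction theta
#' is the sum of the grating responses at `theta - cross_angle/2` and
#' `theta + cross_angle/2` (bin-exact circular indexing on the 30-degree
#' grid). The scale is irrelevant downstream because the comparison is
#' correlation based.
#'
#' @param grating_curve a `tuning_curve` or bare 12-vector.
#' @param cross_angle plaid cross angle, degrees; must be a multiple of the
#'   30-degree direction bin.
#' @return numeric 12-vector.
#' @export
component_prediction <- function(grating_curve, cross_angle = 120) {
  g <- if (inherits(grating_curve, "tuning_curve")) grating_curve$responses
       else grating_curve
  stopifnot(length(g) == 12)
  half_bins <- cross_angle / 2 / 30
  if (abs(half_bins - round(half_bins)) > 1e-9)
    stop("cross_angle must be a multiple of the 30-degree direction bin")
  s <- as.integer(round(half_bins))
  idx <- seq_len(12) - 1
  g[(idx - s) %% 12 + 1] + g[(idx + s) %% 12 + 1]
}

#' Ideal pattern prediction of the plaid tuning curve
#'
#' A perfectly pattern-selective unit is tuned to the global motion
#' direction, so its predicted plaid curve is its grating curve itself.
#'
#' @param grating_curve a `tuning_curve` or bare 12-vector.
#' @return numeric 12-vector.
#' @export
pattern_prediction <- function(grating_curve) {
  g <- if (inherits(grating_curve, "tuning_curve")) grating_curve$responses
       else grating_curve
  stopifnot(length(g) == 12)
  g
}

#' Partial correlations of observed plaid responses with the two predictions
#'
#' Standard partial-correlation form used throughout the dorsal-stream
#' literature: with `r_c`, `r_p` the Pearson correlations of the observed
#' plaid curve with the component and pattern predictions and `r_pc` the
#' correlation between the predictions,
#' `rc = (r_c - r_p * r_pc) / sqrt((1 - r_p^2) (1 - r_pc^2))` and
#' symmetrically for `rp`.
#'
#' @param observed_plaid observed plaid 12-vector (or `tuning_curve`).
#' @param comp_pred,patt_pred predicted 12-vectors from
#'   [component_prediction()] and [pattern_prediction()].
#' @return list with `rc`, `rp` (clipped to `(-1, 1)`), or `NA`s when any
#'   input has zero variance.
#' @export
partial_correlations <- function(observed_plaid, comp_pred, patt_pred) {
  v <- function(x) if (inherits(x, "tuning_curve")) x$responses else x
  o <- v(observed_plaid); cp <- v(comp_pred); pp <- v(patt_pred)
  if (stats::sd(o) == 0 || stats::sd(cp) == 0 || stats::sd(pp) == 0)
    return(list(rc = NA_real_, rp = NA_real_))
  clip <- function(r) max(min(r, 1 - 1e-6), -(1 - 1e-6))
  # clip the raw correlations so perfect-prediction limits stay defined
  r_c <- clip(stats::cor(o, cp))
  r_p <- clip(stats::cor(o, pp))
  r_pc <- clip(stats::cor(cp, pp))
  rc <- (r_c - r_p * r_pc) / sqrt((1 - r_p^2) * (1 - r_pc^2))
  rp <- (r_p - r_c * r_pc) / sqrt((1 - r_c^2) * (1 - r_pc^2))
  list(rc = clip(rc), rp = clip(rp))
}

#' Fisher z-transform of a partial correlation
#'
#' `z = atanh(r) * sqrt(n - 3)`; with the 12-direction protocol (n = 12)
#' the factor is 3. Correlations are clipped to `1 - 1e-6` in magnitude
#' before the transform.
#'
#' @param r correlation.
#' @param n number of observations (directions); must exceed 3.
#' @return Fisher z score.
#' @export
fisher_z <- function(r, n = 12) {
  if (n <= 3) stop("n must exceed 3")
  r <- pmax(pmin(r, 1 - 1e-6), -(1 - 1e-6))
  atanh(r) * sqrt(n - 3)
}

#' Pattern/component classification from Zp and Zc
#'
#' A direction-tuned unit is a pattern cell when Zp is significantly above
#' zero and significantly above Zc, i.e. `zp > z_crit` and
#' `zp - max(zc, 0) > z_crit`; symmetric for component. Everything else is
#' unclassified. `z_crit = 1.28` is the one-sided 90% criterion standard in
#' this literature. Direction selectivity (`dsi > dsi_crit`) is reported as
#' a separate flag so analyses can include or exclude it.
#'
#' @param zp,zc Fisher-transformed partial correlations.
#' @param dsi direction selectivity index (optional, `NA` allowed).
#' @param z_crit significance criterion (default 1.28).
#' @param dsi_crit direction-selectivity criterion (default 0.33).
#' @return list with `label` in `{"pattern", "component", "unclassified"}`
#'   and `direction_selective` flag.
#' @export
classify_zpzc <- function(zp, zc, dsi = NA, z_crit = 1.28, dsi_crit = 0.33) {
  label <- if (is.na(zp) || is.na(zc)) "unclassified"
  else if (zp > z_crit && zp - max(zc, 0) > z_crit) "pattern"
  else if (zc > z_crit && zc - max(zp, 0) > z_crit) "component"
  else "unclassified"
  list(label = label,
       direction_selective = if (is.na(dsi)) NA else dsi > dsi_crit)
}

#' Pattern index
#'
#' `PI = Zp - Zc`, the scalar patternness metric.
#' @param zp,zc Fisher z scores.
#' @return numeric.
#' @export
pattern_index <- function(zp, zc) zp - zc

#' Full classification of one observed grating/plaid curve pair
#'
#' Convenience wrapper chaining predictions, partial correlations, Fisher
#' transform, PI and the label rule.
#'
#' @param grating_curve,plaid_curve `tuning_curve`s or 12-vectors for the
#'   same SF/TF condition.
#' @param cross_angle plaid cross angle, degrees.
#' @param z_crit,dsi_crit see [classify_zpzc()].
#' @return list: `rc`, `rp`, `zc`, `zp`, `pi`, `label`, `dsi`,
#'   `direction_selective`.
#' @export
classify_pair <- function(grating_curve, plaid_curve, cross_angle = 120,
                          z_crit = 1.28, dsi_crit = 0.33) {
  cp <- component_prediction(grating_curve, cross_angle)
  pp <- pattern_prediction(grating_curve)
  pc <- partial_correlations(plaid_curve, cp, pp)
  zc <- if (is.na(pc$rc)) NA_real_ else fisher_z(pc$rc)
  zp <- if (is.na(pc$rp)) NA_real_ else fisher_z(pc$rp)
  dsi <- direction_selectivity_index(grating_curve)
  cl <- classify_zpzc(zp, zc, dsi, z_crit, dsi_crit)
  list(rc = pc$rc, rp = pc$rp, zc = zc, zp = zp,
       pi = if (is.na(zp) || is.na(zc)) NA_real_ else pattern_index(zp, zc),
       label = cl$label, dsi = dsi,
       direction_selective = cl$direction_selective)
}

#' Aligned, normalised population-average tuning curves
#'
#' Each unit's grating/plaid curve pair is circularly shifted so its
#' preferred grating direction sits at 0 degrees, peak-normalised (jointly,
#' preserving the grating/plaid amplitude ratio), then averaged across
#' units. Zc, Zp and PI are recomputed on the averaged pair.
#'
#' @param pairs list of lists, each with elements `grating` and `plaid`
#'   (12-vectors or `tuning_curve`s).
#' @param normalize peak-normalise each pair before averaging.
#' @param cross_angle plaid cross angle for the recomputed indexes.
#' @return list: `directions` (centred grid, -180..150), `grating`, `plaid`
#'   (averaged curves), `zc`, `zp`, `pi`.
#' @export
population_average_curves <- function(pairs, normalize = TRUE,
                                      cross_angle = 120) {
  if (length(pairs) < 2) stop("need at least 2 units")
  v <- function(x) if (inherits(x, "tuning_curve")) x$responses else x
  G <- P <- matrix(0, length(pairs), 12)
  for (i in seq_along(pairs)) {
    g <- v(pairs[[i]]$grating); p <- v(pairs[[i]]$plaid)
    shift <- which.max(g) - 1
    idx <- (seq_len(12) - 1 + shift) %% 12 + 1
    g <- g[idx]; p <- p[idx]
    if (normalize) {
      pk <- max(g, p)
      if (pk > 0) { g <- g / pk; p <- p / pk }
    }
    G[i, ] <- g; P[i, ] <- p
  }
  g_avg <- colMeans(G); p_avg <- colMeans(P)
  cl <- classify_pair(g_avg, p_avg, cross_angle)
  # report on a grid centred on the preferred direction
  ord <- c(7:12, 1:6)
  list(directions = seq(-180, 150, by = 30),
       grating = g_avg[ord], plaid = p_avg[ord],
       zc = cl$zc, zp = cl$zp, pi = cl$pi)
}
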