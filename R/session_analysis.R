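#' All tuning curves of one unit
#'
#' Grating and plaid curves for every SF/TF combination of the session
#' protocol, sharing one baseline estimate.
#'
#' @param session a `session`.
#' @param unit_index which unit.
#' @return list with `grating`, `plaid` (lists of `tuning_curve`s indexed
#'   `sf<k>_tf<j>`), and `baseline`.
#' @export
unit_tuning_curves <- function(session, unit_index) {
  spk <- session$spikes[[unit_index]]
  tr <- session$trials
  bl <- baseline_from_isi(spk, tr, session$protocol$isi)
  out <- list(grating = list(), plaid = list(), baseline = bl)
  for (sf in session$protocol$sfs) for (tf in session$protocol$tfs) {
    key <- sprintf("sf%g_tf%g", sf, tf)
    out$grating[[key]] <- compute_tuning_curve(spk, tr, "grating", sf, tf, bl)
    out$plaid[[key]] <- compute_tuning_curve(spk, tr, "plaid", sf, tf, bl)
  }
  out
}

#' Observed classification of one session unit
#'
#' The standard analysis path: tuning curves at all conditions, best SF/TF
#' by peak grating response, Zp/Zc classification at the best condition,
#' and (for strict analyses) whether the label is consistent across the two
#' SFs at the best TF.
#'
#' @param session a `session`.
#' @param unit_index which unit.
#' @param z_crit,dsi_crit classification thresholds.
#' @return list with `label`, `rc`, `rp`, `zc`, `zp`, `pi`, `dsi`,
#'   `direction_selective`, `best_sf`, `best_tf`, `responsive`,
#'   `consistent`, and the `curves`.
#' @export
classify_session_unit <- function(session, unit_index, z_crit = 1.28,
                                  dsi_crit = 0.33) {
  cv <- unit_tuning_curves(session, unit_index)
  bc <- best_condition(cv$grating)
  key <- sprintf("sf%g_tf%g", bc$sf, bc$tf)
  cl <- classify_pair(cv$grating[[key]], cv$plaid[[key]],
                      session$protocol$cross_angle, z_crit, dsi_crit)
  labels_by_sf <- vapply(session$protocol$sfs, function(sf) {
    k <- sprintf("sf%g_tf%g", sf, bc$tf)
    classify_pair(cv$grating[[k]], cv$plaid[[k]],
                  session$protocol$cross_angle, z_crit, dsi_crit)$label
  }, character(1))
  c(cl, list(best_sf = bc$sf, best_tf = bc$tf,
             responsive = is_responsive(c(cv$grating, cv$plaid)),
             consistent = length(unique(labels_by_sf)) == 1,
             curves = cv))
}

#' Per-unit response metrics table
#'
#' The tidy per-unit summary: responsiveness, DSI, modulation index (from
#' the PSTH of the most effective grating), cross-orientation suppression
#' index and best condition.
#'
#' @param session a `session`.
#' @param psth_bin PSTH bin width for the MI, seconds.
#' @return data.frame with one row per unit.
#' @export
session_metrics_table <- function(session, psth_bin = 0.01) {
  n <- length(session$units)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    cv <- unit_tuning_curves(session, i)
    bc <- best_condition(cv$grating)
    key <- sprintf("sf%g_tf%g", bc$sf, bc$tf)
    gcurve <- cv$grating[[key]]
    best_dir <- gcurve$directions[which.max(gcurve$responses)]
    tt <- session$trials
    sel <- tt$kind == "grating" & abs(tt$sf - bc$sf) < 1e-9 &
      abs(tt$tf - bc$tf) < 1e-9 & abs(tt$direction - best_dir) < 1e-6
    psth <- compute_psth(session$spikes[[i]], tt[sel, , drop = FALSE],
                         psth_bin)
    mi <- modulation_index(psth, bc$tf)
    csi <- cross_suppression_index(cv$grating, cv$plaid)
    rows[[i]] <- data.frame(
      unit_id = session$units[[i]]$unit_id,
      kind = session$units[[i]]$kind,
      responsive = is_responsive(c(cv$grating, cv$plaid)),
      dsi = direction_selectivity_index(gcurve),
      mi = mi, csi = csi, best_sf = bc$sf, best_tf = bc$tf,
      baseline_rate = cv$baseline$mean)
  }
  do.call(rbind, rows)
}

#' Session classification table
#'
#' Zp/Zc classification of every unit at its best condition, with ground
#' truth attached for recovery analyses.
#'
#' @param session a `session`.
#' @param z_crit,dsi_crit classification thresholds.
#' @return data.frame with one row per unit: `unit_id`, `kind`, `rc`, `rp`,
#'   `zc`, `zp`, `pi`, `label`, `dsi`, `direction_selective`,
#'   `responsive`, `consistent`, `best_sf`, `best_tf`.
#' @export
session_classification_table <- function(session, z_crit = 1.28,
                                         dsi_crit = 0.33) {
  n <- length(session$units)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    cl <- classify_session_unit(session, i, z_crit, dsi_crit)
    rows[[i]] <- data.frame(
      unit_id = session$units[[i]]$unit_id,
      kind = session$units[[i]]$kind,
      rc = cl$rc, rp = cl$rp, zc = cl$zc, zp = cl$zp, pi = cl$pi,
      label = cl$label, dsi = cl$dsi,
      direction_selective = cl$direction_selective,
      responsive = cl$responsive, consistent = cl$consistent,
      best_sf = cl$best_sf, best_tf = cl$best_tf)
  }
  do.call(rbind, rows)
}
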