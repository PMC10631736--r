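#' Baseline (spontaneous) firing statistics from interstimulus intervals
#'
#' Firing rates are computed in the 1-s interstimulus windows that follow
#' every trial and pooled across the session. Their mean and SD define the
#' reference distribution for z-scoring evoked responses. The SD is floored
#' at 0.1 spikes/s to keep z-scores finite for near-silent units.
#'
#' @param spikes numeric vector of absolute spike times for one unit.
#' @param trials trial table with columns `onset` and `offset` (seconds).
#' @param isi_duration interstimulus window length, seconds.
#' @param sd_floor lower bound on the baseline SD, spikes/s.
#' @return list with `rates` (per-window spikes/s), `mean`, `sd`.
#' @export
baseline_from_isi <- function(spikes, trials, isi_duration = 1,
                              sd_floor = 0.1) {
  starts <- trials$offset
  rates <- vapply(starts, function(s)
    sum(spikes >= s & spikes < s + isi_duration) / isi_duration, numeric(1))
  list(rates = rates, mean = mean(rates),
       sd = max(stats::sd(rates), sd_floor))
}

new_tuning_curve <- function(directions, responses, raw_rates,
                             stimulus_class, sf, tf, n_trials) {
  tc <- list(directions = directions, responses = responses,
             raw_rates = raw_rates, stimulus_class = stimulus_class,
             sf = sf, tf = tf, n_trials = n_trials)
  class(tc) <- "tuning_curve"
  tc
}

#' @export
print.tuning_curve <- function(x, ...) {
  cat(sprintf("<tuning_curve> %s sf=%g tf=%g (%d trials)\n",
              x$stimulus_class, x$sf, x$tf, x$n_trials))
  print(round(stats::setNames(x$responses, x$directions), 2))
  invisible(x)
}

#' Direction tuning curve from spike trains
#'
#' For each of the 12 directions, the trial-averaged firing rate over the
#' full stimulus window is z-scored against the interstimulus baseline
#' distribution; negative z values are clipped to zero. Raw rates
#' (baseline-subtracted spikes/s) are kept alongside for the metrics that
#' need physical units.
#'
#' @param spikes absolute spike times of one unit, seconds.
#' @param trials trial table: columns `kind`, `direction`, `sf`, `tf`,
#'   `onset`, `offset`.
#' @param stimulus_class `"grating"` or `"plaid"`.
#' @param sf,tf condition selector.
#' @param baseline result of [baseline_from_isi()] (computed if omitted).
#' @return a `tuning_curve`.
#' @export
compute_tuning_curve <- function(spikes, trials, stimulus_class, sf, tf,
                                 baseline = NULL) {
  if (is.null(baseline)) baseline <- baseline_from_isi(spikes, trials)
  sel <- trials$kind == stimulus_class &
    abs(trials$sf - sf) < 1e-9 & abs(trials$tf - tf) < 1e-9
  if (!any(sel)) stop("no trials for ", stimulus_class, " sf=", sf, " tf=", tf)
  tt <- trials[sel, , drop = FALSE]
  dirs <- protocol_directions()
  mean_rate <- vapply(dirs, function(d) {
    rows <- tt[abs(((tt$direction - d) %% 360)) < 1e-6, , drop = FALSE]
    if (nrow(rows) == 0) return(NA_real_)
    mean(vapply(seq_len(nrow(rows)), function(i)
      sum(spikes >= rows$onset[i] & spikes < rows$offset[i]) /
        (rows$offset[i] - rows$onset[i]), numeric(1)))
  }, numeric(1))
  if (anyNA(mean_rate)) stop("missing directions in trial table")
  z <- (mean_rate - baseline$mean) / baseline$sd
  n_tr <- sum(sel) / length(dirs)
  new_tuning_curve(dirs, pmax(z, 0), mean_rate - baseline$mean,
                   stimulus_class, sf, tf, n_tr)
}

#' Responsiveness criterion
#'
#' A unit counts as responsive when its best grating-or-plaid condition
#' exceeds both 2 spikes/s above baseline and 6 z-scored points relative to
#' baseline activity.
#'
#' @param curves list of `tuning_curve`s covering the unit's conditions.
#' @param rate_threshold spikes/s above baseline (default 2).
#' @param z_threshold z-score threshold (default 6).
#' @return logical flag.
#' @export
is_responsive <- function(curves, rate_threshold = 2, z_threshold = 6) {
  best_raw <- max(vapply(curves, function(cv) max(cv$raw_rates), numeric(1)))
  best_z <- max(vapply(curves, function(cv) max(cv$responses), numeric(1)))
  best_raw > rate_threshold && best_z > z_threshold
}

#' Direction selectivity index
#'
#' `DSI = (Rpref - Ropposite) / (Rpref + Ropposite)` on the z-scored curve,
#' with Rpref the maximum response and Ropposite the response 180 degrees
#' away (exact bin arithmetic on the 12-direction grid). Units with
#' DSI > 0.33 are conventionally treated as direction selective.
#'
#' @param curve a `tuning_curve` (or bare 12-vector of responses).
#' @return DSI in `[0, 1]`, or `NA` for an all-zero curve.
#' @export
direction_selectivity_index <- function(curve) {
  r <- if (inherits(curve, "tuning_curve")) curve$responses else curve
  stopifnot(length(r) == 12)
  if (max(r) <= 0) return(NA_real_)
  i <- which.max(r)
  j <- (i - 1 + 6) %% 12 + 1
  (r[i] - r[j]) / (r[i] + r[j])
}

#' Peristimulus time histogram
#'
#' Trial-averaged firing rate in fixed-width bins over the stimulus window.
#'
#' @param spikes absolute spike times.
#' @param trials rows of the trial table to average over (single condition
#'   and direction).
#' @param bin_width seconds (default 0.01).
#' @return list with `rate` (spikes/s per bin), `bin_width`, `n_trials`.
#' @export
compute_psth <- function(spikes, trials, bin_width = 0.01) {
  dur <- trials$offset[1] - trials$onset[1]
  nb <- floor(dur / bin_width + 1e-9)
  counts <- numeric(nb)
  for (i in seq_len(nrow(trials))) {
    rel <- spikes[spikes >= trials$onset[i] & spikes < trials$onset[i] + nb * bin_width] -
      trials$onset[i]
    if (length(rel))
      counts <- counts + tabulate(floor(rel / bin_width) + 1, nbins = nb)
  }
  list(rate = counts / (nrow(trials) * bin_width), bin_width = bin_width,
       n_trials = nrow(trials))
}

#' Modulation index (simple vs complex classification)
#'
#' Standardised strength of response modulation at the stimulus temporal
#' frequency: `MI = |PS(f1) - <PS>| / sd(PS)`, where PS is the power
#' spectral density (periodogram) of the mean-subtracted PSTH and the
#' averages run over all non-DC frequencies up to Nyquist. `f1` is mapped to
#' the nearest frequency-grid bin. Values above 3 indicate strong modulation
#' (simple-like); below 3, phase tolerance (complex-like).
#'
#' @param psth a PSTH as from [compute_psth()], or a bare rate vector.
#' @param f1 stimulus temporal frequency, Hz.
#' @param bin_width bin width in seconds (taken from the PSTH object when
#'   given).
#' @return MI (>= 0), or `NA` for a flat PSTH.
#' @export
modulation_index <- function(psth, f1, bin_width = 0.01) {
  r <- if (is.list(psth)) psth$rate else psth
  if (is.list(psth)) bin_width <- psth$bin_width
  n <- length(r)
  if (all(r == 0)) return(NA_real_)
  if (stats::sd(r) == 0) return(0)  # constant response: no modulation
  if (n * bin_width < 2 / f1)
    warning("PSTH covers fewer than two cycles of f1")
  x <- r - mean(r)
  ps <- Mod(stats::fft(x))^2 / n
  freqs <- (seq_len(n) - 1) / (n * bin_width)
  keep <- 2:(floor(n / 2) + 1)           # exclude DC, keep up to Nyquist
  ps <- ps[keep]; freqs <- freqs[keep]
  i1 <- which.min(abs(freqs - f1))
  abs(ps[i1] - mean(ps)) / stats::sd(ps)
}

#' Cross-orientation suppression index
#'
#' `CSI = (Rg - Rp) / (Rg + Rp)`, with Rg and Rp the peak responses to
#' gratings and plaids at their most effective directions. 1 means complete
#' suppression by the second component (responsive to gratings only), -1
#' complete facilitation, 0 equal peak responses.
#'
#' @param grating_curves,plaid_curves `tuning_curve`s (or lists of them), or
#'   bare peak rates `Rg`, `Rp`.
#' @return CSI in `[-1, 1]`, or `NA` when both peaks are zero.
#' @export
cross_suppression_index <- function(grating_curves, plaid_curves) {
  peak <- function(x) {
    if (is.numeric(x) && length(x) == 1) return(max(x, 0))
    if (inherits(x, "tuning_curve")) x <- list(x)
    max(0, vapply(x, function(cv) max(cv$raw_rates), numeric(1)))
  }
  rg <- peak(grating_curves); rp <- peak(plaid_curves)
  if (rg + rp == 0) return(NA_real_)
  (rg - rp) / (rg + rp)
}

#' Most effective spatial/temporal frequency combination
#'
#' The SF/TF pair whose grating curve has the largest peak response; ties
#' break toward the lowest SF, then the lowest TF.
#'
#' @param grating_curves list of grating `tuning_curve`s covering all
#'   SF x TF combinations.
#' @return list with `sf`, `tf` and the winning curve's index.
#' @export
best_condition <- function(grating_curves) {
  if (length(grating_curves) == 0) stop("no curves supplied")
  info <- data.frame(
    sf = vapply(grating_curves, function(cv) cv$sf, numeric(1)),
    tf = vapply(grating_curves, function(cv) cv$tf, numeric(1)),
    peak = vapply(grating_curves, function(cv) max(cv$responses), numeric(1)))
  ord <- order(-info$peak, info$sf, info$tf)
  i <- ord[1]
  list(sf = info$sf[i], tf = info$tf[i], index = i)
}
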