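test_that("compute_sta equals naive spike-triggered frame averaging", {
  g <- test_geometry()
  movie <- make_noise_movie(11, duration = 200 / 30, frame_rate = 30,
                            geometry = g)
  set.seed(5)
  spikes <- sort(stats::runif(60, 0, 200 / 30))
  st <- compute_sta(spikes, movie, n_lags = 5)
  # oracle: explicit loop over spikes and lags
  fr <- floor(spikes * 30) + 1
  for (k in 1:5) {
    keep <- fr - (k - 1) >= 1
    naive <- Reduce(`+`, lapply(fr[keep], function(f)
      movie$frames[, , f - (k - 1)] - 0.5)) / sum(keep)
    expect_equal(st$mean[, , k], naive, tolerance = 1e-12)
    expect_equal(st$count[k], sum(keep))
  }
  # duplicating the spike train leaves the mean unchanged
  st2 <- compute_sta(rep(spikes, 2), movie, n_lags = 5)
  expect_equal(st2$mean, st$mean, tolerance = 1e-12)
})

test_that("random spikes give a vanishing STA as the count grows", {
  g <- test_geometry()
  movie <- make_noise_movie(12, duration = 30, frame_rate = 30,
                            geometry = g)
  set.seed(6)
  small <- compute_sta(sort(stats::runif(50, 0, 30)), movie, 3)
  big <- compute_sta(sort(stats::runif(5000, 0, 30)), movie, 3)
  expect_lt(mean(abs(big$mean)), mean(abs(small$mean)))
  expect_lt(mean(abs(big$mean)), 0.02)
})

test_that("decorrelation is the identity for a flat spectrum", {
  g <- test_geometry()
  set.seed(7)
  fr <- matrix(stats::rnorm(g$ny * g$nx), g$ny, g$nx)
  flatP <- matrix(1, g$ny, g$nx)
  expect_equal(decorrelate_sta(fr, flatP, 0.1), fr, tolerance = 1e-10)
  expect_error(decorrelate_sta(fr, matrix(0, g$ny, g$nx)), "degenerate")
})

test_that("decorrelation undoes the stimulus correlation of an ideal STA", {
  # infinite-data limit: under correlated Gaussian noise the raw STA is the
  # filter smoothed by the stimulus autocorrelation; whitening against the
  # measured stimulus spectrum must bring it back toward the true filter
  g <- test_geometry()
  u <- make_unit("ln_component", 0, geometry = g, seed = 8)
  truth <- u$filters[[1]]$weights[, , 4]
  P <- matrix(0, g$ny, g$nx)
  for (m in 1:4)
    P <- P + stimulus_power_spectrum(
      make_noise_movie(800 + m, duration = 20, frame_rate = 30,
                       geometry = g)) / 4
  # ideal raw STA: filter convolved with the stimulus autocorrelation
  raw <- Re(stats::fft(stats::fft(truth) * P, inverse = TRUE)) /
    length(truth)
  dec <- decorrelate_sta(raw, P, 0.1)
  expect_gt(abs(stats::cor(as.numeric(dec), as.numeric(truth))),
            abs(stats::cor(as.numeric(raw), as.numeric(truth))))
  # scaling the stimulus contrast rescales the whitened STA shape only
  dec2 <- decorrelate_sta(2 * raw, 4 * P, 0.1)
  expect_gt(abs(stats::cor(as.numeric(dec2), as.numeric(dec))), 0.999)
})

test_that("the STA pipeline recovers an LN unit's filter", {
  s <- noise_session()
  u <- s$units[[1]]
  st <- sta_receptive_field(s, 1, n_perm = 100, seed = 9)
  expect_s3_class(st, "sta_sequence")
  expect_equal(dim(st$z_frames), c(24, 32, 10))
  expect_false(st$low_confidence)
  # raw STA correlates with the ground-truth filter at the matched lag
  r <- vapply(1:10, function(k)
    stats::cor(as.numeric(st$raw_frames[, , k]),
               as.numeric(u$filters[[1]]$weights[, , k])), numeric(1))
  expect_gt(max(abs(r)), 0.8)
  # strongly significant relative to the permutation null
  expect_gt(max(st$ci_per_lag), stats::quantile(st$null_ci, 0.95))
  expect_gt(max(abs(st$z_frames[, , which.max(st$ci_per_lag)])), 6)
  # determinism under a fixed permutation seed
  st2 <- sta_receptive_field(s, 1, n_perm = 100, seed = 9)
  expect_identical(st$z_frames, st2$z_frames)
})

test_that("recovery improves with noise-stimulation duration", {
  g <- test_geometry()
  u <- make_unit("ln_component", 90, geometry = g, seed = 10)
  r_at <- function(n_movies) {
    sums <- array(0, dim = c(g$ny, g$nx, 10)); nk <- 0
    for (m in seq_len(n_movies)) {
      movie <- make_noise_movie(300 + m, duration = 20, frame_rate = 30,
                                geometry = g)
      spk <- generate_spikes(simulate_rate(u, movie), 30, 1, seed = m)[[1]]
      st <- compute_sta(spk, movie, 10)
      sums <- sums + st$sum; nk <- nk + st$count
    }
    k <- 4
    stats::cor(as.numeric(sums[, , k] / nk[k]),
               as.numeric(u$filters[[1]]$weights[, , k]))
  }
  rs <- abs(vapply(c(1, 3, 9), r_at, numeric(1)))
  expect_true(all(diff(rs) > 0))
})

test_that("permutation z-scores are calibrated on shuffled spikes", {
  s <- noise_session()
  # destroy the spike-stimulus relationship, keep the count
  ep <- s$trials[s$trials$kind == "noise", ]
  spk <- s$spikes[[1]]
  n_noise <- sum(vapply(seq_len(nrow(ep)), function(i)
    sum(spk >= ep$onset[i] & spk < ep$offset[i]), numeric(1)))
  set.seed(13)
  sh <- sort(unlist(lapply(seq_len(nrow(ep)), function(i)
    stats::runif(n_noise / nrow(ep), ep$onset[i], ep$offset[i]))))
  s_sh <- s
  s_sh$spikes[[1]] <- sh
  st <- sta_receptive_field(s_sh, 1, n_perm = 150, seed = 14)
  z <- st$z_frames
  expect_gt(mean(z), -0.1); expect_lt(mean(z), 0.1)
  expect_gt(stats::sd(z), 0.9); expect_lt(stats::sd(z), 1.1)
  tail2 <- mean(abs(z) > 2)
  expect_gt(tail2, 0.02); expect_lt(tail2, 0.08)
})

test_that("contrast index is a homogeneous peak-signal summary", {
  set.seed(15)
  fr <- matrix(stats::rnorm(768), 24, 32)
  expect_equal(contrast_index(matrix(0, 24, 32)), 0)
  expect_equal(contrast_index(3 * fr), 3 * contrast_index(fr))
  expect_gt(contrast_index(fr + 5), contrast_index(fr))
})

test_that("Gabor fits recover parameters and reject noise", {
  g <- test_geometry()
  f <- make_drifting_gabor_filter(30, 0.02, 2, 3, 8, geometry = g)
  frame <- f$weights[, , 4] * 50
  fit <- fit_gabor(frame, g)
  expect_gt(fit$r2, 0.99)
  # filter drifts at 30 deg, so the carrier axis is 30 mod 180
  dtheta <- abs(fit$orientation_deg - 30)
  expect_lt(min(dtheta, 180 - dtheta), 5)
  expect_lt(abs(fit$sf - 0.02), 0.005)
  # sign flip: same quality, phase shifted
  fit2 <- fit_gabor(-frame, g)
  expect_gt(fit2$r2, 0.99)
  set.seed(16)
  noise_fit <- fit_gabor(matrix(stats::rnorm(768), 24, 32), g)
  expect_lt(noise_fit$r2, 0.3)
})

test_that("lobe counting matches the filter structure", {
  g <- test_geometry()
  z <- array(0, dim = c(24, 32, 3))
  f <- make_drifting_gabor_filter(0, 0.02, 2, 3, 8, geometry = g)
  z[, , 2] <- f$weights[, , 4] / max(abs(f$weights[, , 4])) * 8
  res <- count_lobes(z, threshold = 3.5, min_area = 4)
  expect_equal(res$best_frame, 2)
  expect_equal(res$n_lobes, 2)  # one excitatory, one inhibitory lobe
  blob <- array(0, dim = c(24, 32, 1))
  blob[10:14, 14:18, 1] <- 6
  expect_equal(count_lobes(blob)$n_lobes, 1)
  set.seed(17)
  expect_equal(count_lobes(array(stats::rnorm(768 * 3),
                                 dim = c(24, 32, 3)))$n_lobes, 0)
})

test_that("dominant spatial frequency tracks the construction", {
  g <- test_geometry()
  f <- make_drifting_gabor_filter(60, 0.02, 2, 3, 8, geometry = g)
  z <- array(f$weights[, , 4], dim = c(24, 32, 1))
  est <- sta_spatial_frequency(z, g)
  expect_lt(abs(est - 0.02), 0.25 * 0.02)
  expect_equal(sta_spatial_frequency(z * 10, g), est)
})
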