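test_that("a tf=0 filter is static and not direction selective", {
  g <- test_geometry()
  f <- make_drifting_gabor_filter(0, 0.02, 0, 3, 8, geometry = g)
  # identical spatial pattern at all lags (up to the temporal envelope)
  for (k in 2:10) {
    a <- as.numeric(f$weights[, , 1]); b <- as.numeric(f$weights[, , k])
    expect_gt(stats::cor(a, b), 1 - 1e-12)
  }
  # opposite drift directions produce equal mean drive
  u <- make_unit("ln_component", 0, tf = 0, geometry = g, seed = 1,
                 threshold_frac = 0)
  r1 <- mean(simulate_rate(u, make_grating(0, 0.02, 2, 1, 1, 60, g)))
  r2 <- mean(simulate_rate(u, make_grating(180, 0.02, 2, 1, 1, 60, g)))
  expect_lt(abs(r1 - r2) / max(r1, r2), 0.05
  )
})

test_that("filter construction rejects envelopes beyond the display", {
  g <- test_geometry()
  expect_error(make_drifting_gabor_filter(0, 0.02, 2, 10, 20, geometry = g),
               "envelope")
})

test_that("simulate_rate follows the LN cascade", {
  g <- test_geometry()
  u <- make_unit("ln_component", 90, geometry = g, seed = 2)
  # zero-contrast movie: rate is baseline everywhere
  m0 <- make_grating(0, 0.02, 2, 0, 0.5, 60, g)
  expect_equal(simulate_rate(u, m0), rep(u$baseline_rate, 30))
  # preferred grating: rate modulated at tf
  m <- make_grating(90, 0.02, 2, 1, 1.5, 60, g)
  r <- simulate_rate(u, m)
  expect_true(all(r >= 0))
  x <- r[16:90] - mean(r[16:90])  # skip onset transient
  ps <- Mod(stats::fft(x))^2
  freqs <- (seq_along(x) - 1) / (length(x) / 60)
  half <- 2:(length(x) / 2)
  expect_lt(abs(freqs[half][which.max(ps[half])] - 2), 0.5)
  # geometry mismatch
  g2 <- display_geometry(pixels_x = 16, pixels_y = 12)
  expect_error(simulate_rate(u, make_grating(0, 0.02, 2, 1, 0.5, 60, g2)),
               "geometry")
})

test_that("energy units respond with little temporal modulation", {
  g <- test_geometry()
  u <- make_unit("energy_complex", 90, geometry = g, seed = 3)
  m <- make_grating(90, 0.02, 2, 1, 1.5, 60, g)
  r <- simulate_rate(u, m)[16:90]
  x <- r - mean(r)
  ps <- Mod(stats::fft(x))^2 / length(x)
  freqs <- (seq_along(x) - 1) / (length(x) / 60)
  f1_power <- ps[which.min(abs(freqs - 2))]
  f0 <- mean(r)^2
  expect_lt(f1_power / f0, 0.05)  # F1/F0 << 1
})

test_that("Poisson spike generation matches count statistics and seed", {
  tr <- generate_spikes(rep(10, 90), 60, n_trials = 1000, seed = 9)
  counts <- lengths(tr)
  expect_lt(abs(mean(counts) - 15), 3 * sqrt(15 / 1000))
  expect_gt(stats::var(counts) / mean(counts), 0.8)
  expect_lt(stats::var(counts) / mean(counts), 1.2)
  # determinism and degenerate cases
  expect_identical(generate_spikes(rep(5, 30), 30, 3, seed = 4),
                   generate_spikes(rep(5, 30), 30, 3, seed = 4))
  expect_equal(lengths(generate_spikes(rep(0, 30), 30, 5, seed = 1)),
               rep(0L, 5))
  expect_error(generate_spikes(c(1, -1), 30, 1, 1), "non-negative")
})

test_that("sessions have the full protocol structure and ground truth", {
  s <- tiny_session()
  pr <- s$protocol
  n_param <- 2 * length(pr$sfs) * length(pr$tfs) * 12 * pr$n_trials
  expect_equal(nrow(s$trials), n_param)
  expect_equal(nrow(s$ground_truth), 10)
  expect_equal(length(s$spikes), 10)
  for (sp in s$spikes) expect_false(is.unsorted(sp))
  # trials are non-overlapping with 1-s gaps
  expect_true(all(diff(s$trials$onset[order(s$trials$onset)]) >=
                    pr$duration + pr$isi - 1e-9))
  # determinism of the whole session
  s2 <- make_session(default_population(4, 2, 2, 2),
                     default_protocol(n_trials = 8, n_noise = 0),
                     test_geometry(), seed = 101)
  expect_identical(s$spikes, s2$spikes)
  expect_identical(s$trials, s2$trials)
})

test_that("noiseless tuning peaks at the construction direction", {
  s <- tiny_session()
  gt <- s$ground_truth
  for (i in which(gt$kind == "ln_component")) {
    cur <- noiseless_tuning(s, i, "grating", gt$sf[i], gt$tf[i])
    expect_equal(protocol_directions()[which.max(cur)], gt$pref_direction[i])
  }
})

test_that("regressor banks have the advertised structure per class", {
  dirs <- protocol_directions()
  bc <- make_regressor_bank(24, "component", seed = 5)
  bp <- make_regressor_bank(24, "pattern", seed = 6)
  bu <- make_regressor_bank(24, "unclassified", seed = 7)
  expect_error(make_regressor_bank(6, "pattern"), "at least 12")
  for (b in list(bc, bp, bu))
    expect_setequal(unique(b$pref_directions), dirs)
  for (i in seq_len(24)) {
    g <- bc$curves[i, 1:12]; p <- bc$curves[i, 13:24]
    gpk <- which.max(g)
    # plaid curve bimodal with peaks +/- 2 bins from the grating peak
    ppks <- order(p, decreasing = TRUE)[1:2]
    expect_setequal(sort(((ppks - 1) - (gpk - 1)) %% 12),
                    c(2, 10))
    expect_equal(classify_pair(g, p)$label, "component")
  }
  for (i in seq_len(24)) {
    g <- bp$curves[i, 1:12]; p <- bp$curves[i, 13:24]
    expect_equal(which.max(g), which.max(p))
    expect_equal(classify_pair(g, p)$label, "pattern")
  }
  for (i in seq_len(24))
    expect_equal(classify_pair(bu$curves[i, 1:12],
                               bu$curves[i, 13:24])$label, "unclassified")
})
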