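test_that("gratings follow the luminance model and protocol geometry", {
  g <- test_geometry()
  m <- make_grating(90, 0.02, 2, 1, 1.5, 60, g)
  expect_equal(dim(m$frames), c(g$ny, g$nx, 90))
  expect_true(all(m$frames >= 0 & m$frames <= 1))
  # full-cycle movie: temporal mean is mid-gray at every pixel
  expect_lt(max(abs(apply(m$frames, c(1, 2), mean) - 0.5)), 1e-6)

  # zero contrast: uniform mid-gray
  m0 <- make_grating(45, 0.02, 2, 0, 1, 60, g)
  expect_equal(max(abs(m0$frames - 0.5)), 0)

  # frame-count rounding rule
  expect_equal(dim(make_grating(0, 0.02, 2, 1, 0.52, 30, g)$frames)[3], 16)

  expect_error(make_grating(0, 0.02, 2, 1, -1, 60, g), "positive")
  expect_error(make_grating(0, 0.02, 2, 1, 1.5, 0, g), "positive")
  # Nyquist guard: >= 4 samples per cycle
  expect_error(make_grating(0, 0.2, 2, 1, 1.5, 60, g), "undersampled")
})

test_that("pixel time series oscillates at exactly the temporal frequency", {
  g <- test_geometry()
  for (tf in c(2, 6)) {
    m <- make_grating(30, 0.02, tf, 1, 1.5, 60, g)
    x <- m$frames[10, 20, ] - 0.5
    ps <- Mod(stats::fft(x))^2
    freqs <- (seq_along(x) - 1) / (length(x) / 60)
    half <- 2:(length(x) / 2)
    expect_equal(freqs[half][which.max(ps[half])], tf)
  }
})

test_that("gratings drift toward the stated direction", {
  g <- test_geometry()
  # displacement over 9 frames at tf/sf = 100 deg/s is 15 deg = 4 px
  px_shift <- function(direction) {
    m <- make_grating(direction, 0.02, 2, 1, 0.5, 60, g)
    f1 <- m$frames[, , 1]; f2 <- m$frames[, , 10]
    shifts <- -6:6
    best <- shifts[which.max(vapply(shifts, function(s) {
      idx <- ((seq_len(g$nx) - 1 - s) %% g$nx) + 1
      stats::cor(as.numeric(f2), as.numeric(f1[, idx]))
    }, numeric(1)))]
    best
  }
  expect_equal(px_shift(0), 4)    # rightward: +x
  expect_equal(px_shift(180), -4) # leftward: -x
  # upward drift moves the pattern along +y (increasing row index)
  m <- make_grating(90, 0.02, 2, 1, 0.5, 60, g)
  f1 <- m$frames[, , 1]; f2 <- m$frames[, , 10]
  shifts <- -6:6
  best <- shifts[which.max(vapply(shifts, function(s) {
    idx <- ((seq_len(g$ny) - 1 - s) %% g$ny) + 1
    stats::cor(as.numeric(f2), as.numeric(f1[idx, ]))
  }, numeric(1)))]
  expect_equal(best, 4)
})

test_that("plaids superpose additively around mid-gray", {
  g <- test_geometry()
  for (pd in protocol_directions()) {
    p <- make_plaid(pd, 120, 0.5, 0.02, 2, 0.5, 60, g)
    g1 <- make_grating(pd - 60, 0.02, 2, 0.5, 0.5, 60, g)
    g2 <- make_grating(pd + 60, 0.02, 2, 0.5, 0.5, 60, g)
    expect_lt(max(abs((p$frames - 0.5) -
                        ((g1$frames - 0.5) + (g2$frames - 0.5)))), 1e-9)
  }
  # mean-luminance conservation holds for the plaid too
  p <- make_plaid(135, 120, 0.5, 0.02, 2, 1.5, 60, g)
  expect_lt(max(abs(apply(p$frames, c(1, 2), mean) - 0.5)), 1e-6)
})

test_that("degenerate plaid equals a full-contrast grating; range is guarded", {
  g <- test_geometry()
  p <- make_plaid(45, 0, 0.5, 0.02, 2, 0.5, 60, g)
  gr <- make_grating(45, 0.02, 2, 1, 0.5, 60, g)
  expect_lt(max(abs(p$frames - gr$frames)), 1e-12)
  expect_warning(make_plaid(0, 120, 0.9, 0.02, 2, 0.1, 60, g), "clipping")
  expect_error(make_plaid(0, 200, 0.5, 0.02, 2, 0.5, 60, g), "cross_angle")
})

test_that("noise movies are deterministic with matched correlation scales", {
  g <- test_geometry()
  a <- make_noise_movie(7, duration = 10, frame_rate = 30, geometry = g)
  b <- make_noise_movie(7, duration = 10, frame_rate = 30, geometry = g)
  expect_identical(a$frames, b$frames)
  expect_false(identical(
    a$frames,
    make_noise_movie(8, duration = 10, frame_rate = 30, geometry = g)$frames))
  expect_equal(dim(make_noise_movie(1, 60, 30, geometry = g)$frames)[3],
               1800)
  expect_error(make_noise_movie(1, 10, 30, spatial_corr = 500,
                                geometry = g), "extent")
})

test_that("noise movie statistics match the requested structure", {
  g <- test_geometry()
  m <- make_noise_movie(3, duration = 60, frame_rate = 30,
                        spatial_corr = 6, temporal_corr = 0.05,
                        geometry = g)
  x <- m$frames - 0.5
  # approximately symmetric marginal
  sk <- mean(x^3) / stats::sd(x)^3
  expect_lt(abs(sk), 0.1)
  # lag-1 temporal autocorrelation ~ exp(-dt/tau)
  flat <- matrix(x, g$ny * g$nx, dim(x)[3])
  r1 <- stats::cor(as.numeric(flat[, -ncol(flat)]),
                   as.numeric(flat[, -1]))
  expect_lt(abs(r1 - exp(-(1 / 30) / 0.05)), 0.15 * exp(-(1 / 30) / 0.05))
  # spatial autocorrelation half-width at half max ~ spatial_corr
  f <- x[, , 25]
  ac <- Re(stats::fft(Mod(stats::fft(f))^2, inverse = TRUE))
  ac <- ac / ac[1, 1]
  prof <- ac[1, 1:10]  # along x at dy = 0
  hwhm_px <- stats::approx(prof, 0:9, xout = 0.5)$y
  hwhm <- hwhm_px * g$deg_per_px
  expect_lt(abs(hwhm - 6), 0.15 * 6)
})
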