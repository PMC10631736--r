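fake_curve <- function(responses, raw_rates = responses,
                       stimulus_class = "grating", sf = 0.02, tf = 2) {
  structure(list(directions = protocol_directions(), responses = responses,
                 raw_rates = raw_rates, stimulus_class = stimulus_class,
                 sf = sf, tf = tf, n_trials = 20),
            class = "tuning_curve")
}

test_that("DSI matches its definition and is monotone in Ropposite", {
  peak <- function(rp, ro) {
    r <- rep(0, 12); r[3] <- rp; r[9] <- ro; r
  }
  expect_equal(direction_selectivity_index(peak(10, 0)), 1)
  expect_equal(direction_selectivity_index(peak(5, 5)), 0)
  expect_equal(direction_selectivity_index(peak(4, 2)), 1 / 3,
               tolerance = 1e-4)
  expect_true(is.na(direction_selectivity_index(rep(0, 12))))
  dsis <- vapply(seq(0, 10, by = 1),
                 function(ro) direction_selectivity_index(peak(10, ro)),
                 numeric(1))
  expect_true(all(diff(dsis) < 0))
})

test_that("tuning curves are z-scored against the ISI baseline and clipped", {
  s <- tiny_session()
  gt <- s$ground_truth
  i <- which(gt$kind == "ln_component")[1]
  tc <- compute_tuning_curve(s$spikes[[i]], s$trials, "grating",
                             gt$sf[i], gt$tf[i])
  expect_length(tc$responses, 12)
  expect_true(all(tc$responses >= 0))
  expect_equal(protocol_directions()[which.max(tc$responses)],
               gt$pref_direction[i])
  expect_error(compute_tuning_curve(s$spikes[[i]], s$trials, "grating",
                                    0.5, 2), "no trials")
  # a silent unit gives an all-zero curve
  tc0 <- compute_tuning_curve(numeric(0), s$trials, "grating",
                              gt$sf[i], gt$tf[i])
  expect_equal(tc0$responses, rep(0, 12))
})

test_that("responsiveness needs both the rate and the z criterion", {
  low <- fake_curve(rep(1, 12), raw_rates = rep(1.9, 12))
  expect_false(is_responsive(list(low)))
  # strong rate but weak z
  strong_rate <- fake_curve(rep(3, 12), raw_rates = rep(10, 12))
  expect_false(is_responsive(list(strong_rate)))
  # 10 spikes/s over a 0.5-SD baseline: z = 20 > 6, rate > 2
  good <- fake_curve(c(20, rep(0, 11)), raw_rates = c(10, rep(0, 11)))
  expect_true(is_responsive(list(good)))
  silent <- fake_curve(rep(0, 12))
  expect_false(is_responsive(list(silent)))
})

test_that("modulation index separates modulated from flat responses", {
  t <- seq(0, 1.5 - 0.01, by = 0.01)
  sine <- 10 + 10 * sin(2 * pi * 2 * t)
  expect_gt(modulation_index(sine, 2, 0.01), 3)
  expect_equal(modulation_index(rep(7, 150), 2, 0.01), 0)
  expect_true(is.na(modulation_index(rep(0, 150), 2, 0.01)))
  # scale invariance of the standardised spectrum
  noisy <- sine + stats::rnorm(length(sine), 0, 1)
  expect_equal(modulation_index(noisy, 2, 0.01),
               modulation_index(5 * noisy, 2, 0.01), tolerance = 1e-10)
  # modulation at the wrong frequency does not inflate MI at f1
  off <- 10 + 10 * sin(2 * pi * 5 * t)
  expect_lt(modulation_index(off, 2, 0.01),
            modulation_index(sine, 2, 0.01))
})

test_that("simple-like and complex-like units fall on either side of MI = 3", {
  g <- test_geometry()
  # noiseless limit: the rate trace itself as the PSTH
  for (tf in c(2, 6)) {
    m <- make_grating(90, 0.02, tf, 1, 1.5, 60, g)
    u_ln <- make_unit("ln_component", 90, tf = tf, geometry = g, seed = 1)
    u_en <- make_unit("energy_complex", 90, tf = tf, geometry = g, seed = 2)
    expect_gt(modulation_index(simulate_rate(u_ln, m), tf, 1 / 60), 3)
    expect_lt(modulation_index(simulate_rate(u_en, m), tf, 1 / 60), 3)
  }
  # with Poisson spiking, the ordering persists at the population level
  s <- tiny_session()
  mt <- session_metrics_table(s)
  ln_mi <- mt$mi[mt$kind == "ln_component"]
  en_mi <- mt$mi[mt$kind == "energy_complex"]
  expect_gt(stats::median(ln_mi), 3)
  expect_lt(stats::median(en_mi), stats::median(ln_mi))
})

test_that("CSI identities, antisymmetry and degenerate input", {
  expect_equal(cross_suppression_index(8, 0), 1)
  expect_equal(cross_suppression_index(0, 8), -1)
  expect_equal(cross_suppression_index(5, 5), 0)
  expect_true(is.na(cross_suppression_index(0, 0)))
  for (i in 1:20) {
    rg <- stats::runif(1, 0, 10); rp <- stats::runif(1, 0, 10)
    expect_equal(cross_suppression_index(rg, rp),
                 -cross_suppression_index(rp, rg))
  }
  # curve interface uses the peak raw rates
  gcv <- fake_curve(rep(1, 12), raw_rates = c(8, rep(0, 11)))
  pcv <- fake_curve(rep(1, 12), raw_rates = rep(0, 12),
                    stimulus_class = "plaid")
  expect_equal(cross_suppression_index(gcv, pcv), 1)
})

test_that("best_condition maximises the grating peak with a stable tie rule", {
  mk <- function(peak, sf, tf) fake_curve(c(peak, rep(0, 11)), sf = sf,
                                          tf = tf)
  curves <- list(mk(1, 0.02, 2), mk(5, 0.04, 2), mk(2, 0.02, 6),
                 mk(3, 0.04, 6))
  expect_equal(best_condition(curves)[c("sf", "tf")],
               list(sf = 0.04, tf = 2))
  ties <- list(mk(2, 0.04, 6), mk(2, 0.02, 6), mk(2, 0.04, 2),
               mk(2, 0.02, 2))
  expect_equal(best_condition(ties)[c("sf", "tf")],
               list(sf = 0.02, tf = 2))
  expect_error(best_condition(list()), "no curves")
})
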