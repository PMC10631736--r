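# shared fixtures, built once per test run

.fixtures <- new.env(parent = emptyenv())

test_geometry <- function() display_geometry(pixels_x = 32, pixels_y = 24)

# small session without noise epochs: classification and metrics tests
tiny_session <- function() {
  if (is.null(.fixtures$tiny)) {
    .fixtures$tiny <- make_session(
      default_population(n_component = 4, n_blobby = 2, n_pattern = 2,
                         n_complex = 2),
      default_protocol(n_trials = 8, n_noise = 0),
      test_geometry(), seed = 101)
  }
  .fixtures$tiny
}

# single-unit session with noise epochs: STA tests
noise_session <- function() {
  if (is.null(.fixtures$noise)) {
    .fixtures$noise <- make_session(
      default_population(n_component = 1, n_blobby = 0, n_pattern = 0,
                         n_complex = 0),
      default_protocol(n_trials = 1, sfs = 0.02, n_noise = 12,
                       noise_duration = 30),
      test_geometry(), seed = 202)
  }
  .fixtures$noise
}

# von Mises tuning bump on the 12-direction grid
vm_curve <- function(pref, kappa = 4) {
  exp(kappa * (cos((protocol_directions() - pref) * pi / 180) - 1))
}

# full-scale session for the headline analyses: 5 units of each mechanism
# class, the complete 20-trial battery and 20 x 60-s noise movies on a
# 48 x 36 grid, plus the LN-prediction table with its STA sequences
headline_session <- function() {
  if (is.null(.fixtures$headline)) {
    .fixtures$headline <- make_session(
      default_population(n_component = 5, n_blobby = 5, n_pattern = 5,
                         n_complex = 0),
      default_protocol(n_trials = 20, n_noise = 20, noise_duration = 60),
      display_geometry(), seed = 7)
  }
  .fixtures$headline
}

headline_ln_table <- function() {
  if (is.null(.fixtures$headline_ln)) {
    .fixtures$headline_ln <- ln_prediction_table(headline_session(),
                                                 n_perm = 100, seed = 11)
  }
  .fixtures$headline_ln
}
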