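test_that("component prediction is the circular shifted sum", {
  delta <- rep(0, 12); delta[4] <- 1  # peak at 90 degrees
  pred <- component_prediction(delta, 120)
  expect_equal(which(pred > 0), c(2, 6))  # 30 and 150 degrees
  expect_equal(component_prediction(rep(1, 12)), rep(2, 12))
  # oracle: explicit loop over shifted copies
  set.seed(1)
  for (i in 1:25) {
    g <- stats::runif(12)
    oracle <- vapply(0:11, function(th) {
      g[(th - 2) %% 12 + 1] + g[(th + 2) %% 12 + 1]
    }, numeric(1))
    expect_equal(component_prediction(g, 120), oracle)
  }
  expect_error(component_prediction(stats::runif(12), 100), "multiple")
})

test_that("pattern prediction is the identity", {
  g <- stats::runif(12)
  expect_identical(pattern_prediction(g), g)
  expect_equal(stats::cor(pattern_prediction(g), g), 1)
})

test_that("partial correlations match the residual-regression oracle", {
  set.seed(42)
  for (i in 1:100) {
    o <- stats::rnorm(12); cp <- stats::rnorm(12); pp <- stats::rnorm(12)
    pc <- partial_correlations(o, cp, pp)
    # oracle: correlate residuals after regressing out the other predictor
    rc_or <- stats::cor(stats::resid(stats::lm(o ~ pp)),
                        stats::resid(stats::lm(cp ~ pp)))
    rp_or <- stats::cor(stats::resid(stats::lm(o ~ cp)),
                        stats::resid(stats::lm(pp ~ cp)))
    expect_lt(abs(pc$rc - rc_or), 1e-10)
    expect_lt(abs(pc$rp - rp_or), 1e-10)
  }
  expect_true(is.na(partial_correlations(rep(1, 12), stats::rnorm(12),
                                         stats::rnorm(12))$rc))
})

test_that("perfect pattern and component limits behave as expected", {
  g <- vm_curve(90)
  cp <- component_prediction(g)
  pp <- pattern_prediction(g)
  lim <- partial_correlations(pp, cp, pp)
  expect_gt(lim$rp, 0.999)
  lim2 <- partial_correlations(cp, cp, pp)
  expect_gt(lim2$rc, 0.999)
  # exchange symmetry: swapping the predictions swaps (rc, rp)
  o <- stats::rnorm(12)
  a <- partial_correlations(o, cp, pp)
  b <- partial_correlations(o, pp, cp)
  expect_equal(a$rc, b$rp)
  expect_equal(a$rp, b$rc)
})

test_that("Fisher z uses sqrt(n - 3) and is odd", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5, 12), 3 * atanh(0.5), tolerance = 1e-12)
  expect_equal(fisher_z(0.5, 12), 1.6479, tolerance = 1e-4)
  for (r in c(0.1, 0.6, 0.95))
    expect_equal(fisher_z(-r), -fisher_z(r))
  expect_error(fisher_z(0.5, 3), "exceed")
  # clipping keeps the transform finite at |r| = 1
  expect_true(is.finite(fisher_z(1)))
})

test_that("the label rule partitions the Zp/Zc plane", {
  expect_equal(classify_zpzc(4, 0)$label, "pattern")
  expect_equal(classify_zpzc(0, 4)$label, "component")
  expect_equal(classify_zpzc(0.5, 0.5)$label, "unclassified")
  expect_equal(classify_zpzc(4, 3.5)$label, "unclassified")
  # zc below zero does not make the pattern criterion easier
  expect_equal(classify_zpzc(1.5, -5)$label, "pattern")
  expect_equal(classify_zpzc(1.2, -5)$label, "unclassified")
  expect_true(classify_zpzc(4, 0, dsi = 0.5)$direction_selective)
  expect_false(classify_zpzc(4, 0, dsi = 0.2)$direction_selective)
  expect_equal(pattern_index(2, 0), 2)
  expect_equal(pattern_index(1, 1), 0)
  expect_equal(pattern_index(3, 1), -pattern_index(1, 3))
})

test_that("classification is invariant to response scaling", {
  g <- vm_curve(60); p <- component_prediction(g) + 0.1 * vm_curve(60)
  base <- classify_pair(g, p)
  for (k in c(0.2, 3, 40)) {
    scaled <- classify_pair(k * g, k * p)
    expect_equal(scaled$rc, base$rc, tolerance = 1e-12)
    expect_equal(scaled$rp, base$rp, tolerance = 1e-12)
    expect_equal(scaled$label, base$label)
  }
})

test_that("class recovery on a synthetic session", {
  s <- tiny_session()
  tab <- session_classification_table(s)
  comp <- tab$kind == "ln_component"
  expect_gte(mean(tab$label[comp] == "component"), 0.9)
  pat <- tab$kind == "pooled_pattern"
  expect_gte(mean(tab$label[pat] == "pattern"), 0.9)
  blob <- tab$kind == "ln_blobby"
  expect_true(all(tab$label[blob] %in% c("pattern", "unclassified")))
  expect_true(all(tab$responsive))
  expect_true(all(tab$dsi > 0.33))
})

test_that("population averages align and recombine correctly", {
  # identical ideal pattern units at scattered preferred directions
  pairs <- lapply(c(0, 60, 150, 270), function(d)
    list(grating = vm_curve(d), plaid = vm_curve(d)))
  avg <- population_average_curves(pairs)
  expect_equal(avg$grating, avg$plaid, tolerance = 1e-12)
  expect_equal(avg$directions[which.max(avg$grating)], 0)
  expect_gt(avg$pi, 3)
  # component population: averaged plaid bimodal at +/- 60
  pairs_c <- lapply(c(30, 120, 210, 300), function(d)
    list(grating = vm_curve(d), plaid = component_prediction(vm_curve(d))))
  avg_c <- population_average_curves(pairs_c)
  pk <- order(avg_c$plaid, decreasing = TRUE)[1:2]
  expect_setequal(avg_c$directions[pk], c(-60, 60))
  expect_error(population_average_curves(pairs_c[1]), "at least 2")
})
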