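#' Default pipeline configuration
#'
#' All protocol constants, population spec, analysis parameters and the
#' master seed in one list; any element can be overridden via `...` (named
#' sublists are merged shallowly). `preset = "smoke"` switches to a reduced
#' problem size for quick end-to-end runs.
#'
#' @param preset `"default"` or `"smoke"`.
#' @param ... overrides, e.g. `population = list(n_component = 4)`.
#' @return nested configuration list.
#' @export
default_config <- function(preset = c("default", "smoke"), ...) {
  preset <- match.arg(preset)
  cfg <- list(
    geometry = list(pixels_x = 64, pixels_y = 48),
    population = default_population(),
    protocol = default_protocol(),
    sta = list(n_lags = 10, n_perm = 200, ridge_fraction = 0.1),
    classify = list(z_crit = 1.28, dsi_crit = 0.33),
    ln = list(upsample = 2, exponent = 2, ci_floor_quantile = 0.95),
    regression = list(bank_size = 16, seed_offset = 50),
    seed = 1)
  if (preset == "smoke") {
    cfg$geometry <- list(pixels_x = 32, pixels_y = 24)
    cfg$population <- default_population(n_component = 3, n_blobby = 2,
                                         n_pattern = 2, n_complex = 1)
    cfg$protocol <- default_protocol(n_trials = 5, n_noise = 4,
                                     noise_duration = 20)
    cfg$sta$n_perm <- 100
  }
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(cfg[[nm]]))
      cfg[[nm]] <- utils::modifyList(cfg[[nm]], over[[nm]])
    else cfg[[nm]] <- over[[nm]]
  }
  cfg
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA), f)
  unname(tools::md5sum(f))
}

#' Run the complete analysis pipeline
#'
#' simulate -> tuning metrics -> Zp/Zc classification -> STA -> LN
#' prediction -> regressor-bank modelling, on one synthetic session. All
#' stage outputs are returned in a bundle and, when `out_dir` is given,
#' written as CSV/JSON stamped with the configuration hash and seed.
#' Identical configuration and seed give identical outputs.
#'
#' @param config a [default_config()] list.
#' @param out_dir optional output directory.
#' @param run_sta run the STA/LN stages (the slow part).
#' @return list with `session`, `metrics`, `classification`, `ln`
#'   (prediction table), `transitions`, `regression`, `banks`, `config`,
#'   `summary`.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL,
                         run_sta = TRUE) {
  seed <- config$seed
  if (is.null(seed)) stop("config must carry a seed")
  geometry <- display_geometry(pixels_x = config$geometry$pixels_x,
                               pixels_y = config$geometry$pixels_y)
  session <- make_session(config$population, config$protocol, geometry,
                          seed = seed)
  metrics <- session_metrics_table(session)
  classification <- session_classification_table(
    session, config$classify$z_crit, config$classify$dsi_crit)

  ln_tab <- NULL; transitions <- NULL
  if (run_sta && any(session$trials$kind == "noise")) {
    ln_tab <- ln_prediction_table(
      session, n_perm = config$sta$n_perm, seed = seed + 1000,
      ci_floor_quantile = config$ln$ci_floor_quantile,
      upsample = config$ln$upsample, exponent = config$ln$exponent)
    ok <- !ln_tab$excluded & ln_tab$consistent
    transitions <- transition_summary(ln_tab$observed_label[ok],
                                      ln_tab$predicted_label[ok])
  }

  banks <- list(
    component = make_regressor_bank(config$regression$bank_size,
                                    "component",
                                    seed = seed + config$regression$seed_offset),
    pattern = make_regressor_bank(config$regression$bank_size, "pattern",
                                  seed = seed + config$regression$seed_offset + 1),
    unclassified = make_regressor_bank(config$regression$bank_size,
                                       "unclassified",
                                       seed = seed + config$regression$seed_offset + 2))
  regression <- session_regression_table(session, banks, seed = seed + 2000)

  summary <- list(
    config_hash = config_hash(config), seed = seed,
    n_units = length(session$units),
    n_trials = nrow(session$trials),
    observed_label_counts = as.list(table(classification$label)),
    median_pi_by_kind = lapply(
      split(classification$pi, classification$kind), stats::median),
    transitions = transitions,
    matched_bank_win =
      if (nrow(regression) > 0) mean_matched_bank_win(regression) else NA)

  bundle <- list(session = session, metrics = metrics,
                 classification = classification, ln = ln_tab,
                 transitions = transitions, regression = regression,
                 banks = banks, config = config, summary = summary)
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

mean_matched_bank_win <- function(regression) {
  sel <- regression$kind %in% c("ln_component", "pooled_pattern")
  if (!any(sel)) return(NA_real_)
  r <- regression[sel, ]
  matched <- ifelse(r$kind == "ln_component", "component", "pattern")
  mean(r$best_bank == matched)
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(bundle$metrics, file.path(out_dir, "metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$classification,
                   file.path(out_dir, "classification.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$session$ground_truth,
                   file.path(out_dir, "ground_truth.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$session$trials, file.path(out_dir, "trials.csv"),
                   row.names = FALSE)
  if (!is.null(bundle$ln))
    utils::write.csv(bundle$ln, file.path(out_dir, "ln_prediction.csv"),
                     row.names = FALSE)
  if (!is.null(bundle$regression))
    utils::write.csv(bundle$regression,
                     file.path(out_dir, "regression.csv"),
                     row.names = FALSE)
  writeLines(jsonlite::toJSON(bundle$summary, auto_unbox = TRUE,
                              digits = NA, pretty = TRUE, na = "null"),
             file.path(out_dir, "summary.json"))
  invisible(out_dir)
}

#' Figure-style report panels
#'
#' Standard diagnostic figures from a pipeline bundle: the Zp/Zc scatter
#' with classification boundaries, class fractions per ground-truth kind,
#' CI distributions, LN-prediction transition bars and aligned
#' population-average curves. Panels are returned as ggplot objects and,
#' when `out_dir` is given, written as PNG.
#'
#' @param bundle result of [run_pipeline()].
#' @param out_dir optional directory for PNG output.
#' @return named list of ggplot objects.
#' @export
make_report <- function(bundle, out_dir = NULL) {
  cl <- bundle$classification
  z_crit <- bundle$config$classify$z_crit
  clip_ax <- function(x) pmax(pmin(x, 12), -4)
  p_scatter <- ggplot2::ggplot(
    cl, ggplot2::aes(x = clip_ax(zc), y = clip_ax(zp), colour = label)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(yintercept = z_crit, linetype = 2) +
    ggplot2::geom_vline(xintercept = z_crit, linetype = 2) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 3) +
    ggplot2::labs(x = "Zc", y = "Zp", colour = "label",
                  title = "Pattern/component classification") +
    ggplot2::theme_minimal()
  p_fractions <- ggplot2::ggplot(
    cl, ggplot2::aes(x = kind, fill = label)) +
    ggplot2::geom_bar(position = "fill") +
    ggplot2::labs(y = "fraction", title = "Labels by ground-truth kind") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
  panels <- list(zpzc_scatter = p_scatter, label_fractions = p_fractions)
  if (!is.null(bundle$ln)) {
    panels$ci_by_kind <- ggplot2::ggplot(
      bundle$ln, ggplot2::aes(x = kind, y = ci)) +
      ggplot2::geom_boxplot() +
      ggplot2::labs(y = "best-frame CI", title = "STA contrast index") +
      ggplot2::theme_minimal() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                         hjust = 1))
    tr <- bundle$transitions
    if (!is.null(tr)) {
      trl <- stats::reshape(
        tr, direction = "long",
        varying = c("to_same", "to_opposite", "to_unclassified"),
        v.names = "fraction", timevar = "transition",
        times = c("to_same", "to_opposite", "to_unclassified"))
      panels$transitions <- ggplot2::ggplot(
        trl[!is.na(trl$fraction), ],
        ggplot2::aes(x = observed_label, y = fraction, fill = transition)) +
        ggplot2::geom_col(position = "dodge") +
        ggplot2::labs(title = "Classification transitions under LN prediction") +
        ggplot2::theme_minimal()
    }
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(panels))
      ggplot2::ggsave(file.path(out_dir, paste0(nm, ".png")), panels[[nm]],
                      width = 6, height = 4, dpi = 120)
  }
  panels
}
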