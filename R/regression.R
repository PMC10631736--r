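#' Ridge regression of a tuning profile on a regressor bank
#'
#' Models a unit's concatenated grating+plaid direction tuning (a 24-vector,
#' peak-normalised) as a linear combination of the tuning curves of the bank
#' members, with ridge regularisation and cross-validated error. Folds hold
#' out direction bins (leave-3-bins-out, 8 folds over the 24 bins),
#' stratified so every fold contains both grating and plaid bins. The ridge
#' penalty is selected from a log-spaced grid by the same cross-validation;
#' `cv_rmse` is the prediction RMSE over held-out bins at the selected
#' penalty and `weights` come from a final fit on all bins.
#'
#' @param target numeric 24-vector (12 grating + 12 plaid responses).
#' @param bank a `regressor_bank` (or bare members-by-24 matrix).
#' @param ridge_lambda a single penalty, or `NULL` to select from
#'   `lambda_grid`.
#' @param lambda_grid candidate penalties (default 7 log-spaced values).
#' @param n_folds number of CV folds (default 8).
#' @param seed seed for the fold assignment.
#' @return a `regression_fit`: list with `weights`, `lambda`, `cv_rmse`,
#'   `predicted` (24-vector), `bank_class`.
#' @export
fit_tuning_regression <- function(target, bank, ridge_lambda = NULL,
                                  lambda_grid = 10^seq(-3, 3, by = 1),
                                  n_folds = 8, seed = 1) {
  X <- t(if (inherits(bank, "regressor_bank")) bank$curves else bank)
  stopifnot(length(target) == 24, nrow(X) == 24)
  if (stats::sd(target) == 0) stop("flat target tuning profile")
  pk <- max(abs(target))
  y <- target / pk
  if (!is.null(ridge_lambda)) {
    if (ridge_lambda <= 0 && qr(X)$rank < ncol(X))
      stop("singular design with lambda = 0; use lambda > 0")
    lambda_grid <- ridge_lambda
  }
  folds <- make_cv_folds(n_folds, seed)
  ridge_solve <- function(Xt, yt, lam) {
    p <- ncol(Xt)
    solve(crossprod(Xt) + diag(lam, p), crossprod(Xt, yt))
  }
  cv_rmse_for <- function(lam) {
    errs <- unlist(lapply(folds, function(ho) {
      w <- ridge_solve(X[-ho, , drop = FALSE], y[-ho], lam)
      as.numeric(X[ho, , drop = FALSE] %*% w) - y[ho]
    }))
    sqrt(mean(errs^2))
  }
  cv <- vapply(lambda_grid, cv_rmse_for, numeric(1))
  best <- which.min(cv)
  w <- ridge_solve(X, y, lambda_grid[best])
  fit <- list(weights = as.numeric(w), lambda = lambda_grid[best],
              cv_rmse = cv[best], cv_path = stats::setNames(cv, lambda_grid),
              predicted = as.numeric(X %*% w) * pk,
              bank_class = if (inherits(bank, "regressor_bank")) bank$class
                           else NA_character_)
  class(fit) <- "regression_fit"
  fit
}

# leave-3-bins-out folds over the 24 concatenated bins; bins 1:12 are
# grating, 13:24 plaid; stratified so each fold holds out bins of both kinds
make_cv_folds <- function(n_folds = 8, seed = 1) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed %% .Machine$integer.max))
  repeat {
    idx <- c(sample(1:12), sample(13:24))
    # interleave gratings and plaids before chunking so folds mix kinds
    mix <- as.numeric(rbind(idx[1:12], idx[13:24]))
    folds <- split(mix, rep(seq_len(n_folds), each = 24 / n_folds))
    ok <- all(vapply(folds, function(f) any(f <= 12) && any(f > 12),
                     logical(1)))
    if (ok) return(unname(folds))
  }
}

#' Compare regressor banks for one unit
#'
#' Fits the target against every bank and ranks them by cross-validated
#' RMSE. The confidence of the winning model is its relative RMSE advantage
#' over the runner-up, `(second - best) / second`, in `[0, 1)`; values above
#' 0.3 are conventionally treated as high confidence.
#'
#' @param target numeric 24-vector.
#' @param banks named list of `regressor_bank`s.
#' @param ... passed to [fit_tuning_regression()].
#' @return list with `best_bank` (name), `confidence`, `cv_rmse` (named
#'   vector), `fits` (list of `regression_fit`s).
#' @export
model_comparison <- function(target, banks, ...) {
  stopifnot(length(banks) >= 2)
  fits <- lapply(banks, function(b) fit_tuning_regression(target, b, ...))
  rmse <- vapply(fits, `[[`, numeric(1), "cv_rmse")
  ord <- order(rmse)
  best <- ord[1]; second <- ord[2]
  conf <- if (rmse[second] > 0)
    max(0, (rmse[second] - rmse[best]) / rmse[second]) else 0
  if (rmse[best] == rmse[second]) best <- which(rmse == rmse[best])[1]
  list(best_bank = names(banks)[best], confidence = conf, cv_rmse = rmse,
       fits = fits)
}

#' Population-averaged predicted tuning curves
#'
#' Assembles per-unit predicted 24-vectors (from regression fits against
#' one bank) into grating/plaid curve pairs and averages them across units
#' after aligning each unit's preferred grating direction to zero,
#' recomputing Zc/Zp/PI on the averages.
#'
#' @param fits list of `regression_fit`s (one per unit, same bank).
#' @param cross_angle plaid cross angle, degrees.
#' @return see [population_average_curves()].
#' @export
predicted_population_curves <- function(fits, cross_angle = 120) {
  pairs <- lapply(fits, function(f)
    list(grating = f$predicted[1:12], plaid = f$predicted[13:24]))
  population_average_curves(pairs, cross_angle = cross_angle)
}

#' Regression model comparison across a session
#'
#' For every responsive unit, the observed grating+plaid profile at the best
#' condition is regressed on each bank; the table records per-bank
#' cross-validated RMSE, the best bank and the confidence score.
#'
#' @param session a `session`.
#' @param banks named list of `regressor_bank`s.
#' @param seed fold-assignment seed.
#' @return data.frame, one row per unit.
#' @export
session_regression_table <- function(session, banks, seed = 1) {
  n <- length(session$units)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    cl <- classify_session_unit(session, i)
    key <- sprintf("sf%g_tf%g", cl$best_sf, cl$best_tf)
    target <- c(cl$curves$grating[[key]]$responses,
                cl$curves$plaid[[key]]$responses)
    if (stats::sd(target) == 0) next
    mc <- model_comparison(target, banks, seed = seed + i)
    row <- data.frame(unit_id = session$units[[i]]$unit_id,
                      kind = session$units[[i]]$kind,
                      observed_label = cl$label,
                      best_bank = mc$best_bank, confidence = mc$confidence)
    for (b in names(banks))
      row[[paste0("rmse_", b)]] <- mc$cv_rmse[[b]]
    rows[[i]] <- row
  }
  do.call(rbind, rows)
}
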