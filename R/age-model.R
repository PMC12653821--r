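#' Fit the cognitive age model with k-fold cross-validation
#'
#' Models chronological age as a linear function of z-scored neuropsychological
#' features, trained on the biomarker-negative reference group by minimizing
#' mean squared error. The pipeline is a feature scaler followed by an
#' unregularized least-squares regressor. A k-fold cross-validation scheme
#' produces an out-of-fold prediction for every training participant; those
#' out-of-fold predictions — never the optimistic in-sample ones — calibrate
#' the regression-to-the-mean bias correction. The final coefficients are
#' refit on the full training sample.
#'
#' @param table Participant table with `age`, `group` and the feature columns
#'   (normally already education-corrected).
#' @param features Ordered predictor names.
#' @param fit_group Clinical group to train on.
#' @param folds Number of cross-validation folds (default 5).
#' @param seed Seed for the shuffled fold assignment.
#' @param bias_method `"subtract"` (default) regresses the raw prediction
#'   error on age and subtracts the fitted line from predictions;
#'   `"invert"` regresses predicted on chronological age and inverts that
#'   line. Both need chronological age at prediction time, which the
#'   cognitive age delta always has.
#' @param scale_within_folds If `TRUE`, the scaler is re-estimated inside each
#'   training fold instead of once on the full fit sample.
#' @return An object of class `cognitive_age_model`.
#' @export
fit_age_model <- function(table, features, fit_group = "CUA-V-", folds = 5L,
                          seed = 1L, bias_method = c("subtract", "invert"),
                          scale_within_folds = FALSE) {
  bias_method <- match.arg(bias_method)
  rows <- if (is.null(fit_group)) table else
    table[table$group %in% fit_group, , drop = FALSE]
  complete <- stats::complete.cases(rows[, c("age", features), drop = FALSE])
  rows <- rows[complete, , drop = FALSE]
  n <- nrow(rows)
  if (n < folds) {
    stop(sprintf("need at least %d complete rows for %d folds, got %d",
                 folds, folds, n), call. = FALSE)
  }
  y <- rows$age
  X <- as.matrix(rows[, features, drop = FALSE])
  mu <- colMeans(X)
  sdev <- apply(X, 2, stats::sd)
  if (any(sdev == 0)) {
    stop("constant feature(s): ", paste(features[sdev == 0], collapse = ", "),
         call. = FALSE)
  }
  Xs <- scale(X, center = mu, scale = sdev)

  qrX <- qr(cbind(`(Intercept)` = 1, Xs))
  if (qrX$rank < ncol(Xs) + 1L) {
    dep <- colnames(cbind(`(Intercept)` = 1, Xs))[qrX$pivot[-seq_len(qrX$rank)]]
    stop("rank-deficient design; linearly dependent column(s): ",
         paste(dep, collapse = ", "), call. = FALSE)
  }

  set.seed(seed)
  fold <- sample(rep(seq_len(folds), length.out = n))
  y_hat_oof <- numeric(n)
  fold_mse <- numeric(folds)
  for (k in seq_len(folds)) {
    tr <- fold != k
    if (scale_within_folds) {
      mu_k <- colMeans(X[tr, , drop = FALSE])
      sd_k <- apply(X[tr, , drop = FALSE], 2, stats::sd)
      Xtr <- scale(X[tr, , drop = FALSE], mu_k, sd_k)
      Xte <- scale(X[!tr, , drop = FALSE], mu_k, sd_k)
    } else {
      Xtr <- Xs[tr, , drop = FALSE]
      Xte <- Xs[!tr, , drop = FALSE]
    }
    fit_k <- stats::lm.fit(cbind(1, Xtr), y[tr])
    pred <- drop(cbind(1, Xte) %*% fit_k$coefficients)
    y_hat_oof[!tr] <- pred
    fold_mse[k] <- mean((pred - y[!tr])^2)
  }

  bias_line <- fit_bias_correction(y_hat_oof, y, method = bias_method)

  final <- stats::lm.fit(cbind(1, Xs), y)
  coefs <- final$coefficients
  structure(
    list(
      feature_order = features,
      scaler = tibble::tibble(feature = features, mean = unname(mu),
                              sd = unname(sdev)),
      coefficients = coefs[-1], intercept = unname(coefs[1]),
      bias_method = bias_method, bias_line = bias_line,
      cv = list(folds = folds, seed = seed, fold_mse = fold_mse),
      oof = tibble::tibble(id = rows$id, y = y, y_hat_oof = y_hat_oof),
      fit_group = fit_group, n_fit = n
    ),
    class = "cognitive_age_model"
  )
}

#' Fit the regression-to-the-mean bias-correction line
#'
#' Age models overpredict young and underpredict old participants. With
#' `method = "subtract"` the raw prediction error (predicted minus
#' chronological age) is regressed on chronological age; the fitted line
#' `a * y + b` is later subtracted from raw predictions. With
#' `method = "invert"` the predicted age is regressed on chronological age
#' and the fitted line is inverted.
#'
#' @param predictions Raw predicted ages (out-of-fold in the standard pipeline).
#' @param ages Chronological ages for the same participants.
#' @param method `"subtract"` or `"invert"`.
#' @return Named numeric `c(slope, intercept)` of the fitted line (error on
#'   age for `"subtract"`, prediction on age for `"invert"`).
#' @export
fit_bias_correction <- function(predictions, ages,
                                method = c("subtract", "invert")) {
  method <- match.arg(method)
  if (length(predictions) != length(ages) || length(ages) < 3) {
    stop("need at least 3 (prediction, age) pairs", call. = FALSE)
  }
  if (stats::var(ages) == 0) stop("ages have zero variance", call. = FALSE)
  if (method == "subtract") ols_line(ages, predictions - ages)
  else ols_line(ages, predictions)
}

apply_bias_correction <- function(y_hat_raw, y, bias_line, bias_method) {
  if (bias_method == "subtract") {
    y_hat_raw - (bias_line[["slope"]] * y + bias_line[["intercept"]])
  } else {
    if (bias_line[["slope"]] == 0) stop("degenerate bias line (zero slope)", call. = FALSE)
    (y_hat_raw - bias_line[["intercept"]]) / bias_line[["slope"]]
  }
}

#' Predict cognitive age and the cognitive age delta
#'
#' Applies the fitted scaler, regression and bias correction to every row that
#' is complete on the model features, in any clinical group — the reference
#' model is reused unchanged for the pathology groups. The cognitive age
#' delta (CAD) is the bias-corrected predicted age minus chronological age;
#' positive values mean cognition looks older than the calendar says.
#'
#' @param model A [fit_age_model()] result.
#' @param table Participant table.
#' @return A tibble with columns `id`, `group` (if present), `y`
#'   (chronological age), `y_hat_raw`, `y_hat_corrected`, `cad`. Rows missing
#'   any model feature are skipped; their ids are in the `"skipped"`
#'   attribute and a message reports the count.
#' @export
predict_cad <- function(model, table) {
  stopifnot(inherits(model, "cognitive_age_model"))
  feats <- model$feature_order
  missing_cols <- setdiff(c("age", feats), names(table))
  if (length(missing_cols)) {
    stop("table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  complete <- stats::complete.cases(table[, c("age", feats), drop = FALSE])
  skipped <- if ("id" %in% names(table)) table$id[!complete] else which(!complete)
  if (any(!complete)) {
    message(sprintf("predict_cad: skipping %d row(s) with missing features",
                    sum(!complete)))
  }
  rows <- table[complete, , drop = FALSE]
  X <- as.matrix(rows[, feats, drop = FALSE])
  Xs <- scale(X, center = model$scaler$mean, scale = model$scaler$sd)
  y_hat_raw <- drop(Xs %*% model$coefficients) + model$intercept
  y <- rows$age
  y_hat_corrected <- apply_bias_correction(y_hat_raw, y, model$bias_line,
                                           model$bias_method)
  out <- tibble::tibble(
    id = if ("id" %in% names(rows)) rows$id else as.character(seq_len(nrow(rows))),
    y = y, y_hat_raw = y_hat_raw, y_hat_corrected = y_hat_corrected,
    cad = y_hat_corrected - y
  )
  if ("group" %in% names(rows)) out <- cbind(out[1], group = rows$group, out[-1])
  out <- tibble::as_tibble(out)
  attr(out, "skipped") <- skipped
  out
}

#' Out-of-fold cognitive age deltas for the training sample
#'
#' Returns the bias-corrected delta computed from each training participant's
#' out-of-fold prediction. Because the bias line is the least-squares fit to
#' exactly these out-of-fold errors, the returned deltas have mean zero and
#' zero regression slope on age by construction (to numerical precision)
#' under the `"subtract"` method.
#'
#' @param model A [fit_age_model()] result.
#' @return A tibble `id`, `y`, `y_hat_oof`, `y_hat_corrected`, `cad`.
#' @export
oof_cad <- function(model) {
  stopifnot(inherits(model, "cognitive_age_model"))
  oof <- model$oof
  corrected <- apply_bias_correction(oof$y_hat_oof, oof$y, model$bias_line,
                                     model$bias_method)
  tibble::tibble(id = oof$id, y = oof$y, y_hat_oof = oof$y_hat_oof,
                 y_hat_corrected = corrected, cad = corrected - oof$y)
}

#' @export
print.cognitive_age_model <- function(x, ...) {
  cat(sprintf("Cognitive age model: %d features, fit on %s (n = %d)\n",
              length(x$feature_order), paste(x$fit_group, collapse = "/"),
              x$n_fit))
  cat(sprintf("  %d-fold CV RMSE: %.2f years; bias line (%s): slope %.3f, intercept %.2f\n",
              x$cv$folds, sqrt(mean(x$cv$fold_mse)), x$bias_method,
              x$bias_line[["slope"]], x$bias_line[["intercept"]]))
  invisible(x)
}

#' Serialize / restore a cognitive age model as JSON
#'
#' @param model A `cognitive_age_model`.
#' @param path JSON file path.
#' @return `write_age_model()` returns `path` invisibly; `read_age_model()`
#'   returns the model (without the out-of-fold table, which is a training
#'   artifact, retained in serialized form for audit).
#' @export
write_age_model <- function(model, path) {
  stopifnot(inherits(model, "cognitive_age_model"))
  payload <- list(
    feature_order = model$feature_order,
    scaler = model$scaler,
    coefficients = as.list(model$coefficients),
    intercept = model$intercept,
    bias_method = model$bias_method,
    bias_line = as.list(model$bias_line),
    cv = model$cv,
    oof = model$oof,
    fit_group = model$fit_group,
    n_fit = model$n_fit
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_age_model
#' @export
read_age_model <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(
      feature_order = raw$feature_order,
      scaler = tibble::as_tibble(raw$scaler),
      coefficients = stats::setNames(unlist(raw$coefficients), names(raw$coefficients)),
      intercept = raw$intercept,
      bias_method = raw$bias_method,
      bias_line = stats::setNames(unlist(raw$bias_line), names(raw$bias_line)),
      cv = raw$cv,
      oof = tibble::as_tibble(raw$oof),
      fit_group = raw$fit_group,
      n_fit = raw$n_fit
    ),
    class = "cognitive_age_model"
  )
}
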