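#' Fit the per-feature education correction
#'
#' For each feature, a simple ordinary-least-squares regression of the score
#' on years of education is fitted within the reference group. The model
#' stores, per feature, the fitting-sample mean, the education slope and
#' intercept, and the fitting n. Rows outside the fitting group are later
#' corrected with these same normative coefficients — the pathology groups
#' never influence the estimated education effect.
#'
#' @param table Participant table with `education` and the feature columns.
#' @param features Feature names to correct.
#' @param fit_group Clinical group to fit within; `NULL` uses all rows.
#' @return An object of class `education_model`: a tibble with one row per
#'   feature (`feature`, `x_bar`, `slope`, `intercept`, `n`) plus the
#'   `fit_group` attribute.
#' @export
fit_education_model <- function(table, features, fit_group = "CUA-V-") {
  rows <- if (is.null(fit_group)) table else
    table[table$group %in% fit_group, , drop = FALSE]
  fits <- lapply(features, function(f) {
    ok <- !is.na(rows$education) & !is.na(rows[[f]])
    if (sum(ok) < 3) {
      stop(sprintf("fewer than 3 complete (education, %s) pairs in fit group", f),
           call. = FALSE)
    }
    edu <- rows$education[ok]
    if (stats::var(edu) == 0) {
      stop("education has zero variance in the fitting sample", call. = FALSE)
    }
    line <- ols_line(edu, rows[[f]][ok])
    tibble::tibble(feature = f, x_bar = mean(rows[[f]][ok]),
                   slope = line[["slope"]], intercept = line[["intercept"]],
                   n = sum(ok))
  })
  structure(do.call(rbind, fits),
            fit_group = fit_group,
            class = c("education_model", class(tibble::tibble())))
}

#' Apply the education correction to a participant table
#'
#' Replaces each modeled feature by its education residual recentered on the
#' fitting-sample mean:
#' \deqn{X_{corrected} = \bar{X} + (X - \hat{X}),}
#' where \eqn{\hat{X}} is the education-predicted score. Recentring on
#' \eqn{\bar{X}} preserves the original scale and range of the test, unlike a
#' plain residual. Rows with missing education cannot be corrected: their
#' feature values are set to missing (and counted in the `"n_flagged"`
#' attribute) so they are excluded rather than passed through uncorrected.
#'
#' @param model An [fit_education_model()] result.
#' @param table Participant table (any group; the normative model is reused).
#' @return The table with corrected feature columns; attribute `"n_flagged"`
#'   counts rows with missing education.
#' @export
apply_education_correction <- function(model, table) {
  stopifnot(inherits(model, "education_model"))
  edu_missing <- is.na(table$education)
  for (i in seq_len(nrow(model))) {
    f <- model$feature[i]
    if (!f %in% names(table)) {
      stop("feature '", f, "' not present in table", call. = FALSE)
    }
    x_hat <- model$intercept[i] + model$slope[i] * table$education
    corrected <- model$x_bar[i] + (table[[f]] - x_hat)
    corrected[edu_missing] <- NA_real_
    table[[f]] <- corrected
  }
  attr(table, "n_flagged") <- sum(edu_missing)
  table
}
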