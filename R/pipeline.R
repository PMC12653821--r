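#' Run the full cognitive-age-delta pipeline on a participant table
#'
#' Chains every stage in the canonical order: biomarker classification,
#' age-sensitivity feature screening in the reference group, education
#' correction (fit on the reference group, applied to everyone), cognitive
#' age model fitting with cross-validated bias correction, CAD prediction
#' for all classifiable participants, and the grouped association suite.
#'
#' @param cohort Participant table (e.g. from [generate_cohort()] or
#'   [read_cohort()]).
#' @param config An [analysis_config()].
#' @param cutoffs A [biomarker_cutoffs()] object.
#' @param fit_group Reference group used for screening, education correction
#'   and model training.
#' @param fit_rows How CAD is computed for the participants the model was
#'   trained on: `"out_of_fold"` (default) takes each training participant's
#'   cross-validated prediction, so their CAD carries no in-sample optimism
#'   (a refit model's residuals are orthogonal to everything it has learned,
#'   which shrinks training-group CAD variance and attenuates associations);
#'   `"refit"` uses the full-sample refit model for everyone. Pathology
#'   groups always use the refit model.
#' @return A list of class `cad_pipeline`: `cohort` (classified table),
#'   `selection`, `education_model`, `age_model`, `cad` (tibble of CAD
#'   records), `group_comparison` (Kruskal-Wallis of CAD across groups, when
#'   more than one group is present) and `associations`.
#' @export
run_cad_pipeline <- function(cohort, config = analysis_config(),
                             cutoffs = biomarker_cutoffs(),
                             fit_group = "CUA-V-",
                             fit_rows = c("out_of_fold", "refit")) {
  fit_rows <- match.arg(fit_rows)
  classified <- classify_cohort(cohort, cutoffs)
  selection <- screen_features(classified, config$selected_features,
                               group = fit_group, config = config)
  if (!length(selection$selected)) {
    stop("no features survived age-sensitivity screening", call. = FALSE)
  }
  edu_model <- fit_education_model(classified, selection$selected, fit_group)
  corrected <- apply_education_correction(edu_model, classified)
  age_model <- fit_age_model(corrected, selection$selected, fit_group,
                             folds = config$cv_folds, seed = config$seed)
  cad <- predict_cad(age_model, corrected)
  if (fit_rows == "out_of_fold") {
    oo <- oof_cad(age_model)
    idx <- match(oo$id, cad$id)
    cad$y_hat_raw[idx] <- oo$y_hat_oof
    cad$y_hat_corrected[idx] <- oo$y_hat_corrected
    cad$cad[idx] <- oo$cad
  }
  comparison <- NULL
  analysis <- cad[cad$group %in% c("CUA-V-", "CUA+", "CUV+"), , drop = FALSE]
  if (length(unique(analysis$group)) >= 2) {
    comparison <- kruskal_wallis(analysis$cad, analysis$group)
  }
  associations <- run_association_suite(cad, classified, config)
  structure(
    list(cohort = classified, selection = selection, education_model = edu_model,
         age_model = age_model, cad = cad, group_comparison = comparison,
         associations = associations),
    class = "cad_pipeline"
  )
}

#' @export
print.cad_pipeline <- function(x, ...) {
  cat(sprintf("CAD pipeline: %d participants, %d features selected, model fit n = %d\n",
              nrow(x$cohort), length(x$selection$selected), x$age_model$n_fit))
  if (!is.null(x$group_comparison)) {
    cat(sprintf("  CAD across groups: H(%d) = %.2f, p = %.3g\n",
                x$group_comparison$df, x$group_comparison$H, x$group_comparison$p))
  }
  if (nrow(x$associations)) {
    sig <- x$associations[x$associations$model == "univariate" &
                            x$associations$significant_fdr, , drop = FALSE]
    cat(sprintf("  associations: %d fitted, %d significant after FDR\n",
                nrow(x$associations), nrow(sig)))
  }
  invisible(x)
}
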