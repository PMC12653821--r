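#' The default twelve-feature neuropsychological battery
#'
#' Ordered, duplicate-free list of the test scores used as cognitive-age
#' predictors: processing speed (Digit Symbol-Coding, Stroop naming, TMT-A),
#' executive function (Stroop interference, TMT-B, phonemic fluency), memory
#' (FCSRT free/total recall, ROCF delayed recall), language (Boston Naming,
#' semantic fluency) and visual perception (15-Objects Test).
#'
#' @return Character vector of length 12.
#' @export
default_feature_set <- function() {
  c("Digit Symbol-Coding",
    "Stroop Color Naming",
    "Stroop Word-Color Interference",
    "15-Objects Test",
    "ROCF Delayed Recall",
    "TMT-A",
    "FCSRT Immediate Total Free Recall",
    "TMT-B",
    "Boston Naming Test",
    "Phonemic Fluency P",
    "FCSRT Immediate Total Recall",
    "Semantic Fluency Animals")
}

#' Analysis configuration
#'
#' Bundles the knobs shared across pipeline stages: which features feed the
#' age model, how factors are grouped into multiple-testing families, the
#' significance level, the collinearity cap for feature selection, the number
#' of cross-validation folds, and an optional column-name map translating a
#' cohort export's headers to the canonical names used here.
#'
#' @param selected_features Ordered feature names (default: the 12-test battery).
#' @param factor_groups Named list: family name -> character vector of factor
#'   columns. Each family forms one false-discovery-rate correction block per
#'   clinical group.
#' @param alpha Type-I error rate, in (0, 1).
#' @param rho_max Collinearity cap on |Pearson rho| between selected features,
#'   in (0, 1].
#' @param cv_folds Number of cross-validation folds (>= 2).
#' @param seed Integer seed used for fold assignment.
#' @param column_name_map Named character vector: canonical name -> column
#'   name found in the file. Applied on read; identity by default.
#' @param sensitivity_covariates Covariates added in the covariate-adjusted
#'   sensitivity model for factors significant after FDR.
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(selected_features = default_feature_set(),
                            factor_groups = list(
                              cognitive_reserve = c("vocabulary",
                                                    "cognitive_reserve_questionnaire"),
                              lifestyle = c("daily_sitting_hours", "active_smoker")
                            ),
                            alpha = 0.05, rho_max = 0.7, cv_folds = 5L,
                            seed = 1L, column_name_map = NULL,
                            sensitivity_covariates = c("sex", "apoe4_load",
                                                       "education")) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)", call. = FALSE)
  if (rho_max <= 0 || rho_max > 1) stop("rho_max must lie in (0, 1]", call. = FALSE)
  if (cv_folds < 2) stop("cv_folds must be >= 2", call. = FALSE)
  structure(
    list(selected_features = selected_features, factor_groups = factor_groups,
         alpha = alpha, rho_max = rho_max, cv_folds = as.integer(cv_folds),
         seed = as.integer(seed), column_name_map = column_name_map,
         sensitivity_covariates = sensitivity_covariates),
    class = "analysis_config"
  )
}

#' Read or write an analysis configuration as JSON or YAML
#'
#' @param config An `analysis_config` object.
#' @param path File path ending in `.json`, `.yaml` or `.yml`.
#' @return `write_analysis_config()` returns `path` invisibly;
#'   `read_analysis_config()` returns an `analysis_config`.
#' @export
write_analysis_config <- function(config, path) {
  stopifnot(inherits(config, "analysis_config"))
  payload <- unclass(config)
  if (grepl("\\.ya?ml$", path)) yaml::write_yaml(payload, path)
  else jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_analysis_config
#' @export
read_analysis_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path) else jsonlite::read_json(path)
  analysis_config(
    selected_features = unlist(raw$selected_features),
    factor_groups = lapply(raw$factor_groups, unlist),
    alpha = raw$alpha %||% 0.05,
    rho_max = raw$rho_max %||% 0.7,
    cv_folds = raw$cv_folds %||% 5L,
    seed = raw$seed %||% 1L,
    column_name_map = if (length(raw$column_name_map)) unlist(raw$column_name_map) else NULL,
    sensitivity_covariates = unlist(raw$sensitivity_covariates %||%
                                      c("sex", "apoe4_load", "education"))
  )
}

#' Read a participant table from CSV
#'
#' Reads a comma-delimited UTF-8 file with a header row, applies the config's
#' column-name map, validates mandatory columns and types, and returns a
#' tibble with canonical column names. Empty cells and `"NA"` are read as
#' missing. Numeric columns containing unparseable text are reported with row
#' numbers rather than silently coerced.
#'
#' @param path CSV file path.
#' @param config An [analysis_config()]; its `column_name_map` renames columns
#'   on the way in.
#' @return A tibble. An attribute `"row_problems"` (tibble of row, column,
#'   value) lists cells that failed numeric parsing and were set to `NA`.
#' @export
read_cohort <- function(path, config = analysis_config()) {
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                         na.strings = c("", "NA"), colClasses = "character",
                         fileEncoding = "UTF-8")
  map <- config$column_name_map
  if (!is.null(map)) {
    for (canonical in names(map)) {
      found <- map[[canonical]]
      if (found %in% names(raw)) names(raw)[names(raw) == found] <- canonical
    }
  }
  mandatory <- c("id", "age", "sex", "education")
  absent <- setdiff(mandatory, names(raw))
  if (length(absent)) {
    stop("mandatory column(s) missing from ", path, ": ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  character_cols <- c("id", "group", "sex", "A", "T", "N", "V")
  logical_cols <- c("css", "ischemic_lesion")
  problems <- list()
  for (col in names(raw)) {
    if (col %in% character_cols) next
    if (col %in% logical_cols) { raw[[col]] <- as.logical(raw[[col]]); next }
    parsed <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(!is.na(raw[[col]]) & is.na(parsed))
    if (length(bad)) {
      problems[[col]] <- tibble::tibble(row = bad, column = col,
                                        value = raw[[col]][bad])
    }
    raw[[col]] <- parsed
  }
  out <- tibble::as_tibble(raw)
  if ("age" %in% names(out) && any(!is.na(out$age) & out$age <= 0)) {
    stop("age must be positive for all rows", call. = FALSE)
  }
  if ("apoe4_load" %in% names(out)) {
    bad <- !is.na(out$apoe4_load) & !out$apoe4_load %in% 0:2
    if (any(bad)) stop("apoe4_load outside {0, 1, 2} in row(s): ",
                       paste(which(bad), collapse = ", "), call. = FALSE)
  }
  problems <- if (length(problems)) do.call(rbind, problems) else
    tibble::tibble(row = integer(), column = character(), value = character())
  if (nrow(problems)) {
    warning(sprintf("%d cell(s) failed numeric parsing and were set to NA (see attr 'row_problems')",
                    nrow(problems)), call. = FALSE)
  }
  attr(out, "row_problems") <- problems
  out
}

#' Write a participant table (or any pipeline result) to CSV
#'
#' UTF-8, comma-delimited, header row, missing values written as empty cells.
#' Numeric formatting uses full precision so a write/read round trip preserves
#' values exactly.
#'
#' @param table A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a JSON run manifest for reproducibility
#'
#' Records the analysis seed, a hash of the configuration, package and R
#' versions, and a timestamp alongside any result files.
#'
#' @param path Output path for the manifest JSON.
#' @param config The [analysis_config()] used.
#' @param seed The seed the run used.
#' @param extra Optional named list of additional fields.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(path, config, seed, extra = list()) {
  cfg_hash <- sum(utf8ToInt(paste(utils::capture.output(utils::str(unclass(config))),
                                  collapse = "\n")) * 31L %% .Machine$integer.max)
  manifest <- c(list(
    package = "cogagedelta",
    package_version = as.character(utils::packageVersion("cogagedelta")),
    r_version = as.character(getRversion()),
    seed = seed,
    config_hash = sprintf("%.0f", cfg_hash),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  ), extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
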