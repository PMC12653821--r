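#' Kruskal-Wallis comparison of a variable across clinical groups
#'
#' Rank-based H statistic with tie correction and a chi-square p-value on
#' k - 1 degrees of freedom, plus per-group medians and interquartile ranges.
#' The degenerate case where every observation is identical (ranks fully
#' tied) is reported as H = 0, p = 1.
#'
#' @param values Numeric vector of observations.
#' @param groups Group label for each observation.
#' @return A list of class `group_comparison`: `H`, `df`, `p`, and `summary`
#'   (tibble with group, n, median, q1, q3).
#' @export
kruskal_wallis <- function(values, groups) {
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]; groups <- as.character(groups[ok])
  k <- length(unique(groups))
  if (k < 2) stop("need at least 2 groups", call. = FALSE)
  summ <- do.call(rbind, lapply(split(values, groups), function(v) {
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    tibble::tibble(n = length(v), median = q[2], q1 = q[1], q3 = q[3])
  }))
  summ <- cbind(tibble::tibble(group = names(split(values, groups))), summ)
  if (stats::sd(values) == 0) {
    res <- list(H = 0, df = k - 1L, p = 1, summary = tibble::as_tibble(summ))
  } else {
    kt <- stats::kruskal.test(values, factor(groups))
    res <- list(H = unname(kt$statistic), df = unname(kt$parameter),
                p = kt$p.value, summary = tibble::as_tibble(summ))
  }
  structure(res, class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H(%d) = %.2f, p = %.3g\n", x$df, x$H, x$p))
  print(x$summary)
  invisible(x)
}

#' Association between the cognitive age delta and one factor
#'
#' Ordinary-least-squares general linear model of CAD (in years,
#' unstandardized) on the z-scored factor, optionally adding z-scored
#' covariates for the sensitivity analysis. The coefficient is therefore
#' interpreted as years of cognitive age per standard deviation of the
#' factor. Binary factors are 0/1-coded before standardization, like every
#' other input. Complete-case analysis within the supplied rows.
#'
#' @param data Data frame for one clinical group holding a `cad` column, the
#'   factor column and any covariate columns.
#' @param factor Name of the factor column.
#' @param covariates Character vector of covariate columns (empty for the
#'   univariate model).
#' @param cad_col Name of the outcome column (default `"cad"`).
#' @param conf_level Confidence level for the interval (default 0.95).
#' @return One-row tibble: `factor`, `model` (`"univariate"` or
#'   `"covariate_adjusted"`), `n`, `beta`, `se`, `ci_low`, `ci_high`, `t`,
#'   `p_raw`, `n_missing` (rows dropped as incomplete).
#' @export
fit_association <- function(data, factor, covariates = character(),
                            cad_col = "cad", conf_level = 0.95) {
  cols <- c(cad_col, factor, covariates)
  absent <- setdiff(cols, names(data))
  if (length(absent)) {
    stop("unknown column(s): ", paste(absent, collapse = ", "), call. = FALSE)
  }
  df <- data[, cols, drop = FALSE]
  df[[factor]] <- coerce_factor_numeric(df[[factor]], factor)
  for (cv in covariates) df[[cv]] <- coerce_factor_numeric(df[[cv]], cv)
  complete <- stats::complete.cases(df)
  n_missing <- sum(!complete)
  df <- df[complete, , drop = FALSE]
  n <- nrow(df)
  p_terms <- 1L + length(covariates)
  if (n < p_terms + 2L) {
    stop(sprintf("too few complete rows (%d) for %d predictor(s)", n, p_terms),
         call. = FALSE)
  }
  if (stats::sd(df[[factor]]) == 0) {
    stop("constant factor: ", factor, call. = FALSE)
  }
  y <- df[[cad_col]]
  Z <- cbind(zscore(df[[factor]]),
             if (length(covariates)) {
               sapply(covariates, function(cv) zscore(df[[cv]], allow_constant = TRUE))
             })
  colnames(Z) <- c(factor, covariates)
  fit <- stats::lm(y ~ Z)
  sm <- summary(fit)$coefficients
  # the factor of interest is always the first predictor after the intercept
  beta <- sm[2, "Estimate"]; se <- sm[2, "Std. Error"]
  tval <- sm[2, "t value"]; p <- sm[2, "Pr(>|t|)"]
  dfree <- fit$df.residual
  tq <- stats::qt(1 - (1 - conf_level) / 2, dfree)
  tibble::tibble(
    factor = factor,
    model = if (length(covariates)) "covariate_adjusted" else "univariate",
    n = n, beta = unname(beta), se = unname(se),
    ci_low = unname(beta - tq * se), ci_high = unname(beta + tq * se),
    t = unname(tval), p_raw = unname(p), n_missing = n_missing
  )
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjustment within one multiple-testing family (one factor group in
#' one clinical group). Monotone in the order statistics and capped at 1.
#'
#' @param p Numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values in input order; empty input yields empty output.
#' @export
fdr_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(!is.na(p) & (p < 0 | p > 1))) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Run the grouped association suite
#'
#' For every clinical group crossed with every factor group in the
#' configuration: fit the univariate model CAD ~ factor for each factor,
#' adjust the raw p-values by Benjamini-Hochberg within that block (factors
#' are deliberately analyzed in small thematic families so the correction is
#' not diluted across every factor ever measured), and re-test each
#' post-FDR-significant factor in a covariate-adjusted sensitivity model
#' (default covariates: sex, APOE e4 load, education years). Sensitivity
#' models inherit the univariate FDR decision and are reported with their raw
#' p-value.
#'
#' @param cad_records Tibble from [predict_cad()] (needs `id`, `cad`).
#' @param table Classified participant table with `id`, `group`, factor and
#'   covariate columns.
#' @param config An [analysis_config()] supplying `factor_groups`, `alpha`
#'   and `sensitivity_covariates`.
#' @param clinical_groups Clinical groups to analyze (defaults to the three
#'   analysis groups, restricted to those present).
#' @return Tibble with one row per clinical group x factor x model:
#'   `clinical_group`, `factor_group`, `factor`, `model`, `n`, `beta`, `se`,
#'   `ci_low`, `ci_high`, `t`, `p_raw`, `p_fdr` (`NA` for sensitivity
#'   models), `significant_fdr`. Unknown factor columns are skipped with a
#'   warning.
#' @export
run_association_suite <- function(cad_records, table, config = analysis_config(),
                                  clinical_groups = c("CUA-V-", "CUA+", "CUV+")) {
  merged <- merge(cad_records[, c("id", "cad")], table, by = "id")
  clinical_groups <- intersect(clinical_groups, unique(merged$group))
  out <- list()
  for (cg in clinical_groups) {
    rows <- merged[merged$group == cg, , drop = FALSE]
    for (fg in names(config$factor_groups)) {
      factors <- config$factor_groups[[fg]]
      unknown <- setdiff(factors, names(rows))
      if (length(unknown)) {
        warning(sprintf("skipping unknown factor column(s) in '%s': %s",
                        fg, paste(unknown, collapse = ", ")), call. = FALSE)
        factors <- setdiff(factors, unknown)
      }
      if (!length(factors)) next
      uni <- do.call(rbind, lapply(factors, function(f) {
        tryCatch(fit_association(rows, f, covariates = character()),
                 error = function(e) {
                   warning(sprintf("skipping factor '%s' in %s/%s: %s",
                                   f, cg, fg, conditionMessage(e)), call. = FALSE)
                   NULL
                 })
      }))
      if (is.null(uni) || !nrow(uni)) next
      uni$p_fdr <- fdr_adjust(uni$p_raw)
      uni$significant_fdr <- uni$p_fdr < config$alpha
      uni <- cbind(tibble::tibble(clinical_group = cg, factor_group = fg), uni)
      out[[length(out) + 1L]] <- uni
      for (f in uni$factor[uni$significant_fdr]) {
        covs <- setdiff(config$sensitivity_covariates, f)
        adj <- fit_association(rows, f, covariates = covs)
        adj$p_fdr <- NA_real_
        adj$significant_fdr <- TRUE  # inherited from the univariate decision
        adj <- cbind(tibble::tibble(clinical_group = cg, factor_group = fg), adj)
        out[[length(out) + 1L]] <- adj
      }
    }
  }
  if (!length(out)) {
    return(tibble::tibble(clinical_group = character(), factor_group = character(),
                          factor = character(), model = character(), n = integer(),
                          beta = numeric(), se = numeric(), ci_low = numeric(),
                          ci_high = numeric(), t = numeric(), p_raw = numeric(),
                          n_missing = integer(), p_fdr = numeric(),
                          significant_fdr = logical()))
  }
  tibble::as_tibble(do.call(rbind, out))
}
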