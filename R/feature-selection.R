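#' Correlate candidate features with chronological age
#'
#' Pearson correlation of each feature with age inside one clinical group
#' (by default the biomarker-negative reference group), on pairwise-complete
#' observations, with the two-sided p-value from the t-distributed transform
#' of r. Constant features, and features with fewer than three complete
#' pairs, are reported with `NA` and skipped by downstream selection.
#'
#' @param table Participant table with an `age` column and a `group` column.
#' @param feature_names Candidate feature columns.
#' @param group Clinical group to correlate within; `NULL` uses all rows.
#' @return A tibble with columns `name`, `n`, `r`, `p` in input order.
#' @export
correlate_with_age <- function(table, feature_names, group = "CUA-V-") {
  missing_cols <- setdiff(feature_names, names(table))
  if (length(missing_cols)) {
    stop("unknown feature column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  rows <- if (is.null(group)) table else table[table$group %in% group, , drop = FALSE]
  res <- lapply(feature_names, function(f) {
    ok <- !is.na(rows$age) & !is.na(rows[[f]])
    n <- sum(ok)
    if (n < 3 || stats::sd(rows[[f]][ok]) == 0) {
      return(tibble::tibble(name = f, n = n, r = NA_real_, p = NA_real_))
    }
    ct <- stats::cor.test(rows$age[ok], rows[[f]][ok], method = "pearson")
    tibble::tibble(name = f, n = n, r = unname(ct$estimate), p = ct$p.value)
  })
  do.call(rbind, res)
}

#' Pairwise feature correlation matrix
#'
#' Pearson correlations between features on pairwise-complete observations,
#' within one clinical group, used for collinearity pruning.
#'
#' @inheritParams correlate_with_age
#' @return A symmetric numeric matrix with feature names as dimnames.
#' @export
feature_rho_matrix <- function(table, feature_names, group = "CUA-V-") {
  rows <- if (is.null(group)) table else table[table$group %in% group, , drop = FALSE]
  stats::cor(as.matrix(rows[, feature_names, drop = FALSE]),
             use = "pairwise.complete.obs", method = "pearson")
}

#' Select age-sensitive, non-collinear features
#'
#' Two-stage screen: (1) keep candidates whose raw age-correlation p-value
#' passes Bonferroni correction, `p < alpha / m_tests`; (2) scan survivors in
#' descending |r| (ties broken by input order) and drop any candidate whose
#' |rho| with an already-kept feature exceeds `rho_max`.
#'
#' @param correlations Tibble from [correlate_with_age()].
#' @param rho_matrix Matrix from [feature_rho_matrix()] covering at least the
#'   Bonferroni survivors.
#' @param alpha Family-wise error rate before Bonferroni division.
#' @param rho_max Collinearity cap on |rho|.
#' @param m_tests Number of tests in the Bonferroni family; defaults to the
#'   number of candidates with a defined correlation.
#' @return An object of class `feature_selection` with elements `candidates`
#'   (the input tibble plus a `passed_bonferroni` flag), `bonferroni_alpha`,
#'   `selected` (ordered kept names), and `dropped_collinear` (tibble of
#'   kept/dropped/rho).
#' @export
select_features <- function(correlations, rho_matrix, alpha = 0.05,
                            rho_max = 0.7, m_tests = NULL) {
  if (nrow(correlations) == 0L) stop("empty candidate list", call. = FALSE)
  defined <- !is.na(correlations$r)
  m <- m_tests %||% sum(defined)
  if (m < sum(defined)) {
    stop("m_tests must be at least the number of candidates", call. = FALSE)
  }
  thr <- alpha / m
  passed <- defined & correlations$p < thr
  cand <- correlations[passed, , drop = FALSE]
  # greedy scan in descending |r|; order() is stable so ties keep input order
  cand <- cand[order(-abs(cand$r)), , drop = FALSE]
  kept <- character()
  dropped <- tibble::tibble(kept = character(), dropped = character(),
                            rho = numeric())
  for (i in seq_len(nrow(cand))) {
    f <- cand$name[i]
    if (length(kept)) {
      rho <- rho_matrix[f, kept]
      hit <- which(abs(rho) > rho_max)
      if (length(hit)) {
        dropped <- rbind(dropped, tibble::tibble(
          kept = kept[hit[1]], dropped = f, rho = unname(rho[hit[1]])))
        next
      }
    }
    kept <- c(kept, f)
  }
  correlations$passed_bonferroni <- passed
  structure(
    list(candidates = correlations, bonferroni_alpha = thr,
         selected = kept, dropped_collinear = dropped),
    class = "feature_selection"
  )
}

#' @export
print.feature_selection <- function(x, ...) {
  cat(sprintf("Feature selection: %d candidate(s), %d passed Bonferroni (p < %.3g), %d selected\n",
              nrow(x$candidates), sum(x$candidates$passed_bonferroni),
              x$bonferroni_alpha, length(x$selected)))
  if (nrow(x$dropped_collinear)) {
    for (i in seq_len(nrow(x$dropped_collinear))) {
      cat(sprintf("  dropped '%s' (|rho| = %.2f with kept '%s')\n",
                  x$dropped_collinear$dropped[i],
                  abs(x$dropped_collinear$rho[i]), x$dropped_collinear$kept[i]))
    }
  }
  invisible(x)
}

#' Run the full feature screen on a classified cohort
#'
#' @param table Classified participant table.
#' @param feature_names Candidate features (default: the 12-test battery).
#' @param group Reference group for screening.
#' @param config An [analysis_config()] supplying `alpha` and `rho_max`.
#' @return A `feature_selection` object.
#' @export
screen_features <- function(table, feature_names = default_feature_set(),
                            group = "CUA-V-", config = analysis_config()) {
  corr <- correlate_with_age(table, feature_names, group = group)
  rho <- feature_rho_matrix(table, feature_names, group = group)
  select_features(corr, rho, alpha = config$alpha, rho_max = config$rho_max)
}
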