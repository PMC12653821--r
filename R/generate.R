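# Synthetic cohort generation.
#
# Biomarkers are drawn on the correct side of each classification cutoff by
# reflecting Gaussian draws about the cutoff, so every generated row
# classifies back into the group it was generated for (strict inequalities
# hold almost surely for continuous draws).

draw_side <- function(n, mean, sd, cutoff, side = c("below", "above")) {
  side <- match.arg(side)
  x <- stats::rnorm(n, mean, sd)
  if (side == "below") ifelse(x < cutoff, x, 2 * cutoff - x)
  else ifelse(x > cutoff, x, 2 * cutoff - x)
}

theoretical_z <- function(x, distribution, params) {
  switch(distribution,
    normal = (x - params$mean) / params$sd,
    bernoulli = (x - params$prob) / sqrt(params$prob * (1 - params$prob)),
    uniform = (x - (params$min + params$max) / 2) / ((params$max - params$min) / sqrt(12)),
    stop("unknown covariate distribution: ", distribution, call. = FALSE)
  )
}

draw_covariate <- function(n, distribution, params) {
  switch(distribution,
    normal = stats::rnorm(n, params$mean, params$sd),
    bernoulli = stats::rbinom(n, 1L, params$prob),
    uniform = stats::runif(n, params$min, params$max),
    stop("unknown covariate distribution: ", distribution, call. = FALSE)
  )
}

# CSF and MRI values consistent with one group label under the default-style
# cutoffs passed in. ATN positivity is strict (<, >); vascular uses >=.
draw_biomarkers <- function(n, group, noise, cutoffs) {
  ab_sd <- noise[["abeta42"]]; pt_sd <- noise[["ptau"]]; tt_sd <- noise[["ttau"]]
  a_neg <- function(n) draw_side(n, 850, ab_sd, cutoffs$abeta_pos_below, "above")
  a_pos <- function(n) draw_side(n, 460, ab_sd, cutoffs$abeta_pos_below, "below")
  t_neg <- function(n) draw_side(n, 45, pt_sd, cutoffs$ptau_pos_above, "below")
  t_pos <- function(n) draw_side(n, 78, pt_sd, cutoffs$ptau_pos_above, "above")
  n_neg <- function(n) draw_side(n, 250, tt_sd, cutoffs$ttau_pos_above, "below")
  n_pos <- function(n) draw_side(n, 430, tt_sd, cutoffs$ttau_pos_above, "above")
  faz_vneg <- function(n) sample(0:1, n, replace = TRUE, prob = c(0.7, 0.3))
  cmb_vneg <- function(n) sample(0:3, n, replace = TRUE, prob = c(0.85, 0.09, 0.04, 0.02))

  if (group == "CUA-V-") {
    tibble::tibble(abeta42 = a_neg(n), ptau = t_neg(n), ttau = n_neg(n),
                   fazekas = faz_vneg(n), cmb_count = cmb_vneg(n))
  } else if (group == "CUA+") {
    # amyloid-positive irrespective of tau status; enrich some T+/N+
    tpos <- stats::runif(n) < 0.30
    npos <- stats::runif(n) < 0.20
    tibble::tibble(
      abeta42 = a_pos(n),
      ptau = ifelse(tpos, t_pos(n), t_neg(n)),
      ttau = ifelse(npos, n_pos(n), n_neg(n)),
      fazekas = faz_vneg(n), cmb_count = cmb_vneg(n)
    )
  } else if (group == "CUV+") {
    mech <- sample(c("wmh", "cmb", "both"), n, replace = TRUE, prob = c(0.6, 0.25, 0.15))
    faz <- ifelse(mech == "cmb", faz_vneg(n),
                  sample(2:3, n, replace = TRUE, prob = c(0.8, 0.2)))
    cmb <- ifelse(mech == "wmh", cmb_vneg(n),
                  sample(4:8, n, replace = TRUE, prob = c(0.45, 0.25, 0.15, 0.1, 0.05)))
    tibble::tibble(abeta42 = a_neg(n), ptau = t_neg(n), ttau = n_neg(n),
                   fazekas = faz, cmb_count = cmb)
  } else {
    stop("unknown group label: ", group, call. = FALSE)
  }
}

#' Generate a synthetic participant table
#'
#' Draws one row per participant with demographics, CSF and MRI biomarker
#' values consistent with the requested analysis-group label, neuropsychological
#' test scores that are affine in age and education plus Gaussian noise, and
#' covariates with optional planted effects on cognitive age (see
#' [covariate_def()]).
#'
#' Ages are uniform on the spec's age range; groups listed in
#' `group_age_shift` have their lower age bound raised by twice the shift, so
#' their mean age exceeds the reference group's by the stated number of years.
#' APOE e4 load is multinomial with carrier enrichment in the amyloid-positive
#' group.
#'
#' @param spec A [cohort_spec()] object.
#' @return A tibble with one row per participant: `id`, `group` (the label the
#'   row was generated to satisfy), demographics, biomarkers, one column per
#'   feature, and one column per covariate. Running [assign_group()] on the
#'   biomarker columns reproduces `group` for every row.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_spec(seed = 42))
#' nrow(cohort)  # 177
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  cutoffs <- biomarker_cutoffs()
  set.seed(spec$seed)
  groups <- names(spec$n_per_group)
  blocks <- lapply(groups, function(g) {
    n <- spec$n_per_group[[g]]
    if (n == 0L) return(NULL)
    shift <- if (g %in% names(spec$group_age_shift)) spec$group_age_shift[[g]] else 0
    lo <- min(spec$age_range[1] + 2 * shift, spec$age_range[2] - 1)
    age <- stats::runif(n, lo, spec$age_range[2])
    education <- sample(spec$education_levels, n, replace = TRUE,
                        prob = spec$education_probs)
    sex <- ifelse(stats::runif(n) < spec$female_prob, "female", "male")
    apoe_probs <- if (g == "CUA+") c(0.45, 0.45, 0.10) else c(0.70, 0.27, 0.03)
    apoe4_load <- sample(0:2, n, replace = TRUE, prob = apoe_probs)
    bio <- draw_biomarkers(n, g, spec$biomarker_noise, cutoffs)

    base <- tibble::tibble(
      id = NA_character_, group = g, age = age, sex = sex,
      education = as.numeric(education), apoe4_load = apoe4_load,
      css = FALSE, ischemic_lesion = FALSE
    )
    base <- cbind(base, bio)

    # covariates, and the coherent cognitive-age displacement they plant
    cad_shift <- numeric(n)
    if (!is.null(spec$covariate_defs) && nrow(spec$covariate_defs) > 0L) {
      for (i in seq_len(nrow(spec$covariate_defs))) {
        cv <- spec$covariate_defs[i, ]
        vals <- draw_covariate(n, cv$distribution, cv$params[[1]])
        base[[cv$name]] <- vals
        affected <- cv$groups_affected[[1]]
        if (cv$planted_cad_effect != 0 && (is.null(affected) || g %in% affected)) {
          cad_shift <- cad_shift +
            cv$planted_cad_effect * theoretical_z(vals, cv$distribution, cv$params[[1]])
        }
      }
    }

    fd <- spec$feature_defs
    for (i in seq_len(nrow(fd))) {
      base[[fd$name[i]]] <- fd$intercept[i] +
        fd$age_slope[i] * (age + cad_shift) +
        fd$education_slope[i] * base$education +
        stats::rnorm(n, 0, fd$noise_sd[i])
    }
    base
  })
  out <- tibble::as_tibble(do.call(rbind, blocks))
  out$id <- sprintf("P%04d", seq_len(nrow(out)))
  out
}

#' Remove feature values completely at random
#'
#' Marks exactly `n_missing` rows as incomplete by setting one randomly chosen
#' feature among `feature_names` to `NA` in each, emulating participants
#' excluded from cognitive-age computation for missing test scores.
#'
#' @param table A participant table.
#' @param feature_names Features eligible for blanking.
#' @param n_missing Number of rows to make incomplete (0 <= n_missing <= rows).
#' @param seed RNG seed for row/feature choice.
#' @return The table with `NA`s injected.
#' @export
inject_missingness <- function(table, feature_names, n_missing, seed = 1L) {
  if (n_missing < 0) stop("n_missing must be non-negative", call. = FALSE)
  if (n_missing > nrow(table)) {
    stop("n_missing exceeds the number of rows", call. = FALSE)
  }
  missing_cols <- setdiff(feature_names, names(table))
  if (length(missing_cols)) {
    stop("unknown feature column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (n_missing == 0) return(table)
  set.seed(seed)
  rows <- sample.int(nrow(table), n_missing)
  cols <- sample(feature_names, n_missing, replace = TRUE)
  for (k in seq_along(rows)) table[[cols[k]]][rows[k]] <- NA_real_
  table
}
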