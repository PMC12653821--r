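#' Define a neuropsychological feature for the synthetic cohort generator
#'
#' Each synthetic test score is an affine function of chronological age and
#' education years plus Gaussian noise:
#' `score = intercept + age_slope * age + education_slope * education + N(0, noise_sd)`.
#'
#' @param name Test identifier (matches the column name in the generated table).
#' @param age_slope Score units per year of age. Negative for tests where
#'   performance declines with age (most scores), positive for timed tests
#'   where completion time grows (TMT-A, TMT-B).
#' @param education_slope Score units per year of education.
#' @param intercept Score units at age 0 / education 0 (an extrapolation; only
#'   the affine form matters).
#' @param noise_sd Residual standard deviation in score units; must be >= 0.
#' @return A one-row tibble describing the feature.
#' @export
feature_def <- function(name, age_slope, education_slope, intercept, noise_sd) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.finite(noise_sd) || noise_sd < 0) {
    stop("noise_sd must be a finite non-negative number", call. = FALSE)
  }
  tibble::tibble(
    name = name, age_slope = as.numeric(age_slope),
    education_slope = as.numeric(education_slope),
    intercept = as.numeric(intercept), noise_sd = as.numeric(noise_sd)
  )
}

#' Define a covariate with an optional planted effect on cognitive age
#'
#' Covariates are drawn independently of age. A non-zero `planted_cad_effect`
#' displaces every feature score of affected participants by
#' `age_slope * planted_cad_effect * z(covariate)` — i.e. the participant's
#' whole test profile moves as if they were `planted_cad_effect * z` years
#' older — so that a downstream association model should recover
#' `planted_cad_effect` as the standardized coefficient of the covariate on
#' the cognitive age delta. `z(covariate)` uses the theoretical mean/SD of the
#' sampling distribution, keeping the planted effect independent of the
#' realized sample.
#'
#' @param name Covariate/column name.
#' @param distribution One of `"normal"`, `"bernoulli"`, `"uniform"`.
#' @param params Named numeric vector: `c(mean=, sd=)` for normal,
#'   `c(prob=)` for bernoulli, `c(min=, max=)` for uniform.
#' @param planted_cad_effect Years of cognitive-age displacement per SD of the
#'   covariate (default 0: a null covariate).
#' @param groups_affected Character vector of group labels the effect applies
#'   to; `NULL` means every group.
#' @return A one-row tibble describing the covariate.
#' @export
covariate_def <- function(name, distribution = c("normal", "bernoulli", "uniform"),
                          params, planted_cad_effect = 0, groups_affected = NULL) {
  distribution <- match.arg(distribution)
  if (!is.finite(planted_cad_effect)) {
    stop("planted_cad_effect must be finite", call. = FALSE)
  }
  params <- as.list(params)
  switch(distribution,
    normal = stopifnot(all(c("mean", "sd") %in% names(params)), params$sd > 0),
    bernoulli = {
      stopifnot("prob" %in% names(params))
      if (params$prob < 0 || params$prob > 1) {
        stop("bernoulli prob must lie in [0, 1]", call. = FALSE)
      }
    },
    uniform = stopifnot(all(c("min", "max") %in% names(params)),
                        params$min < params$max)
  )
  tibble::tibble(
    name = name, distribution = distribution, params = list(params),
    planted_cad_effect = as.numeric(planted_cad_effect),
    groups_affected = list(groups_affected)
  )
}

#' Default battery of twelve age-sensitive neuropsychological features
#'
#' Slopes and intercepts give each test a realistic direction (timed trail
#' making tests worsen, i.e. increase, with age; all other scores decline).
#' Noise levels are calibrated so each score's marginal age correlation sits
#' near |r| = 0.68-0.73 in a 40-80 year cohort: strong enough that the whole
#' battery survives Bonferroni age-correlation screening at reference-group
#' sample sizes, while the age signal shared between any two tests stays
#' below the 0.7 collinearity cap with margin for sampling variability.
#'
#' @return A tibble with one row per feature.
#' @export
default_feature_defs <- function() {
  defs <- list(
    feature_def("Digit Symbol-Coding",                 -0.90,  0.60, 110, 10.2),
    feature_def("Stroop Color Naming",                 -0.45,  0.25,  95,  5.8),
    feature_def("Stroop Word-Color Interference",      -0.40,  0.25,  62,  4.5),
    feature_def("15-Objects Test",                     -0.25,  0.10,  55,  3.2),
    feature_def("ROCF Delayed Recall",                 -0.22,  0.18,  28,  2.5),
    feature_def("TMT-A",                                0.80, -0.40,  10, 10.4),
    feature_def("FCSRT Immediate Total Free Recall",   -0.28,  0.15,  45,  3.2),
    feature_def("TMT-B",                                2.20, -1.00,  30, 28.6),
    feature_def("Boston Naming Test",                  -0.20,  0.20,  60,  2.3),
    feature_def("Phonemic Fluency P",                  -0.25,  0.30,  28,  3.2),
    feature_def("FCSRT Immediate Total Recall",        -0.25,  0.13,  52,  2.8),
    feature_def("Semantic Fluency Animals",            -0.30,  0.20,  38,  3.9)
  )
  do.call(rbind, defs)
}

#' Default covariate set (all null effects)
#'
#' Vocabulary and a cognitive-reserve questionnaire proxy lifelong enrichment,
#' daily sitting hours proxies sedentarism, and active smoking is a binary
#' lifestyle factor. All planted effects default to zero; tests and
#' simulations override them to plant recoverable effects.
#'
#' @return A tibble with one row per covariate.
#' @export
default_covariate_defs <- function() {
  rbind(
    covariate_def("vocabulary", "normal", c(mean = 45, sd = 8)),
    covariate_def("cognitive_reserve_questionnaire", "normal", c(mean = 14, sd = 4)),
    covariate_def("daily_sitting_hours", "normal", c(mean = 6, sd = 1.8)),
    covariate_def("active_smoker", "bernoulli", c(prob = 0.2))
  )
}

#' Specification of a synthetic cohort
#'
#' Collects every generator parameter: group sizes, age structure, the
#' feature battery, the education distribution, covariates with planted
#' effects, biomarker noise, and the random seed. With a fixed seed the
#' generated table is byte-identical across runs.
#'
#' @param n_per_group Named integer vector of participants per analysis group.
#'   Defaults mirror a reference cohort of 140 biomarker-negative (CUA-V-),
#'   23 amyloid-positive (CUA+) and 14 vascular-positive (CUV+) participants.
#' @param age_range Two-element numeric `(min, max)` in years; ages are drawn
#'   uniformly within it per group.
#' @param group_age_shift Named numeric vector of per-group mean age shifts in
#'   years, implemented by raising the group's lower age bound by twice the
#'   shift. Defaults make the pathology groups about five years older than the
#'   reference group, reproducing a common confound between pathology status
#'   and age.
#' @param feature_defs Tibble from [feature_def()] rows.
#' @param education_levels,education_probs Discrete education distribution in
#'   completed years; default spans 8-20 years peaking at 12-16.
#' @param covariate_defs Tibble from [covariate_def()] rows.
#' @param biomarker_noise Named SDs (pg/mL) for the three CSF markers.
#' @param female_prob Probability a participant is female.
#' @param seed Integer RNG seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = c("CUA-V-" = 140, "CUA+" = 23, "CUV+" = 14),
                        age_range = c(40, 80),
                        group_age_shift = c("CUA+" = 5, "CUV+" = 5),
                        feature_defs = default_feature_defs(),
                        education_levels = 8:20,
                        education_probs = NULL,
                        covariate_defs = default_covariate_defs(),
                        biomarker_noise = c(abeta42 = 120, ptau = 10, ttau = 60),
                        female_prob = 0.55,
                        seed = 1L) {
  if (is.null(names(n_per_group)) || any(!nzchar(names(n_per_group)))) {
    stop("n_per_group must be a named vector of group sizes", call. = FALSE)
  }
  known <- c("CUA-V-", "CUA+", "CUV+")
  unknown <- setdiff(names(n_per_group), known)
  if (length(unknown)) {
    stop("unknown group label(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (any(n_per_group < 0)) stop("group counts must be >= 0", call. = FALSE)
  if (length(age_range) != 2L || age_range[1] >= age_range[2]) {
    stop("age_range must be (min, max) with min < max", call. = FALSE)
  }
  if (is.null(feature_defs) || nrow(feature_defs) == 0L) {
    stop("feature_defs must contain at least one feature", call. = FALSE)
  }
  if (anyDuplicated(feature_defs$name)) {
    stop("duplicate feature names in feature_defs", call. = FALSE)
  }
  if (is.null(education_probs)) {
    # mildly peaked around 12-16 completed years
    w <- stats::dnorm(education_levels, mean = 14, sd = 3.2)
    education_probs <- w / sum(w)
  }
  stopifnot(length(education_probs) == length(education_levels),
            abs(sum(education_probs) - 1) < 1e-8)
  structure(
    list(
      n_per_group = n_per_group, age_range = as.numeric(age_range),
      group_age_shift = group_age_shift, feature_defs = feature_defs,
      education_levels = as.integer(education_levels),
      education_probs = as.numeric(education_probs),
      covariate_defs = covariate_defs,
      biomarker_noise = biomarker_noise,
      female_prob = female_prob, seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Synthetic cohort specification\n")
  cat("  groups: ", paste(sprintf("%s (n=%d)", names(x$n_per_group), x$n_per_group),
                          collapse = ", "), "\n", sep = "")
  cat(sprintf("  ages: uniform %g-%g years; %d features; %d covariates; seed %d\n",
              x$age_range[1], x$age_range[2], nrow(x$feature_defs),
              if (is.null(x$covariate_defs)) 0L else nrow(x$covariate_defs), x$seed))
  invisible(x)
}

#' Read or write a cohort specification as JSON or YAML
#'
#' Only generator parameters are serialized; the spec round-trips through
#' [cohort_spec()] so invariants are re-checked on read.
#'
#' @param spec A `cohort_spec` object.
#' @param path File path ending in `.json`, `.yaml` or `.yml`.
#' @return `write_cohort_spec()` returns `path` invisibly;
#'   `read_cohort_spec()` returns a `cohort_spec`.
#' @export
write_cohort_spec <- function(spec, path) {
  stopifnot(inherits(spec, "cohort_spec"))
  cov <- spec$covariate_defs
  fd <- spec$feature_defs
  payload <- list(
    n_per_group = as.list(spec$n_per_group),
    age_range = spec$age_range,
    group_age_shift = as.list(spec$group_age_shift),
    feature_defs = lapply(seq_len(nrow(fd)), function(i) {
      list(name = fd$name[i], age_slope = fd$age_slope[i],
           education_slope = fd$education_slope[i],
           intercept = fd$intercept[i], noise_sd = fd$noise_sd[i])
    }),
    education_levels = spec$education_levels,
    education_probs = spec$education_probs,
    covariate_defs = if (is.null(cov)) NULL else lapply(seq_len(nrow(cov)), function(i) {
      list(name = cov$name[i], distribution = cov$distribution[i],
           params = cov$params[[i]],
           planted_cad_effect = cov$planted_cad_effect[i],
           groups_affected = cov$groups_affected[[i]])
    }),
    biomarker_noise = as.list(spec$biomarker_noise),
    female_prob = spec$female_prob,
    seed = spec$seed
  )
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(payload, path, precision = 15L)
  } else {
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}

#' @rdname write_cohort_spec
#' @export
read_cohort_spec <- function(path) {
  if (!file.exists(path)) stop("spec file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path) else jsonlite::read_json(path)
  fd <- do.call(rbind, lapply(raw$feature_defs, function(f) {
    feature_def(f$name, f$age_slope, f$education_slope, f$intercept, f$noise_sd)
  }))
  cd <- if (length(raw$covariate_defs)) {
    do.call(rbind, lapply(raw$covariate_defs, function(cv) {
      covariate_def(cv$name, cv$distribution, unlist(cv$params),
                    cv$planted_cad_effect %||% 0,
                    if (length(cv$groups_affected)) unlist(cv$groups_affected) else NULL)
    }))
  } else NULL
  probs <- unlist(raw$education_probs)
  cohort_spec(
    n_per_group = unlist(raw$n_per_group),
    age_range = unlist(raw$age_range),
    group_age_shift = unlist(raw$group_age_shift),
    feature_defs = fd,
    education_levels = unlist(raw$education_levels),
    education_probs = probs / sum(probs),  # guard against formatting round-off
    covariate_defs = cd,
    biomarker_noise = unlist(raw$biomarker_noise),
    female_prob = raw$female_prob,
    seed = raw$seed
  )
}
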