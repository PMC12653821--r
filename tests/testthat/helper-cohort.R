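# Shared fixtures: all synthetic, built in code.

# Cohort spec with a planted cognitive-age effect on one covariate.
plant_spec <- function(seed, effect, covariate = "vocabulary",
                       groups_affected = "CUA-V-", n_per_group = NULL) {
  cds <- default_covariate_defs()
  i <- which(cds$name == covariate)
  cds$planted_cad_effect[i] <- effect
  cds$groups_affected[[i]] <- groups_affected
  if (is.null(n_per_group)) cohort_spec(covariate_defs = cds, seed = seed)
  else cohort_spec(n_per_group = n_per_group, covariate_defs = cds, seed = seed)
}

# Tiny deterministic cohort for unit tests: 3 features affine in age/education
# plus optional noise, one group label.
tiny_table <- function(n = 30, seed = 1, noise_sd = 0, group = "CUA-V-") {
  set.seed(seed)
  age <- runif(n, 40, 80)
  education <- sample(8:20, n, replace = TRUE)
  tibble::tibble(
    id = sprintf("T%03d", seq_len(n)), group = group,
    age = age, education = as.numeric(education),
    sex = sample(c("female", "male"), n, replace = TRUE),
    apoe4_load = sample(0:2, n, replace = TRUE, prob = c(.7, .27, .03)),
    f1 = 100 - 0.8 * age + 0.5 * education + rnorm(n, 0, noise_sd),
    f2 = 20 + 0.6 * age - 0.3 * education + rnorm(n, 0, noise_sd),
    f3 = 50 - 0.4 * age + 0.2 * education + rnorm(n, 0, noise_sd)
  )
}

# Closed-form OLS via the normal equations; the independent oracle for every
# regression in the package.
normal_eq <- function(X, y) {
  Xi <- cbind(1, X)
  unname(drop(solve(t(Xi) %*% Xi, t(Xi) %*% y)))
}
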