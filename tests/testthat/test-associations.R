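test_that("Kruskal-Wallis matches the brute-force rank-sum formula", {
  values <- c(1, 2, 3, 4, 5, 6, 7, 8, 9)
  groups <- rep(c("a", "b", "c"), each = 3)
  res <- kruskal_wallis(values, groups)
  # oracle: H = 12 / (N (N + 1)) * sum n_i * Rbar_i^2 - 3 (N + 1), no ties
  rk <- rank(values)
  rbar <- tapply(rk, groups, mean)
  n_i <- tapply(rk, groups, length)
  H_hand <- 12 / (9 * 10) * sum(n_i * rbar^2) - 3 * 10
  expect_equal(res$H, H_hand, tolerance = 1e-12)
  expect_equal(res$df, 2L)
  expect_equal(res$p, stats::pchisq(H_hand, 2, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(res$summary$median, c(2, 5, 8))
})

test_that("Kruskal-Wallis is invariant to group relabeling and handles ties", {
  set.seed(2)
  values <- c(rnorm(10), rnorm(12, 1), rnorm(8, 2))
  groups <- rep(c("x", "y", "z"), c(10, 12, 8))
  res1 <- kruskal_wallis(values, groups)
  relabeled <- c(x = "z", y = "x", z = "y")[groups]
  res2 <- kruskal_wallis(values, relabeled)
  expect_equal(res1$H, res2$H, tolerance = 1e-12)
  # fully tied data is the degenerate H = 0, p = 1 case
  flat <- kruskal_wallis(rep(4, 9), rep(c("a", "b", "c"), 3))
  expect_equal(flat$H, 0)
  expect_equal(flat$p, 1)
  expect_error(kruskal_wallis(1:5, rep("a", 5)), "at least 2 groups")
})

test_that("an exact linear relation is recovered with zero residual", {
  set.seed(5)
  voc <- rnorm(50, 45, 8)
  dat <- tibble::tibble(cad = 3 * as.vector(scale(voc)), vocabulary = voc)
  # lm warns about the perfect fit; the zero-residual case is the point here
  res <- suppressWarnings(fit_association(dat, "vocabulary"))
  expect_equal(res$beta, 3, tolerance = 1e-10)
  expect_lt(res$se, 1e-10)
  expect_equal(res$model, "univariate")
})

test_that("association beta, t and p equal the closed-form OLS computation", {
  set.seed(21)
  for (rep in 1:10) {
    n <- 25 + rep
    dat <- tibble::tibble(cad = rnorm(n, 0, 3), factor_x = rnorm(n, 10, 2),
                          sex = rbinom(n, 1, 0.5), education = rnorm(n, 13, 3))
    covs <- if (rep %% 2 == 0) c("sex", "education") else character()
    res <- fit_association(dat, "factor_x", covariates = covs)
    Z <- cbind(scale(dat$factor_x),
               if (length(covs)) sapply(covs, function(cv) scale(dat[[cv]])))
    hand <- normal_eq(Z, dat$cad)
    Xi <- cbind(1, Z)
    resid <- dat$cad - Xi %*% hand
    dfree <- n - ncol(Xi)
    sigma2 <- sum(resid^2) / dfree
    se_hand <- sqrt(diag(solve(t(Xi) %*% Xi)) * sigma2)[2]
    t_hand <- hand[2] / se_hand
    p_hand <- 2 * stats::pt(-abs(t_hand), dfree)
    expect_equal(res$beta, hand[2], tolerance = 1e-10)
    expect_equal(res$se, unname(se_hand), tolerance = 1e-10)
    expect_equal(res$t, unname(t_hand), tolerance = 1e-10)
    expect_equal(res$p_raw, unname(p_hand), tolerance = 1e-10)
  }
})

test_that("beta, CI and p are invariant to positive rescaling of the factor", {
  set.seed(9)
  dat <- tibble::tibble(cad = rnorm(40), hours = runif(40, 2, 12))
  res1 <- fit_association(dat, "hours")
  dat$hours <- dat$hours * 60  # minutes instead of hours
  res2 <- fit_association(dat, "hours")
  expect_equal(res1$beta, res2$beta, tolerance = 1e-12)
  expect_equal(res1$ci_low, res2$ci_low, tolerance = 1e-12)
  expect_equal(res1$p_raw, res2$p_raw, tolerance = 1e-12)
})

test_that("binary and categorical factors are 0/1-coded then standardized", {
  set.seed(13)
  smoker <- rbinom(60, 1, 0.4)
  dat <- tibble::tibble(cad = 2 * as.vector(scale(smoker)) + rnorm(60, 0, 0.1),
                        smoker_num = smoker,
                        smoker_chr = ifelse(smoker == 1, "yes", "no"))
  res_num <- fit_association(dat, "smoker_num")
  res_chr <- fit_association(dat, "smoker_chr")
  expect_equal(res_chr$beta, res_num$beta, tolerance = 1e-12)
  expect_error(
    fit_association(tibble::tibble(cad = rnorm(9), f = letters[1:9]), "f"),
    "levels")
})

test_that("degenerate association inputs error clearly", {
  dat <- tibble::tibble(cad = rnorm(10), flat = 1,
                        f = rnorm(10), c1 = rnorm(10), c2 = rnorm(10))
  expect_error(fit_association(dat, "flat"), "constant factor")
  expect_error(fit_association(dat[1:4, ], "f", covariates = c("c1", "c2")),
               "too few")
  expect_error(fit_association(dat, "nope"), "unknown column")
})

test_that("Benjamini-Hochberg adjustment matches the hand computation", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04),
               tolerance = 1e-12)
  expect_equal(fdr_adjust(0.2), 0.2)
  expect_equal(fdr_adjust(rep(0.2, 4)), rep(0.2, 4))
  expect_identical(fdr_adjust(numeric(0)), numeric(0))
  expect_error(fdr_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  # oracle on random vectors: sorted p * m / rank, cumulative min from largest
  set.seed(31)
  for (rep in 1:25) {
    p <- runif(sample(1:12, 1))
    adj <- fdr_adjust(p)
    o <- order(p)
    m <- length(p)
    hand <- pmin(1, rev(cummin(rev(sort(p) * m / seq_len(m)))))[order(o)]
    expect_equal(adj, hand, tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-15) && all(adj <= 1))
  }
})

test_that("the suite shares one BH family per factor group and clinical group", {
  set.seed(17)
  n <- 80
  tab <- tibble::tibble(
    id = sprintf("s%02d", 1:n), group = "CUA-V-",
    sex = rbinom(n, 1, 0.5), apoe4_load = rbinom(n, 2, 0.2),
    education = rnorm(n, 13, 3),
    fa = rnorm(n), fb = rnorm(n), fc = rnorm(n)
  )
  cad <- tibble::tibble(id = tab$id, cad = -1.2 * as.vector(scale(tab$fa)) + rnorm(n, 0, 1))
  cfg <- analysis_config(factor_groups = list(block = c("fa", "fb", "fc")))
  res <- run_association_suite(cad, tab, cfg)
  uni <- res[res$model == "univariate", ]
  expect_equal(nrow(uni), 3L)
  expect_equal(uni$p_fdr, fdr_adjust(uni$p_raw), tolerance = 1e-12)
  # the planted factor triggers a covariate-adjusted sensitivity model
  expect_true("fa" %in% res$factor[res$model == "covariate_adjusted"])
  expect_false(any(c("fb", "fc") %in% res$factor[res$model == "covariate_adjusted"]))
  adj <- res[res$model == "covariate_adjusted" & res$factor == "fa", ]
  expect_true(is.na(adj$p_fdr))
})

test_that("no sensitivity models are fitted when nothing survives FDR", {
  set.seed(23)
  n <- 60
  tab <- tibble::tibble(id = sprintf("s%02d", 1:n), group = "CUA-V-",
                        sex = rbinom(n, 1, 0.5), apoe4_load = rbinom(n, 2, 0.2),
                        education = rnorm(n, 13, 3),
                        f1 = rnorm(n), f2 = rnorm(n))
  cad <- tibble::tibble(id = tab$id, cad = rnorm(n, 0, 3))
  cfg <- analysis_config(factor_groups = list(noise = c("f1", "f2")))
  res <- run_association_suite(cad, tab, cfg)
  if (!any(res$significant_fdr[res$model == "univariate"])) {
    expect_false(any(res$model == "covariate_adjusted"))
  }
  expect_warning(
    run_association_suite(cad, tab,
                          analysis_config(factor_groups = list(x = "ghost"))),
    "unknown factor")
})

test_that("CSF markers run through the same association path with covariates", {
  cohort <- classify_cohort(generate_cohort(cohort_spec(seed = 14)))
  res <- suppressWarnings(run_cad_pipeline(cohort))
  rows <- merge(res$cad[, c("id", "cad")], res$cohort, by = "id")
  rows <- rows[rows$group == "CUA-V-", ]
  csf <- fit_association(rows, "abeta42",
                         covariates = c("sex", "apoe4_load", "education"))
  expect_equal(csf$model, "covariate_adjusted")
  expect_true(is.finite(csf$beta) && csf$p_raw >= 0 && csf$p_raw <= 1)
})
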