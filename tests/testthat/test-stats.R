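# Regression machinery: OLS, correlation matrix, proportional-odds grade
# model, mixed-effects models and their algebraic identities.

no_excl <- function(...) cohort_spec(..., exclusion_probs = c(damage = 0,
                                                              orientation = 0))

test_that("univariate OLS recovers an exact linear relationship", {
  x <- seq(1, 20, by = 0.5)
  r <- suppressWarnings(univariate_ols(2 * x, x, term = "x"))  # exact fit
  slope <- r$coefficients[r$coefficients$term == "x", ]
  expect_equal(slope$estimate, 2, tolerance = 1e-12)
  expect_lt(slope$p_value, 1e-12)
})

test_that("null OLS p-values are uniform across replicates", {
  set.seed(19)
  pvals <- replicate(300, {
    x <- rnorm(100); y <- rnorm(100)
    r <- univariate_ols(y, x, term = "x")
    r$coefficients$p_value[2]
  })
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
  slope_mean <- mean(replicate(50, {
    x <- rnorm(200); coef(lm(rnorm(200) ~ x))[2]
  }))
  expect_lt(abs(slope_mean), 0.05)
})

test_that("correlation matrix has unit diagonal and sign antisymmetry", {
  set.seed(2)
  d <- data.frame(a = rnorm(200), b = rnorm(200))
  d$c <- d$a + rnorm(200)
  cm <- correlation_matrix(d, c("a", "b", "c"))
  expect_equal(diag(cm$r), c(a = 1, b = 1, c = 1))
  d2 <- d; d2$c <- -d2$c
  cm2 <- correlation_matrix(d2, c("a", "b", "c"))
  expect_equal(cm2$r["a", "c"], -cm$r["a", "c"], tolerance = 1e-12)
  expect_equal(cm2$p["a", "c"], cm$p["a", "c"], tolerance = 1e-12)
})

test_that("cohort correlation of CEP T2* with NP T1rho emerges near 0.259", {
  coh <- generate_cohort(cohort_spec(n_subjects = 10000, seed = 13))
  r <- cor(coh$cep_t2star_ms, coh$np_t1rho_ms)
  # emergent (not directly targeted): generated by the linear model plus
  # the covariate copula; should land in the neighbourhood of the study r
  expect_gt(r, 0.2)
  expect_lt(r, 0.4)
})

test_that("proportional-odds model detects the negative grade association", {
  coh <- generate_cohort(no_excl(n_subjects = 60, seed = 17))
  fit <- pfirrmann_model(coh$pfirrmann, coh$np_t1rho_ms)
  expect_lt(fit$coefficients$estimate, 0)
  expect_lt(fit$coefficients$p_value, 0.05)

  # perfectly separated cutpoint data: monotone negative coefficient
  t1 <- c(90, 85, 80, 70, 65, 60, 50, 45, 40, 30)
  g <- c(1, 1, 1, 2, 2, 2, 3, 3, 4, 4)
  sep <- suppressWarnings(pfirrmann_model(g, t1))
  expect_lt(sep$coefficients$estimate, 0)

  # binary mode works and agrees in sign
  b <- pfirrmann_model(coh$pfirrmann, coh$np_t1rho_ms, mode = "binary")
  expect_lt(b$coefficients$estimate, 0)

  expect_error(pfirrmann_model(rep(2, 10), rnorm(10, 60)), "distinct")
})

test_that("permuted grades give a null ordinal association", {
  coh <- generate_cohort(no_excl(n_subjects = 60, seed = 23))
  set.seed(71)
  p <- replicate(100, {
    g <- sample(coh$pfirrmann)
    suppressWarnings(pfirrmann_model(g, coh$np_t1rho_ms)$coefficients$p_value)
  })
  expect_lt(mean(p < 0.05), 0.12)   # near-nominal false positive rate
  expect_gt(mean(p), 0.35)          # p-values not piled near zero
})

test_that("noiseless interaction-free data give exact coefficient recovery", {
  sp <- no_excl(
    n_subjects = 40,
    beta = c(intercept = 62.4, cep_t2s = 1.06, level = 5.80,
             cep_t2s_level = 0, age = -0.45, bmff = -0.13, sex = 2.32,
             bmi = -0.26),
    random_intercept_sd = 0, residual_sd = 0, seed = 2
  )
  coh <- generate_cohort(sp)
  fit <- mixed_model(coh, "model1")
  cf <- fit$coefficients
  truth <- attr(coh, "truth")$beta[cf$term_key]
  # main effects are invariant to the centring origin; the intercept matches
  # the generative grand mean only up to covariate-mean offsets, so compare
  # non-intercept terms
  keep <- cf$term_key != "intercept"
  expect_equal(cf$estimate[keep], unname(truth[keep]), tolerance = 1e-6)
})

test_that("zero random-intercept variance reproduces OLS exactly", {
  coh <- generate_cohort(no_excl(n_subjects = 80, random_intercept_sd = 0,
                                 residual_sd = 8, seed = 31))
  # force the between-subject variance below its expectation so the REML
  # estimate lands on the boundary: centre the residual part within subject
  d0 <- spineqmr:::.model_frame(coh)
  fitted_part <- with(d0, 62.4 + 1.06 * cep_c + 5.8 * level_ec +
                        0.83 * cep_c * level_ec - 0.45 * age_c - 0.13 * bmff_c +
                        2.32 * sex_ec - 0.26 * bmi_c)
  resid_part <- coh$np_t1rho_ms - fitted_part
  coh$np_t1rho_ms <- fitted_part + resid_part -
    stats::ave(resid_part, coh$subject_id) + mean(resid_part)
  m <- mixed_model(coh, "model1")
  expect_lt(m$random_intercept_variance, 1e-8)
  d <- spineqmr:::.model_frame(coh)
  ols <- lm(y ~ cep_c * level_ec + age_c + bmff_c + sex_ec + bmi_c, data = d)
  ols_est <- coef(ols)[c("(Intercept)", "cep_c", "level_ec", "cep_c:level_ec",
                         "age_c", "bmff_c", "sex_ec", "bmi_c")]
  expect_equal(m$coefficients$estimate, unname(ols_est), tolerance = 1e-6)
})

test_that("balanced noiseless data satisfy the effect-coding identity", {
  sp <- no_excl(
    n_subjects = 30,
    beta = c(intercept = 62.4, cep_t2s = 1.06, level = 5.80,
             cep_t2s_level = 0, age = -0.45, bmff = -0.13, sex = 2.32,
             bmi = -0.26),
    random_intercept_sd = 0, residual_sd = 0, seed = 8
  )
  coh <- generate_cohort(sp)
  fit <- mixed_model(coh, "model1")
  beta_level <- fit$coefficients$estimate[fit$coefficients$term_key == "level"]
  lm_ <- level_means(fit)
  expect_equal(lm_$mean[lm_$level == "L4/5"] - lm_$mean[lm_$level == "L5/S1"],
               2 * beta_level, tolerance = 1e-6)
  expect_equal(2 * beta_level, 2 * 5.80, tolerance = 1e-6)
})

test_that("level means require both levels and bracket the generative truth", {
  coh <- generate_cohort(no_excl(n_subjects = 200, seed = 41))
  fit <- mixed_model(coh, "model1")
  lm_ <- level_means(fit)
  # generative adjusted means: intercept +/- beta_level
  expect_true(lm_$ci_lower[1] <= 62.4 + 5.8 && 62.4 + 5.8 <= lm_$ci_upper[1] ||
                abs(lm_$mean[1] - (62.4 + 5.8)) < 2)
  expect_true(lm_$mean[1] > lm_$mean[2])

  one <- coh[coh$level == "L4/5", ]
  one$level <- "L4/5"
  fit1 <- try(mixed_model(one, "model1"), silent = TRUE)
  if (!inherits(fit1, "try-error")) expect_error(level_means(fit1), "both")
})

test_that("mixed model flags missing columns and single-observation data", {
  coh <- generate_cohort(no_excl(n_subjects = 20, seed = 4))
  expect_error(mixed_model(coh[, setdiff(names(coh), "bmi")]), "bmi")
  single <- coh[!duplicated(coh$subject_id), ]
  expect_error(mixed_model(single), "repeated observations")
})
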