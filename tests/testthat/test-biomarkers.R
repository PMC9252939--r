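# Endplate unit assembly, exclusion bookkeeping and intra-rater ICC.

make_measurements <- function(n_subjects, damaged_subjects = integer(0),
                              angle = 55, seed = 1) {
  set.seed(seed)
  g <- expand.grid(level = c("L4/5", "L5/S1"),
                   endplate = c("superior", "inferior"),
                   subject = seq_len(n_subjects))
  data.frame(
    subject_id = sprintf("S%03d", g$subject),
    level = as.character(g$level),
    endplate = as.character(g$endplate),
    cep_t2star_ms = runif(nrow(g), 15, 25),
    vertebral_bmff_pct = runif(nrow(g), 30, 50),
    np_t1rho_ms = runif(nrow(g), 40, 90),
    cep_angle_deg = rep(angle, nrow(g)),
    damaged = g$subject %in% damaged_subjects,
    stringsAsFactors = FALSE
  )
}

make_covariates <- function(n_subjects) {
  data.frame(subject_id = sprintf("S%03d", seq_len(n_subjects)),
             age = 40, sex = "F", bmi = 26, stringsAsFactors = FALSE)
}

test_that("assembly yields four units per subject with derived inclusion", {
  meas <- make_measurements(60)
  units <- assemble_units(meas, make_covariates(60))
  expect_equal(nrow(units), 240)
  expect_true(all(units$included))
  expect_true(all(units$exclusion_reason == "none"))

  # empty NP region -> excluded with reason
  meas$np_t1rho_ms[5] <- NA
  units2 <- assemble_units(meas, make_covariates(60))
  bad <- units2[is.na(units2$np_t1rho_ms), ]
  expect_false(bad$included)
  expect_equal(bad$exclusion_reason, "empty_region")

  # key mismatch names the orphans
  expect_error(assemble_units(make_measurements(4), make_covariates(5)), "S005")
})

test_that("the printed exclusion bookkeeping reproduces the final cohort", {
  # 80 subjects with complete MRI, 20 damaged, 110 of the remaining 240
  # endplates excluded for orientation -> 60 subjects, 130 endplates
  meas <- make_measurements(80, damaged_subjects = 1:20)
  # spread 110 orientation exclusions over the 60 surviving subjects (one
  # endplate each, plus a second for 50 of them) so that, as in the study,
  # every surviving subject retains at least one endplate
  surviving <- 21:80
  first_ep <- (surviving - 1) * 4 + 1
  second_ep <- (surviving[1:50] - 1) * 4 + 2
  meas$cep_angle_deg[c(first_ep, second_ep)] <- 20  # outside the window
  units <- assemble_units(meas, make_covariates(80))
  res <- apply_exclusions(units, n_enrolled = 84, n_complete_mri = 80)
  expect_equal(res$ledger$n_subjects_excluded_damage, 20)
  expect_equal(res$ledger$n_endplates_excluded_orientation, 110)
  expect_equal(res$ledger$n_subjects_final, 60)
  expect_equal(res$ledger$n_endplates_final, 130)
  expect_equal(nrow(res$included), 130)
})

test_that("edge cases: no exclusions and all-damaged cohorts keep valid ledgers", {
  units <- assemble_units(make_measurements(80), make_covariates(80))
  res <- apply_exclusions(units)
  expect_equal(res$ledger$n_endplates_final, 320)
  expect_equal(res$ledger$n_subjects_final, 80)

  units_all <- assemble_units(make_measurements(10, damaged_subjects = 1:10),
                              make_covariates(10))
  res0 <- apply_exclusions(units_all)
  expect_equal(res0$ledger$n_endplates_final, 0)
  expect_equal(res0$ledger$n_subjects_final, 0)
})

test_that("ledger arithmetic identity holds under random exclusion patterns", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(5:40, 1)
    dmg <- which(runif(n) < 0.3)
    meas <- make_measurements(n, damaged_subjects = dmg, seed = seed)
    flip <- runif(nrow(meas)) < 0.4
    meas$cep_angle_deg[flip] <- 10
    drop <- runif(nrow(meas)) < 0.1
    meas$np_t1rho_ms[drop] <- NA
    units <- assemble_units(meas, make_covariates(n))
    res <- apply_exclusions(units)
    lg <- res$ledger
    expect_equal(
      lg$n_endplates_final,
      (lg$n_complete_mri - lg$n_subjects_excluded_damage) * 4 -
        lg$n_endplates_excluded_orientation - lg$n_endplates_excluded_other
    )
    expect_equal(nrow(res$included) + sum(!units$included), nrow(units))
  }
})

test_that("ICC closed forms match the classic inter-rater benchmark", {
  # Shrout & Fleiss (1979) six-target, four-judge example
  r <- matrix(c(9, 2, 5, 8,
                6, 1, 3, 2,
                8, 4, 6, 8,
                7, 1, 2, 6,
                10, 5, 6, 9,
                6, 2, 4, 7), 6, 4, byrow = TRUE)
  expect_equal(round(intra_rater_icc(r, "ICC1")$icc, 2), 0.17)
  expect_equal(round(intra_rater_icc(r, "ICC2")$icc, 2), 0.29)
  expect_equal(round(intra_rater_icc(r, "ICC3")$icc, 2), 0.71)

  # mean squares agree with aov on the long layout
  long <- data.frame(y = as.vector(r),
                     item = factor(rep(1:6, times = 4)),
                     rater = factor(rep(1:4, each = 6)))
  ms <- anova(lm(y ~ item + rater, data = long))
  got <- intra_rater_icc(r, "ICC2")$ms
  expect_equal(got$between, ms["item", "Mean Sq"], tolerance = 1e-10)
  expect_equal(got$raters, ms["rater", "Mean Sq"], tolerance = 1e-10)
  expect_equal(got$error, ms["Residuals", "Mean Sq"], tolerance = 1e-10)
})

test_that("ICC is 1 for identical pairs and ~0 for independent pairs", {
  x <- c(9, 6, 8, 7, 10, 6)
  expect_equal(intra_rater_icc(cbind(x, x))$icc, 1)

  set.seed(33)
  r <- cbind(rnorm(1000), rnorm(1000))
  expect_lt(abs(intra_rater_icc(r)$icc), 0.1)

  # zero between-item variance: defined limit with warning
  same <- cbind(c(5, 6, 4), c(6, 5, 7))  # equal item means, residual noise
  expect_warning(res <- intra_rater_icc(same), "between-item")
  expect_true(is.finite(res$icc) && res$icc <= 0)
  expect_warning(res0 <- intra_rater_icc(matrix(3, 4, 2)), "zero variance")
  expect_equal(res0$icc, 0)
})
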