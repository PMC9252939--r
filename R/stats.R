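# Association analyses: univariate OLS, Pearson correlation matrix,
# proportional-odds (or binary logistic) model of Pfirrmann grade on NP
# T1rho, and two random-intercept mixed-effects models of NP T1rho fitted
# by REML. Coding conventions (documented, switchable): spinal level is
# effect-coded +1 = L4/5, -1 = L5/S1; sex is effect-coded +1 = female,
# -1 = male; continuous predictors are centred at their sample means before
# interactions are formed, so main effects are interpretable at the mean.
# Inference uses Wald z intervals by default (Satterthwaite df optional);
# no multiple-testing correction is applied.

.mk_result <- function(coefs, model_label, n_obs, n_subjects = NA_integer_,
                       ri_var = NA_real_, res_var = NA_real_,
                       converged = TRUE, fit = NULL, data = NULL) {
  structure(list(
    coefficients = coefs,
    model = model_label,
    n_obs = n_obs,
    n_subjects = n_subjects,
    random_intercept_variance = ri_var,
    residual_variance = res_var,
    converged = converged,
    fit = fit,
    data = data
  ), class = "model_fit_result")
}

#' @export
print.model_fit_result <- function(x, digits = 3, ...) {
  cat("<model_fit_result>", x$model, "| n =", x$n_obs)
  if (!is.na(x$n_subjects)) cat(" obs,", x$n_subjects, "subjects")
  cat(if (x$converged) " | converged\n" else " | NOT CONVERGED\n")
  cf <- x$coefficients
  cf$term_key <- NULL
  print(format(cf, digits = digits), row.names = FALSE)
  if (!is.na(x$random_intercept_variance))
    cat(sprintf("  random intercept var %.3f | residual var %.3f\n",
                x$random_intercept_variance, x$residual_variance))
  invisible(x)
}

#' Univariate linear regression of one biomarker on another
#'
#' Ordinary least squares of `y` on a single predictor with Wald 95% CI and
#' two-sided p-value.
#'
#' @param y response vector (e.g. NP T1rho, ms).
#' @param x predictor vector (e.g. CEP T2* or vertebral BMFF).
#' @param term name used for the predictor in the output.
#' @return a `model_fit_result` with `(Intercept)` and slope rows.
#' @export
univariate_ols <- function(y, x, term = deparse(substitute(x))) {
  keep <- is.finite(y) & is.finite(x)
  fit <- stats::lm(y ~ x, data = data.frame(y = y[keep], x = x[keep]))
  sm <- summary(fit)$coefficients
  ci <- stats::confint(fit)
  coefs <- data.frame(
    term = c("(Intercept)", term),
    term_key = c("intercept", "x"),
    estimate = sm[, 1],
    ci_lower = ci[, 1], ci_upper = ci[, 2],
    p_value = sm[, 4],
    row.names = NULL, stringsAsFactors = FALSE
  )
  .mk_result(coefs, paste("OLS:", term), n_obs = sum(keep),
             res_var = summary(fit)$sigma^2, fit = fit)
}

#' Pairwise Pearson correlation matrix with p-values
#'
#' @param table data.frame holding the variables.
#' @param variables character vector of column names.
#' @return object of class `correlation_matrix`: list with matrices `r` and
#'   `p` (two-sided) and pairwise `n`.
#' @export
correlation_matrix <- function(table, variables) {
  stopifnot(all(variables %in% names(table)))
  X <- as.data.frame(table)[variables]
  k <- length(variables)
  r <- diag(k); p <- matrix(NA_real_, k, k); n <- matrix(NA_integer_, k, k)
  dimnames(r) <- dimnames(p) <- dimnames(n) <- list(variables, variables)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) { n[i, j] <- sum(is.finite(X[[i]])); next }
    ok <- is.finite(X[[i]]) & is.finite(X[[j]])
    ct <- stats::cor.test(X[[i]][ok], X[[j]][ok], method = "pearson")
    r[i, j] <- unname(ct$estimate); p[i, j] <- ct$p.value; n[i, j] <- sum(ok)
  }
  structure(list(r = r, p = p, n = n), class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, digits = 3, ...) {
  cat("<correlation_matrix> Pearson r (lower triangle), p (upper)\n")
  m <- x$r
  m[upper.tri(m)] <- x$p[upper.tri(x$p)]
  print(round(m, digits))
  invisible(x)
}

#' Ordinal or binary logistic model of Pfirrmann grade on NP T1rho
#'
#' Default: proportional-odds model (cumulative logit) of the ordered grade
#' on mean NP T1rho; a negative slope means lower T1rho at higher grade.
#' `mode = "binary"` dichotomises at grade >= `binary_cut` and fits
#' ordinary logistic regression.
#'
#' @param grade integer/ordered Pfirrmann grades (I-V as 1-5).
#' @param t1rho mean NP T1rho per observation, ms.
#' @param mode `"ordinal"` (default) or `"binary"`.
#' @param binary_cut grade threshold for binary mode (default 3).
#' @return a `model_fit_result` with the T1rho slope (log-odds scale).
#' @export
pfirrmann_model <- function(grade, t1rho, mode = c("ordinal", "binary"),
                            binary_cut = 3) {
  mode <- match.arg(mode)
  keep <- is.finite(t1rho) & !is.na(grade)
  grade <- as.integer(grade)[keep]
  t1rho <- t1rho[keep]
  if (length(unique(grade)) < 2)
    stop("Pfirrmann grades must take at least 2 distinct values")
  msgs <- character()
  if (mode == "ordinal") {
    d <- data.frame(g = factor(grade, ordered = TRUE), x = t1rho)
    # explicit start (zero slope, cumulative-logit cutpoints) keeps the
    # optimiser finite on small or separated samples
    cum <- cumsum(table(d$g)) / nrow(d)
    start <- c(0, stats::qlogis(pmin(pmax(cum[-length(cum)], 1e-6), 1 - 1e-6)))
    fit <- withCallingHandlers(
      MASS::polr(g ~ x, data = d, Hess = TRUE, start = start),
      warning = function(w) {
        msgs <<- c(msgs, conditionMessage(w)); invokeRestart("muffleWarning")
      })
    sm <- summary(fit)$coefficients
    est <- sm["x", "Value"]; se <- sm["x", "Std. Error"]
  } else {
    d <- data.frame(g = as.integer(grade >= binary_cut), x = t1rho)
    fit <- withCallingHandlers(
      stats::glm(g ~ x, family = stats::binomial(), data = d),
      warning = function(w) {
        msgs <<- c(msgs, conditionMessage(w)); invokeRestart("muffleWarning")
      })
    sm <- summary(fit)$coefficients
    est <- sm["x", 1]; se <- sm["x", 2]
  }
  z <- est / se
  coefs <- data.frame(
    term = "NP T1rho", term_key = "np_t1rho",
    estimate = est,
    ci_lower = est - stats::qnorm(0.975) * se,
    ci_upper = est + stats::qnorm(0.975) * se,
    p_value = 2 * stats::pnorm(-abs(z)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  .mk_result(coefs, paste0("Pfirrmann (", mode, ")"), n_obs = length(grade),
             converged = length(msgs) == 0, fit = fit)
}

# model term layouts: display label and generator beta key per coefficient
.MODEL_TERMS <- list(
  model1 = data.frame(
    coef = c("(Intercept)", "cep_c", "level_ec", "cep_c:level_ec",
             "age_c", "bmff_c", "sex_ec", "bmi_c"),
    term = c("(Intercept)", "CEP T2*", "Level", "CEP T2* x Level",
             "Age", "Vertebral BMFF", "Sex", "BMI"),
    term_key = c("intercept", "cep_t2s", "level", "cep_t2s_level",
                 "age", "bmff", "sex", "bmi"),
    stringsAsFactors = FALSE
  ),
  model2 = data.frame(
    coef = c("(Intercept)", "level_ec", "cep_c", "cep_c:level_ec", "age_c",
             "bmff_c", "level_ec:bmff_c", "cep_c:bmff_c",
             "cep_c:level_ec:bmff_c"),
    term = c("(Intercept)", "Level", "CEP T2*", "CEP T2* x Level", "Age",
             "Vertebral BMFF", "Vertebral BMFF x Level",
             "CEP T2* x Vertebral BMFF", "CEP T2* x Vertebral BMFF x Level"),
    term_key = c("intercept", "level", "cep_t2s", "cep_t2s_level", "age",
                 "bmff", "bmff_level", "cep_t2s_bmff", "cep_t2s_bmff_level"),
    stringsAsFactors = FALSE
  )
)

# per-replicate estimand: the generative (noise-free) mean function
# projected onto the fitted fixed-effect design; exact whenever the
# generative terms are a subset of the model terms
.realized_truth <- function(coh, res, layout) {
  tr <- attr(coh, "truth")
  if (is.null(tr)) stop("cohort lacks generative truth attributes")
  bt <- tr$beta; ctr <- tr$centers
  cc <- coh$cep_t2star_ms - ctr["cep_t2s"]
  cb <- coh$vertebral_bmff_pct - ctr["bmff"]
  ca <- coh$age - ctr["age"]
  cm <- coh$bmi - ctr["bmi"]
  Lc <- ifelse(coh$level == "L4/5", 1, -1)
  Sx <- if (is.numeric(coh$sex)) coh$sex else ifelse(coh$sex == "F", 1, -1)
  mu <- bt["intercept"] + bt["cep_t2s"] * cc + bt["level"] * Lc +
    bt["cep_t2s_level"] * cc * Lc + bt["age"] * ca + bt["bmff"] * cb +
    bt["sex"] * Sx + bt["bmi"] * cm + bt["bmff_level"] * cb * Lc +
    bt["cep_t2s_bmff"] * cc * cb + bt["cep_t2s_bmff_level"] * cc * cb * Lc
  X <- stats::model.matrix(lme4::nobars(stats::formula(res$fit))[-2], res$data)
  beta_star <- qr.coef(qr(X), as.numeric(mu))
  canon <- function(x) vapply(strsplit(x, ":"), function(p)
    paste(sort(p), collapse = ":"), character(1))
  unname(beta_star[match(canon(layout$coef), canon(colnames(X)))])
}

# prepare the modelling frame: effect codes and (optionally) mean-centred
# continuous predictors
.model_frame <- function(units, center = TRUE) {
  need <- c("subject_id", "level", "np_t1rho_ms", "cep_t2star_ms",
            "vertebral_bmff_pct", "age", "sex", "bmi")
  miss <- setdiff(need, names(units))
  if (length(miss)) stop("units lacks columns: ", paste(miss, collapse = ", "))
  d <- as.data.frame(units)
  lv <- unique(d$level)
  if (!all(lv %in% c("L4/5", "L5/S1")))
    stop("level must be 'L4/5' or 'L5/S1'")
  ctr <- function(x) if (center) x - mean(x) else x
  data.frame(
    subject_id = d$subject_id,
    y = d$np_t1rho_ms,
    cep_c = ctr(d$cep_t2star_ms),
    bmff_c = ctr(d$vertebral_bmff_pct),
    age_c = ctr(d$age),
    bmi_c = ctr(d$bmi),
    level_ec = ifelse(d$level == "L4/5", 1, -1),
    sex_ec = if (is.numeric(d$sex)) d$sex else ifelse(d$sex == "F", 1, -1),
    stringsAsFactors = FALSE
  )
}

#' Random-intercept mixed-effects models of NP T1rho
#'
#' Fits one of the two multivariable models by REML with a random intercept
#' per subject. `model1` regresses NP T1rho on CEP T2*, level, their
#' interaction, age, vertebral BMFF, sex and BMI. `model2` compares CEP T2*
#' and vertebral BMFF directly: level, CEP T2*, CEP T2* x level, age, BMFF,
#' BMFF x level, CEP T2* x BMFF and the three-way interaction.
#'
#' @param units per-endplate units: needs `subject_id`, `level`,
#'   `np_t1rho_ms`, `cep_t2star_ms`, `vertebral_bmff_pct`, `age`, `sex`,
#'   `bmi`.
#' @param model `"model1"` or `"model2"`.
#' @param center centre continuous predictors at their sample means
#'   (default TRUE).
#' @param df_method `"wald"` (z intervals, default) or `"satterthwaite"`
#'   (requires the lmerTest package).
#' @return a `model_fit_result`; non-convergence is flagged in `converged`,
#'   never silently replaced.
#' @export
mixed_model <- function(units, model = c("model1", "model2"), center = TRUE,
                        df_method = c("wald", "satterthwaite")) {
  model <- match.arg(model)
  df_method <- match.arg(df_method)
  d <- .model_frame(units, center = center)
  if (max(table(d$subject_id)) < 2)
    stop("mixed model needs repeated observations for at least one subject")
  form <- if (model == "model1") {
    y ~ cep_c * level_ec + age_c + bmff_c + sex_ec + bmi_c + (1 | subject_id)
  } else {
    y ~ cep_c * level_ec * bmff_c + age_c + (1 | subject_id)
  }
  msgs <- character()
  use_lmertest <- df_method == "satterthwaite"
  if (use_lmertest && !requireNamespace("lmerTest", quietly = TRUE))
    stop("df_method = 'satterthwaite' requires the lmerTest package")
  fitter <- if (use_lmertest) lmerTest::lmer else lme4::lmer
  fit <- withCallingHandlers(
    fitter(form, data = d, REML = TRUE),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w)); invokeRestart("muffleWarning")
    },
    message = function(m) {
      msgs <<- c(msgs, conditionMessage(m)); invokeRestart("muffleMessage")
    })
  opt_msgs <- fit@optinfo$conv$lme4$messages
  converged <- is.null(opt_msgs) ||
    !any(grepl("failed to converge", opt_msgs, ignore.case = TRUE))

  sm <- summary(fit)$coefficients
  layout <- .MODEL_TERMS[[model]]
  # lme4 may order interaction factors differently; match on sorted parts
  canon <- function(x) vapply(strsplit(x, ":"), function(p)
    paste(sort(p), collapse = ":"), character(1))
  idx <- match(canon(layout$coef), canon(rownames(sm)))
  if (anyNA(idx)) stop("internal: model terms not found in fit")
  est <- sm[idx, "Estimate"]
  se <- sm[idx, "Std. Error"]
  if (use_lmertest) {
    df <- sm[idx, "df"]
    crit <- stats::qt(0.975, df)
    p <- 2 * stats::pt(-abs(est / se), df)
  } else {
    crit <- stats::qnorm(0.975)
    p <- 2 * stats::pnorm(-abs(est / se))
  }
  coefs <- data.frame(
    term = layout$term, term_key = layout$term_key,
    estimate = unname(est),
    ci_lower = unname(est - crit * se), ci_upper = unname(est + crit * se),
    p_value = unname(p),
    row.names = NULL, stringsAsFactors = FALSE
  )
  vc <- as.data.frame(lme4::VarCorr(fit))
  ri_var <- vc$vcov[vc$grp == "subject_id" & vc$var1 == "(Intercept)"][1]
  res_var <- vc$vcov[vc$grp == "Residual"][1]
  .mk_result(coefs, model, n_obs = nrow(d),
             n_subjects = length(unique(d$subject_id)),
             ri_var = ri_var, res_var = res_var,
             converged = converged, fit = fit, data = d)
}

#' Adjusted per-level NP T1rho means with 95% CI
#'
#' Model-adjusted means of NP T1rho at L4/5 and L5/S1 (other predictors at
#' their means), from a fitted [mixed_model()] via emmeans.
#'
#' @param result a `model_fit_result` from [mixed_model()].
#' @return data.frame with `level`, `mean`, `ci_lower`, `ci_upper`.
#' @export
level_means <- function(result) {
  stopifnot(inherits(result, "model_fit_result"))
  if (is.null(result$fit) || !inherits(result$fit, "merMod"))
    stop("level_means needs a mixed_model result")
  d <- result$data
  if (length(unique(d$level_ec)) < 2)
    stop("both spinal levels must be present to compute level means")
  em <- suppressMessages(
    emmeans::emmeans(result$fit, ~level_ec, at = list(level_ec = c(1, -1)),
                     lmer.df = "asymptotic", data = d))
  s <- as.data.frame(em)
  data.frame(
    level = c("L4/5", "L5/S1"),
    mean = s$emmean,
    ci_lower = s$asymp.LCL,
    ci_upper = s$asymp.UCL,
    stringsAsFactors = FALSE
  )
}

#' Parameter-recovery and error-rate study for the mixed model
#'
#' Simulates `n_reps` cohorts from a [cohort_spec()], fits the chosen mixed
#' model to each, and summarises per-coefficient recovery: mean estimate,
#' relative bias, Monte-Carlo SE, 95% CI coverage of the generative truth,
#' and the two-sided Wald rejection rate at alpha = 0.05 (the type-I error
#' rate for coefficients whose generative value is zero).
#'
#' @param spec a [cohort_spec()]; exclusion probabilities are honoured, so
#'   set them to zero to study the estimator under the pure generative
#'   model.
#' @param n_reps number of simulated cohorts.
#' @param model passed to [mixed_model()].
#' @param seed master seed; per-replicate seeds are drawn from it.
#' @param apply_exclusion fit on included units only (default FALSE).
#'
#' @details Coverage is assessed against the per-replicate estimand: the
#'   generative mean function projected onto the fitted (sample-centred)
#'   design. Because sample-mean centring is an exact reparameterisation,
#'   this equals the generative coefficient for every term not involved in
#'   an interaction with a centred covariate; for terms that are (e.g. the
#'   level main effect when a CEP x level interaction is present), the
#'   fitted coefficient's true value shifts by `beta_int * (xbar - mu)` and
#'   the CI is judged against that value. Bias (`mean_estimate`, `rel_bias`)
#'   is still reported against the generative coefficients, whose expected
#'   estimate is identical.
#' @return data.frame, one row per fixed-effect coefficient.
#' @export
recovery_study <- function(spec, n_reps = 200, model = "model1", seed = 1,
                           apply_exclusion = FALSE) {
  stopifnot(inherits(spec, "cohort_spec"), n_reps >= 2)
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, n_reps))
  layout <- .MODEL_TERMS[[model]]
  est <- cov <- rej <- matrix(NA_real_, n_reps, nrow(layout))
  truth_beta <- spec$beta
  n_used <- numeric(n_reps)
  for (i in seq_len(n_reps)) {
    sp <- spec
    sp$seed <- seeds[i]
    coh <- generate_cohort(sp)
    if (apply_exclusion) {
      tr <- attr(coh, "truth")
      cov_tab <- unique(coh[c("subject_id", "age", "sex", "bmi")])
      coh <- assemble_units(coh[setdiff(names(coh), c("age", "sex", "bmi"))],
                            cov_tab)
      coh <- apply_exclusions(coh)$included
      attr(coh, "truth") <- tr
    }
    res <- mixed_model(coh, model = model)
    cf <- res$coefficients
    truth_i <- .realized_truth(coh, res, layout)
    est[i, ] <- cf$estimate
    cov[i, ] <- as.numeric(cf$ci_lower <= truth_i & truth_i <= cf$ci_upper)
    rej[i, ] <- as.numeric(cf$p_value < 0.05)
    n_used[i] <- res$n_obs
  }
  truth <- truth_beta[layout$term_key]
  data.frame(
    term = layout$term,
    term_key = layout$term_key,
    truth = unname(truth),
    mean_estimate = colMeans(est),
    rel_bias = ifelse(truth != 0, (colMeans(est) - truth) / truth, NA_real_),
    mc_se = apply(est, 2, stats::sd) / sqrt(n_reps),
    coverage = colMeans(cov),
    rejection_rate = colMeans(rej),
    n_reps = n_reps,
    mean_n_obs = mean(n_used),
    row.names = NULL, stringsAsFactors = FALSE
  )
}
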