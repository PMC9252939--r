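# Simulated cLBP cohort with the generative structure used by the
# association analyses: per-endplate NP T1rho follows a linear model in CEP
# T2*, spinal level (effect-coded +1 = L4/5, -1 = L5/S1), their interaction,
# age, vertebral BMFF, sex (effect-coded +1 = female) and BMI, with a
# Gaussian random intercept per subject and Gaussian residuals. Covariates
# are drawn from a moment-matched Gaussian copula: bounded truncated-normal
# marginals whose latent parameters are solved so the realised mean/SD equal
# the requested ones, and latent correlations de-attenuated so the realised
# Pearson correlations match the requested targets.

# ---- truncated normal helpers ------------------------------------------

.tnorm_moments <- function(mu, sigma, lo, hi) {
  a <- (lo - mu) / sigma; b <- (hi - mu) / sigma
  Z <- stats::pnorm(b) - stats::pnorm(a)
  da <- stats::dnorm(a); db <- stats::dnorm(b)
  m <- mu + sigma * (da - db) / Z
  aa <- ifelse(is.finite(a), a * da, 0)
  bb <- ifelse(is.finite(b), b * db, 0)
  v <- sigma^2 * (1 + (aa - bb) / Z - ((da - db) / Z)^2)
  c(mean = m, sd = sqrt(v))
}

# latent (mu, sigma) such that the [lo, hi]-truncated normal has the target
# mean and SD
.tnorm_match <- function(mean, sd, lo, hi) {
  mean <- unname(mean); sd <- unname(sd)
  if (!is.finite(lo) && !is.finite(hi)) return(c(mu = mean, sigma = sd))
  obj <- function(par) {
    m <- .tnorm_moments(par[1], exp(par[2]), lo, hi)
    (m[1] - mean)^2 / sd^2 + (m[2] - sd)^2 / sd^2
  }
  fit <- stats::optim(c(mean, log(sd)), obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  c(mu = unname(fit$par[1]), sigma = unname(exp(fit$par[2])))
}

.qtnorm <- function(u, mu, sigma, lo, hi) {
  pa <- stats::pnorm(lo, mu, sigma); pb <- stats::pnorm(hi, mu, sigma)
  stats::qnorm(pa + u * (pb - pa), mu, sigma)
}

# linear (Hermite first-order) attenuation factor of a margin transform
# f(z) = Q_trunc(pnorm(z)): lambda = cor(f(Z), Z) under Z ~ N(0,1)
.margin_lambda <- function(mu, sigma, lo, hi) {
  z <- seq(-8, 8, length.out = 4001)
  w <- stats::dnorm(z); w <- w / sum(w)
  f <- .qtnorm(stats::pnorm(z), mu, sigma, lo, hi)
  mf <- sum(w * f)
  vf <- sum(w * (f - mf)^2)
  sum(w * (f - mf) * z) / sqrt(vf)
}

.nearest_corr <- function(S) {
  e <- eigen(S, symmetric = TRUE)
  if (min(e$values) > 1e-10) return(S)
  v <- pmax(e$values, 1e-8)
  S2 <- e$vectors %*% diag(v) %*% t(e$vectors)
  d <- 1 / sqrt(diag(S2))
  S2 * outer(d, d)
}

# ---- cohort specification ----------------------------------------------

default_cohort_beta <- function() {
  c(intercept = 62.4, cep_t2s = 1.06, level = 5.80, cep_t2s_level = 0.83,
    age = -0.45, bmff = -0.13, sex = 2.32, bmi = -0.26,
    bmff_level = 0, cep_t2s_bmff = 0, cep_t2s_bmff_level = 0)
}

default_covariate_dists <- function() {
  list(
    age      = c(mean = 40.0, sd = 11.9, min = 19,   max = 65),
    bmi      = c(mean = 26.1, sd = 4.7,  min = 18.8, max = 45.7),
    bmff     = c(mean = 40,   sd = 10,   min = 10,   max = 70),
    cep_t2s  = c(mean = 20,   sd = 5,    min = 5,    max = 40),
    sex_female_prop = 28 / 60
  )
}

default_covariate_corr <- function() {
  v <- c("age", "bmi", "bmff", "cep_t2s")
  R <- diag(4); dimnames(R) <- list(v, v)
  R["age", "bmi"] <- R["bmi", "age"] <- -0.100
  R["age", "bmff"] <- R["bmff", "age"] <- 0.599
  R["age", "cep_t2s"] <- R["cep_t2s", "age"] <- -0.185
  R["bmi", "bmff"] <- R["bmff", "bmi"] <- -0.049
  R["bmi", "cep_t2s"] <- R["cep_t2s", "bmi"] <- 0.339
  R["bmff", "cep_t2s"] <- R["cep_t2s", "bmff"] <- -0.160
  R
}

#' Specification of a simulated cohort
#'
#' Parameters of the generative model behind [generate_cohort()]: the fixed
#' effects of the per-endplate NP T1rho model, the variance components, the
#' covariate marginals and correlation targets, the Pfirrmann cutpoints and
#' the exclusion probabilities.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param levels_per_subject spinal levels per subject; fixed at 2
#'   (L4/5 and L5/S1).
#' @param endplates_per_level endplates observed per level (default 2:
#'   superior and inferior), so 4 endplate units per subject.
#' @param beta named coefficient vector; see [default_cohort_beta()] for the
#'   names and defaults (ms per unit of each centred predictor; `level` and
#'   `sex` are effect-coded +/-1). Partial vectors override by name.
#' @param random_intercept_sd subject random-intercept SD, ms.
#' @param residual_sd residual SD, ms.
#' @param covariate_dists list of `c(mean, sd, min, max)` for `age`, `bmi`,
#'   `bmff`, `cep_t2s`, plus `sex_female_prop`.
#' @param covariate_corr 4x4 target Pearson correlation matrix for
#'   (age, bmi, bmff, cep_t2s).
#' @param pfirrmann_cutpoints strictly decreasing NP T1rho thresholds (ms)
#'   separating grades I|II, II|III, III|IV, IV|V (higher grade = lower
#'   T1rho).
#' @param pfirrmann_noise_sd SD of the latent noise added to the level-mean
#'   NP T1rho before grading, ms.
#' @param exclusion_probs `c(damage = , orientation = )`: per-subject CEP
#'   damage probability and per-endplate orientation-exclusion probability.
#' @param seed RNG seed.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 60,
                        levels_per_subject = 2,
                        endplates_per_level = 2,
                        beta = default_cohort_beta(),
                        random_intercept_sd = 10,
                        residual_sd = 11,
                        covariate_dists = default_covariate_dists(),
                        covariate_corr = default_covariate_corr(),
                        pfirrmann_cutpoints = c(85.5, 61, 48, 20),
                        pfirrmann_noise_sd = 5,
                        exclusion_probs = c(damage = 0.25,
                                            orientation = 110 / 240),
                        seed = 1L) {
  b <- default_cohort_beta()
  stopifnot(all(names(beta) %in% names(b)))
  b[names(beta)] <- beta
  cd <- utils::modifyList(default_covariate_dists(), covariate_dists)
  if (levels_per_subject != 2)
    stop("levels_per_subject is fixed at 2 (L4/5 and L5/S1)")
  if (n_subjects < 2) stop("n_subjects must be >= 2")
  if (random_intercept_sd < 0 || residual_sd < 0)
    stop("variance-component SDs must be >= 0")
  for (v in c("age", "bmi", "bmff", "cep_t2s")) {
    x <- cd[[v]]
    if (x["sd"] <= 0) stop("covariate SD must be > 0: ", v)
    if (x["min"] >= x["max"]) stop("covariate bounds must satisfy min < max: ", v)
  }
  if (cd$sex_female_prop < 0 || cd$sex_female_prop > 1)
    stop("sex_female_prop must lie in [0, 1]")
  stopifnot(all(dim(covariate_corr) == c(4, 4)),
            max(abs(covariate_corr - t(covariate_corr))) < 1e-12,
            all(diag(covariate_corr) == 1))
  if (min(eigen(covariate_corr, symmetric = TRUE, only.values = TRUE)$values) < -1e-10)
    stop("covariate_corr must be positive semi-definite")
  if (any(diff(pfirrmann_cutpoints) >= 0))
    stop("pfirrmann_cutpoints must be strictly decreasing (higher grade = lower T1rho)")
  if (any(exclusion_probs < 0 | exclusion_probs > 1))
    stop("exclusion_probs must lie in [0, 1]")
  structure(list(
    n_subjects = as.integer(n_subjects),
    levels_per_subject = 2L,
    endplates_per_level = as.integer(endplates_per_level),
    beta = b,
    random_intercept_sd = random_intercept_sd,
    residual_sd = residual_sd,
    covariate_dists = cd,
    covariate_corr = covariate_corr,
    pfirrmann_cutpoints = pfirrmann_cutpoints,
    pfirrmann_noise_sd = pfirrmann_noise_sd,
    exclusion_probs = exclusion_probs,
    seed = as.integer(seed)
  ), class = "cohort_spec")
}

#' Simulate a cohort of per-endplate observations
#'
#' Draws subject covariates (age, BMI, sex) and endplate-level biomarkers
#' (CEP T2*, vertebral BMFF) from the moment-matched Gaussian copula, then
#' generates NP T1rho for endplate k of subject i as
#' `X beta + b_i + e_ik` with `b_i ~ N(0, random_intercept_sd^2)` and
#' `e ~ N(0, residual_sd^2)`; continuous predictors enter centred at their
#' target means. Pfirrmann grade is assigned per disc level by cutpoints on
#' the level-mean NP T1rho plus latent noise; CEP damage (subject level) and
#' orientation angles (endplate level) are sampled from `exclusion_probs`.
#'
#' @param spec a [cohort_spec()].
#' @return a `data.frame` of class `cohort_table`, one row per endplate
#'   unit, with columns `subject_id`, `level`, `endplate`, `age`, `sex`,
#'   `bmi`, `cep_t2star_ms`, `vertebral_bmff_pct`, `np_t1rho_ms`,
#'   `pfirrmann`, `cep_angle_deg`, `damaged`. The generative truth
#'   (coefficients and variance components) is attached as
#'   `attr(, "truth")`.
#' @examples
#' coh <- generate_cohort(cohort_spec(n_subjects = 10, seed = 7))
#' head(coh)
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_subjects
  epl <- spec$endplates_per_level
  cd <- spec$covariate_dists
  vars <- c("age", "bmi", "bmff", "cep_t2s")

  # latent marginal parameters and attenuation factors
  mm <- lapply(vars, function(v) {
    x <- cd[[v]]
    .tnorm_match(x["mean"], x["sd"], x["min"], x["max"])
  })
  names(mm) <- vars
  lam <- vapply(vars, function(v) {
    x <- cd[[v]]
    .margin_lambda(mm[[v]]["mu"], mm[[v]]["sigma"], x["min"], x["max"])
  }, numeric(1))

  S <- spec$covariate_corr
  L <- outer(lam, lam)
  Slat <- S / L
  diag(Slat) <- 1
  Slat[Slat > 0.999] <- 0.999
  Slat[Slat < -0.999] <- -0.999
  Slat <- .nearest_corr(Slat)

  # partition: subject-level block (age, bmi) and endplate-level (bmff, cep)
  S11 <- Slat[1:2, 1:2]; S12 <- Slat[1:2, 3:4]; S22 <- Slat[3:4, 3:4]
  S11i <- solve(S11)
  cond_B <- t(S12) %*% S11i
  cond_cov <- S22 - t(S12) %*% S11i %*% S12
  chol11 <- chol(S11)
  cholc <- chol(cond_cov)

  n_ep <- 2L * epl                       # endplates per subject
  with_seed(spec$seed, {
    z12 <- matrix(stats::rnorm(n * 2), n, 2) %*% chol11
    sex <- ifelse(stats::runif(n) < cd$sex_female_prop, "F", "M")
    b_i <- stats::rnorm(n, 0, spec$random_intercept_sd)

    # endplate-level latent draws, conditional on the subject block
    mu34 <- z12 %*% t(cond_B)
    z34 <- matrix(stats::rnorm(n * n_ep * 2), n * n_ep, 2) %*% cholc +
      mu34[rep(seq_len(n), each = n_ep), ]

    tr <- function(z, v) {
      x <- cd[[v]]
      .qtnorm(stats::pnorm(z), mm[[v]]["mu"], mm[[v]]["sigma"], x["min"], x["max"])
    }
    age <- tr(z12[, 1], "age")
    bmi <- tr(z12[, 2], "bmi")
    bmff <- tr(z34[, 1], "bmff")
    cep <- tr(z34[, 2], "cep_t2s")

    subj <- rep(seq_len(n), each = n_ep)
    level <- rep(rep(c("L4/5", "L5/S1"), each = epl), times = n)
    endplate <- rep(rep(c("superior", "inferior"), length.out = epl), times = 2 * n)
    Lc <- ifelse(level == "L4/5", 1, -1)
    Sx <- ifelse(sex == "F", 1, -1)[subj]

    bt <- spec$beta
    cc <- cep - cd$cep_t2s["mean"]
    cb <- bmff - cd$bmff["mean"]
    ca <- (age - cd$age["mean"])[subj]
    cm <- (bmi - cd$bmi["mean"])[subj]
    eps <- stats::rnorm(n * n_ep, 0, spec$residual_sd)
    y <- bt["intercept"] + bt["cep_t2s"] * cc + bt["level"] * Lc +
      bt["cep_t2s_level"] * cc * Lc + bt["age"] * ca + bt["bmff"] * cb +
      bt["sex"] * Sx + bt["bmi"] * cm +
      bt["bmff_level"] * cb * Lc + bt["cep_t2s_bmff"] * cc * cb +
      bt["cep_t2s_bmff_level"] * cc * cb * Lc +
      b_i[subj] + eps
    # physical floor: relaxation times are positive; at the default
    # parameters the clipped Gaussian tail is ~5e-4 of draws
    y <- pmax(y, 1)

    # Pfirrmann grade per disc level from the level-mean NP T1rho
    key <- paste(subj, level)
    lev_mean <- tapply(y, key, mean)[key]
    latent <- lev_mean + stats::rnorm(n * n_ep, 0, spec$pfirrmann_noise_sd)
    # grade index per endplate row; identical within a level up to latent
    # noise drawn once per level:
    lat_lev <- tapply(latent, key, function(v) v[1])[key]
    grade <- 1L + vapply(lat_lev, function(v)
      sum(spec$pfirrmann_cutpoints > v), integer(1))

    damaged <- (stats::runif(n) < spec$exclusion_probs["damage"])[subj]
    win <- magic_angle_window()
    incl <- stats::runif(n * n_ep) >= spec$exclusion_probs["orientation"]
    lo_side <- stats::runif(n * n_ep) < 0.5
    angle <- ifelse(incl,
                    stats::runif(n * n_ep, win[1] + 0.25, win[2] - 0.25),
                    ifelse(lo_side,
                           stats::runif(n * n_ep, 0, win[1] - 0.5),
                           stats::runif(n * n_ep, win[2] + 0.5, 90)))

    out <- data.frame(
      subject_id = sprintf("S%03d", subj),
      level = level,
      endplate = endplate,
      age = age[subj],
      sex = sex[subj],
      bmi = bmi[subj],
      cep_t2star_ms = cep,
      vertebral_bmff_pct = bmff,
      np_t1rho_ms = as.numeric(y),
      pfirrmann = as.integer(grade),
      cep_angle_deg = angle,
      damaged = damaged,
      stringsAsFactors = FALSE
    )
    attr(out, "truth") <- list(
      beta = spec$beta,
      random_intercept_sd = spec$random_intercept_sd,
      residual_sd = spec$residual_sd,
      centers = c(cep_t2s = unname(cd$cep_t2s["mean"]),
                  bmff = unname(cd$bmff["mean"]),
                  age = unname(cd$age["mean"]),
                  bmi = unname(cd$bmi["mean"]))
    )
    class(out) <- c("cohort_table", "data.frame")
    out
  })
}
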