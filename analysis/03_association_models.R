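#!/usr/bin/env Rscript
# The association analyses on the simulated included cohort: univariate
# regressions of NP T1rho on CEP T2* and on vertebral BMFF, the
# proportional-odds model against Pfirrmann grade, both multivariable
# random-intercept mixed models, and the adjusted per-level means. Writes
# results/model1_coefficients.csv, results/model2_coefficients.csv,
# results/univariate.csv and results/level_means.csv.

library(spineqmr)
dir.create("results", showWarnings = FALSE)

coh <- generate_cohort(cohort_spec(n_subjects = 80, seed = 20260505))
cov_tab <- unique(coh[c("subject_id", "age", "sex", "bmi")])
units <- assemble_units(coh[setdiff(names(coh), c("age", "sex", "bmi"))],
                        cov_tab)
inc <- apply_exclusions(units, n_enrolled = 84, n_complete_mri = 80)$included

uni_cep <- univariate_ols(inc$np_t1rho_ms, inc$cep_t2star_ms, "CEP T2*")
uni_bmff <- univariate_ols(inc$np_t1rho_ms, inc$vertebral_bmff_pct,
                           "Vertebral BMFF")
uni <- rbind(cbind(model = "NP T1rho ~ CEP T2*", uni_cep$coefficients),
             cbind(model = "NP T1rho ~ BMFF", uni_bmff$coefficients))
uni$term_key <- NULL
write.csv(uni, "results/univariate.csv", row.names = FALSE)
cat("Univariate associations with NP T1rho:\n")
print(uni, row.names = FALSE, digits = 3)

pf <- pfirrmann_model(inc$pfirrmann, inc$np_t1rho_ms)
cat(sprintf("\nProportional-odds Pfirrmann model: slope %.3f per ms, p = %.2g\n",
            pf$coefficients$estimate, pf$coefficients$p_value))
cat("(negative: lower NP T1rho at higher degenerative grade)\n")

m1 <- mixed_model(inc, "model1")
m2 <- mixed_model(inc, "model2")
for (m in list(m1, m2)) print(m)
w1 <- m1$coefficients; w1$term_key <- NULL
w2 <- m2$coefficients; w2$term_key <- NULL
write.csv(w1, "results/model1_coefficients.csv", row.names = FALSE)
write.csv(w2, "results/model2_coefficients.csv", row.names = FALSE)

lm_ <- level_means(m1)
write.csv(lm_, "results/level_means.csv", row.names = FALSE)
cat("\nAdjusted NP T1rho by spinal level:\n")
print(lm_, row.names = FALSE, digits = 4)
cat(sprintf("\nLevel difference %.1f ms = 2 x the level coefficient (%.2f).\n",
            lm_$mean[1] - lm_$mean[2],
            w1$estimate[w1$term == "Level"]))
cat("CEP T2* stays significant after covariate adjustment while BMFF does\n")
cat("not, matching the generative coefficients the cohort was drawn from.\n")
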