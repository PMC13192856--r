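#!/usr/bin/env Rscript
# Multivariate receptor-expression models: a 3-class orthogonalized PLSDA
# predicting trimester with repeated 5-fold CV and permutation testing, and
# an orthogonalized PLS regression on gestational age with Q2 and
# independent cohort-2 prediction.

library(placentaFcR)

dir.create("results", showWarnings = FALSE)
b1 <- generate_bundle(sim_config(seed = 1))
b2 <- generate_bundle(sim_config(seed = 501))
prof1 <- build_expression_profile(b1$areas$areas, b1$areas$meta)
prof2 <- build_expression_profile(b2$areas$areas, b2$areas$meta)
feats <- setdiff(names(prof1), c("patient_id", "gestational_age_weeks", "trimester"))
X1 <- as.matrix(prof1[feats]); X2 <- as.matrix(prof2[feats])

# trimester PLSDA
plsda <- orthogonalize(fit_plsda(X1, factor(prof1$trimester), n_components = 2))
perm <- permutation_test(X1, factor(prof1$trimester), rounds = 200, seed = 2)
cat(sprintf("trimester PLSDA: mean CV accuracy %.1f%% over 200 rounds, permutation p = %.2g\n",
            100 * perm$mean_statistic, perm$p_value))
vip <- sort(vip_scores(plsda), decreasing = TRUE)
cat("features with VIP > 1:\n")
print(round(vip[vip > 1], 2))

# gestational-age OPLSR
oplsr <- orthogonalize(fit_pls(X1, prof1$gestational_age_weeks, n_components = 2))
q2 <- q2_score(X1, prof1$gestational_age_weeks, seed = 2)
pred2 <- predict(oplsr, X2)[, 1]
r <- cor(pred2, prof2$gestational_age_weeks)
slope <- coef(lm(prof2$gestational_age_weeks ~ pred2))[2]
cat(sprintf("gestational-age OPLSR: Q2 = %.2f; cohort-2 prediction Pearson R = %.2f, slope = %.2f\n",
            q2, r, slope))

write.table(data.frame(feature = names(vip), vip = as.numeric(vip)),
            "results/plsda_vip.tsv", sep = "\t", row.names = FALSE, quote = FALSE)
write.table(data.frame(patient_id = prof2$patient_id,
                       predicted_ga = pred2,
                       actual_ga = prof2$gestational_age_weeks),
            "results/oplsr_cohort2_predictions.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
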