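#!/usr/bin/env Rscript
# Unsupervised clinical clustering: log/center/scale preprocessing, PCA,
# WSS-guided k-means on PC1-PC2, projection of cohort 2 into cohort 1's
# latent space, and the per-cluster transfer contrast.

library(placentaFcR)

dir.create("results", showWarnings = FALSE)
b1 <- generate_bundle(sim_config(seed = 1))
b2 <- generate_bundle(sim_config(seed = 501))

clin_feats <- function(tab) tab[, setdiff(names(tab), "gestational_age_weeks")]
model <- fit_latent_model(clin_feats(b1$clinical), k_max = 6, seed = 1)
cat(sprintf("PC1+PC2 capture %.0f%% of clinical variance; WSS elbow selects K = %d%s\n",
            100 * sum(model$explained_variance[1:2]), model$k,
            if (model$weak_elbow) " (weak elbow)" else ""))

proj <- project_cohort(model, clin_feats(b2$clinical))
assigned <- assign_clusters(proj[, 1:2, drop = FALSE], model)

write.table(data.frame(patient_id = rownames(model$scores),
                       model$scores[, 1:2], cluster = model$labels),
            "results/cluster_scores_cohort1.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
write.table(data.frame(patient_id = rownames(proj), proj[, 1:2],
                       cluster = assigned),
            "results/cluster_scores_cohort2.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

ari <- mclust::adjustedRandIndex(model$labels, b1$labels)
cat(sprintf("cluster recovery vs planted labels: ARI = %.3f\n", ari))

# transfer efficiency across fitted clusters (cohort 1)
tr <- cm_ratio(b1$serology$maternal, b1$serology$cord)
igg1 <- tr[tr$feature == "IgG1", ]
cl_of <- model$labels[match(igg1$patient_id, rownames(model$scores))]
med <- tapply(igg1$log10_cm, cl_of, median)
cat("median IgG1 log10 C:M by fitted cluster:\n"); print(round(med, 3))
kw <- kruskal.test(igg1$log10_cm, factor(cl_of))
cat(sprintf("Kruskal-Wallis across clusters: p = %.2g\n", kw$p.value))
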