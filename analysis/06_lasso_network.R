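#!/usr/bin/env Rscript
# Maternal-vs-cord glycoform discrimination: LASSO stability selection,
# a 2-class PLSDA on the stable feature set with permutation testing, and
# the Pearson co-correlate network around the selected features.

library(placentaFcR)

dir.create("results", showWarnings = FALSE)
b1 <- generate_bundle(sim_config(seed = 1))

gw <- b1$glycoforms
codes <- setdiff(names(gw), c("patient_id", "compartment", "subclass"))
wide <- reshape(gw, direction = "wide", idvar = c("patient_id", "compartment"),
                timevar = "subclass", v.names = codes)
X <- as.matrix(wide[, setdiff(names(wide), c("patient_id", "compartment"))])
labels <- factor(wide$compartment)

sel <- stability_select(X, labels, n_iterations = 200, seed = 4)
print(sel)
write.table(data.frame(feature = names(sel$frequency),
                       frequency = as.numeric(sel$frequency)),
            "results/lasso_frequencies.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

if (length(sel$selected) >= 1) {
  perm <- permutation_test(X[, sel$selected, drop = FALSE], labels,
                           rounds = 200, seed = 4)
  cat(sprintf("PLSDA on the %d stable features: mean CV accuracy %.1f%%, permutation p = %.2g\n",
              length(sel$selected), 100 * perm$mean_statistic, perm$p_value))
  net <- cocorrelate_network(X, sel$selected, alpha = 0.05)
  print(net)
  write_network(net, graphml = "results/cocorrelate.graphml",
                edgelist = "results/cocorrelate_edges.csv")
}
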