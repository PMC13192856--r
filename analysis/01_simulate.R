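#!/usr/bin/env Rscript
# Generate the two synthetic cohorts used throughout the analysis: clinical
# covariates with three planted clusters, dyadic IgG subclass serology with
# cluster-dependent transfer offsets, maternal/cord Fc glycoform
# compositions, and per-image Fc receptor area/density tables following
# cubic gestational trajectories. Writes the table families as TSV plus the
# planted ground truth as JSON.

library(placentaFcR)

out_dir <- "results/synthetic"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

cfg1 <- sim_config(seed = 1)
cfg2 <- sim_config(seed = 501)
b1 <- generate_bundle(cfg1)
b2 <- generate_bundle(cfg2)

wt <- function(df, name) write.table(df, file.path(out_dir, name),
                                     sep = "\t", row.names = FALSE, quote = FALSE)
wt(b1$clinical, "cohort1_clinical.tsv")
wt(b2$clinical, "cohort2_clinical.tsv")
wt(b1$serology$maternal, "cohort1_maternal_igg.tsv")
wt(b1$serology$cord, "cohort1_cord_igg.tsv")
wt(b1$glycoforms, "cohort1_glycoforms.tsv")
wt(b1$areas$areas, "cohort1_area_quantification.tsv")
wt(b2$areas$areas, "cohort2_area_quantification.tsv")

jsonlite::write_json(
  list(cohort1 = list(labels = b1$labels,
                      cm_offsets = cfg1$cm_offsets,
                      glycan_shift = as.list(cfg1$glycan_shift),
                      trajectory_coeffs = cfg1$trajectory_coeffs,
                      transfer_link = as.list(cfg1$transfer_link)),
       cohort2 = list(labels = b2$labels)),
  file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA)

v1 <- validate_tables(b1); v2 <- validate_tables(b2)
cat(sprintf("cohort 1: %d patients, %d images, %d dyads; %d validation violations\n",
            nrow(b1$clinical), nrow(b1$areas$areas),
            length(unique(b1$glycoforms$patient_id)), nrow(v1)))
cat(sprintf("cohort 2: %d patients; %d validation violations\n",
            nrow(b2$clinical), nrow(v2)))
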