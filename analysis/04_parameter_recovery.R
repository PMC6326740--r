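#!/usr/bin/env Rscript
# Step 4: parameter recovery and calibration checks for the synthetic
# generator. Runs the full pipeline on a 500-subject cohort with the
# default planted effect (population BGC-symptom r ~ -0.25) and on 200
# null cohorts (effect_beta = 0) to measure the pooled per-network
# uncorrected false-positive rate. Writes results/parameter_recovery.tsv.
# Takes a few minutes.

suppressPackageStartupMessages(library(bgcnet))

seed <- 2026L

cat("recovery run: 500 subjects, 4 networks x 15 regions, 600 frames\n")
cfg <- cohort_config_scaled(n_subjects = 500L, seed = seed)
rep <- run_pipeline(pipeline_config(cohort = cfg, tables = "network",
                                    seed = seed))
r_fpn <- rep$network_bgc$estimate[rep$network_bgc$unit == "Fronto-parietal"]
cat(sprintf("  recovered effect-network r = %.3f (planted ~ -0.25)\n",
            r_fpn))

cat("null runs: 200 seeded cohorts, 40 subjects each, effect_beta = 0\n")
hits <- 0L
total <- 0L
for (s in seq_len(200L)) {
  nseed <- seed + s
  ncfg <- cohort_config_scaled(n_subjects = 40L, effect_beta = 0,
                               seed = nseed)
  nrep <- run_pipeline(pipeline_config(cohort = ncfg, tables = "network",
                                       seed = nseed))
  hits <- hits + sum(nrep$network_bgc$p < 0.05)
  total <- total + nrow(nrep$network_bgc)
}
rate <- hits / total
cat(sprintf("  pooled uncorrected false-positive rate = %.3f (nominal 0.05)\n",
            rate))

out <- data.frame(
  quantity = c("recovered_effect_r", "null_false_positive_rate"),
  value = c(r_fpn, rate),
  n = c(500L, total)
)
dir.create("results", showWarnings = FALSE)
utils::write.table(out, "results/parameter_recovery.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat("wrote results/parameter_recovery.tsv\n")
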