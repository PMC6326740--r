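#!/usr/bin/env Rscript
# Step 3: recompute the inferential worked examples that depend only on
# printed inputs: two-tailed p values for the reported network-level
# correlation estimates at n = 96, the Fisher-z comparison of the
# default-mode BGC and within-network correlations, and the BH-FDR
# adjustment of the 12 network-level uncorrected p values. Writes
# results/worked_statistics.tsv.

suppressPackageStartupMessages(library(bgcnet))

n <- 96L
rows <- list(
  c("fpn_bgc_pearson",        -0.247),
  c("dmn_bgc_pearson",        -0.241),
  c("language_bgc_pearson",   -0.268),
  c("fpn_exclusion_pearson",  -0.226),
  c("fpn_bgc_spearman",       -0.227),
  c("dmn_bgc_spearman",       -0.220),
  c("language_bgc_spearman",  -0.285)
)
tab <- data.frame(
  statistic = vapply(rows, `[`, "", 1),
  estimate = as.numeric(vapply(rows, `[`, "", 2)),
  n = n
)
tab$p_two_tailed <- vapply(tab$estimate, correlation_pvalue, numeric(1),
                           n = n)

cc <- compare_correlations(-0.241, n, 0.143, n)
tab <- rbind(tab, data.frame(
  statistic = "dmn_bgc_vs_within_fisher_z",
  estimate = abs(cc$z), n = n, p_two_tailed = cc$p
))

p12 <- c(0.884, 0.850, 0.085, 0.164, 0.008, 0.018, 0.015, 0.340,
         0.284, 0.275, 0.261, 0.448)
tab <- rbind(tab, data.frame(
  statistic = "network_table_min_bh_fdr_p",
  estimate = NA_real_, n = 12L, p_two_tailed = min(bh_fdr(p12))
))

dir.create("results", showWarnings = FALSE)
utils::write.table(tab, "results/worked_statistics.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat("worked inferential statistics (n = 96 unless noted):\n")
print(tab, row.names = FALSE, digits = 3)
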