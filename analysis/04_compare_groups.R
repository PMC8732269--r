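#!/usr/bin/env Rscript
# Group-level comparisons of the per-cell metrics measured in
# 02_quantify_panels.R: Mann-Whitney for the two directional contrasts and
# one-way ANOVA + Dunnett against wildtype, plus the tabular/graphical
# report (scatter with mean +/- s.d. per group).

suppressPackageStartupMessages(library(cellsweep))
metrics <- read.csv("results/metrics.csv")
if (nrow(metrics) == 0) stop("run analysis/02_quantify_panels.R first")

mw_mdr <- compare_groups(metrics[metrics$group %in% c("wildtype", "dispersed"), ],
                         "mdr_normalized", "mannwhitney")
mw_asym <- compare_groups(metrics[metrics$group %in% c("wildtype", "clustered"), ],
                          "asymmetry", "mannwhitney")
dn_mdr <- compare_groups(metrics, "mdr_normalized", "anova_dunnett",
                         reference = "wildtype")
dn_asym <- compare_groups(metrics, "asymmetry", "anova_dunnett",
                          reference = "wildtype")
comparisons <- rbind(mw_mdr, mw_asym, dn_mdr, dn_asym)

message("group means +/- s.d.:")
gs <- group_summary(metrics)
for (i in seq_len(nrow(gs))) {
  message(sprintf("  %-10s n=%d  MDR %5.1f +/- %4.1f %%   asymmetry %5.3f +/- %5.3f",
                  gs$group[i], gs$n[i], gs$mdr_normalized_mean[i],
                  gs$mdr_normalized_sd[i], gs$asymmetry_mean[i], gs$asymmetry_sd[i]))
}
message(sprintf("Mann-Whitney dispersed vs wildtype on MDR:        P = %.3g",
                mw_mdr$p_value))
message(sprintf("Mann-Whitney clustered vs wildtype on asymmetry:  P = %.3g",
                mw_asym$p_value))

files <- render_report(metrics, comparisons, "results/report", plots = TRUE)
message("report written: ", paste(basename(files), collapse = ", "))
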