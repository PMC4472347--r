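#!/usr/bin/env Rscript
# Stage 2: benign-vs-cancer diagnostic accuracy of the five methylation
# markers -- empirical ROC AUC, Mann-Whitney separation, and
# sensitivity/specificity/PPV/NPV at the 1% and 2% positivity cutoffs.

suppressPackageStartupMessages(library(methstrat))

benign <- read_cohort("results/cohorts/BPH.csv")

for (cohort in c("PCa1", "PCa2")) {
  cancer <- read_cohort(sprintf("results/cohorts/%s.csv", cohort))
  rep <- diagnostic_summary(benign, cancer, cutoffs = c(1, 2))
  write.csv(rep, sprintf("results/diagnostics_%s.csv", cohort),
            row.names = FALSE)
  cat(sprintf("\n%s vs benign:\n", cohort))
  at2 <- rep[rep$cutoff == 2, ]
  for (i in seq_len(nrow(at2)))
    cat(sprintf("  %-6s AUC = %.2f  sens = %.2f  spec = %.2f (2%% cutoff)\n",
                at2$gene[i], at2$auc[i], at2$sensitivity[i],
                at2$specificity[i]))
  best <- at2[which.max(at2$auc), ]
  cat(sprintf("  best classifier: %s (AUC %.2f)\n", best$gene, best$auc))
}
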