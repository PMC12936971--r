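#!/usr/bin/env Rscript
# Stage 3: warped Bayesian linear regression normative models of each nodal
# hub metric on age and sex (fit on controls), per-subject deviation
# z-scores, extreme-deviation maps (|z| >= 2) with group and spatial
# permutation inference, FDR control, and effect sizes.

source(file.path("analysis", "00_config.R"))

res <- run_stages(c("simulate", "msn", "topology", "normative", "deviations"))
st <- res$state

ctrl <- st$sim$cohort$group == "control"
z <- st$devs$z
cat(sprintf("control extreme-deviation rate: %.2f%% (Gaussian reference %.2f%%)\n",
            100 * mean(abs(z[ctrl, , ]) >= 2), 100 * 2 * pnorm(-2)))
cat(sprintf("case extreme-deviation rate:    %.2f%%\n",
            100 * mean(abs(z[!ctrl, , ]) >= 2)))
cat(sprintf("site-prediction balanced accuracy: %.3f (chance %.3f)\n",
            st$site_acc, 1 / length(unique(st$sim$cohort$site))))

burden <- st$burden
for (i in seq_len(nrow(burden)))
  cat(sprintf("%s: %.2f (%.2f) vs %.2f (%.2f) extreme nodes/subject; t = %.2f, d = %.2f, p = %.3g\n",
              burden$metric[i], burden$mean_case[i], burden$sd_case[i],
              burden$mean_control[i], burden$sd_control[i], burden$t[i],
              burden$cohen_d[i], burden$p[i]))

tab <- st$diff_table
sig <- tab[tab$q < 0.05 & tab$p_spin < 0.05, ]
cat(sprintf("%d node-metric case-control differences survive FDR and spin tests\n",
            nrow(sig)))
cat("maps written under results/workspace/deviations/\n")
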