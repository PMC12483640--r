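#!/usr/bin/env Rscript
# Global sensitivity of bone volume fraction and damage at 10 weeks to all
# 20 model and loading parameters (plus an inert dummy): Latin-hypercube
# PRCC and Saltelli/Sobol indices.

suppressPackageStartupMessages(library(equibone))
dir.create("results", showWarnings = FALSE)
seed <- 1

cat("== PRCC (n = 1000 Latin-hypercube samples, outputs at 70 days) ==\n")
pr <- prcc_analysis(n = 1000, seed = seed)
est <- pr$estimates
utils::write.csv(est, "results/sensitivity_prcc.csv", row.names = FALSE)
for (out in c("fBM", "D")) {
  sub <- est[est$output == out, ]
  sub <- sub[order(-abs(sub$prcc)), ][1:6, ]
  cat(sprintf("  %s: strongest influences: %s\n", out,
              paste(sprintf("%s (%+.2f)", sub$parameter, sub$prcc),
                    collapse = ", ")))
}
cat(sprintf("  dummy PRCC: fBM %+.3f, D %+.3f (noise floor)\n",
            est$prcc[est$output == "fBM" & est$parameter == "dummy"],
            est$prcc[est$output == "D" & est$parameter == "dummy"]))

cat("\n== Sobol indices (Saltelli base 512, damage at 70 days) ==\n")
so <- sobol_indices(n_base = 512, seed = seed, n_boot = 100, output = "D")
utils::write.csv(so$first, "results/sensitivity_sobol_first.csv",
                 row.names = FALSE)
utils::write.csv(so$total, "results/sensitivity_sobol_total.csv",
                 row.names = FALSE)
utils::write.csv(so$second, "results/sensitivity_sobol_second.csv",
                 row.names = FALSE)
f <- so$first[order(-so$first$estimate), ][1:4, ]
cat(sprintf("  leading first-order indices: %s\n",
            paste(sprintf("%s (%.3f)", f$parameter, f$estimate),
                  collapse = ", ")))
vn_pairs <- so$second[so$second$parameter_i == "vn" |
                        so$second$parameter_j == "vn", ]
top <- vn_pairs[which.max(vn_pairs$estimate), ]
cat(sprintf("  largest second-order index among pairs with vn: (%s, %s) = %.3f\n",
            top$parameter_i, top$parameter_j, top$estimate))
cat("  -> joint stress dominates; stress and daily cycles interact on damage\n")

write_manifest("results/sensitivity_manifest.json", seed = seed,
               n_prcc = pr$n, sobol_base = so$n_base,
               evaluation_time_days = 70,
               initial_state = list(fBM = 0.7, D = 0))
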