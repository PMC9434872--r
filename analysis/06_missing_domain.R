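#!/usr/bin/env Rscript
# Incomplete-domain handling on synth-pd (3168-candidate space, 1536
# present): zero-filling the missing combinations versus restricting the
# search space to the candidates that exist. 50 paired replicates per
# acquisition and mode.

suppressPackageStartupMessages(library(reactbo))
dir.create("results", showWarnings = FALSE)

pd <- benchmark_surface("synth-pd")
acqs <- c("ei", "ts", "random")

rows <- list()
for (a in acqs) {
  message("missing-domain experiment, ", a, " ...")
  ex <- missing_domain_experiment(pd, pd$partial, pd$allowed,
                                  run_config(a, q = 5, budget = 50),
                                  n_runs = 50, seed_base = 1)
  for (m in c("zero_fill", "restricted")) {
    s <- ex[[m]]
    rows[[paste(a, m)]] <- data.frame(acquisition = a, mode = m,
                                      mean_best = s$mean_best, sem = s$sem,
                                      q1 = s$q1, median = s$median,
                                      q3 = s$q3, n_global = s$n_global)
  }
  cat(sprintf("%s: restricted - zero_fill = %.3f points\n", a, ex$mean_diff))
}
tab <- do.call(rbind, rows)
print(tab, row.names = FALSE)
write.csv(tab, "results/missing_domain.csv", row.names = FALSE)
cat("\nA positive difference means telling the optimizer the allowed domain",
    "up front beats coding missing combinations as zero yield.\n")
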