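#!/usr/bin/env Rscript
# Does the initial batch matter? Uniform initialization vs initialization
# drawn only from the bottom decile of the yield table (an adversarial
# start), EI, batch 5, budget 50, 50 replicates each on synth-suzuki.

suppressPackageStartupMessages(library(reactbo))
dir.create("results", showWarnings = FALSE)

surf <- benchmark_surface("synth-suzuki")
modes <- c("uniform", "bottom_decile")
summaries <- lapply(modes, function(m) {
  message("replicating init = ", m, " ...")
  replicate_runs(surf$space, surf$objective,
                 run_config("ei", q = 5, budget = 50, init = m),
                 n_runs = 50, seed_base = 1)
})
names(summaries) <- modes

tab <- do.call(rbind, lapply(modes, function(m) {
  s <- summaries[[m]]
  data.frame(init = m, mean_best = s$mean_best, sem = s$sem, q1 = s$q1,
             median = s$median, q3 = s$q3, n_global = s$n_global)
}))
print(tab, row.names = FALSE)
write.csv(tab, "results/initialization_strategies.csv", row.names = FALSE)

w <- welch_t_test(summaries$uniform$best, summaries$bottom_decile$best)
cat(sprintf("\nmean difference %.3f points (Welch p = %.3g)\n",
            summaries$uniform$mean_best - summaries$bottom_decile$mean_best,
            w$p))
cat("Identical or near-identical quartiles for the bottom-decile start",
    "indicate convergence to the same local maximum across seeds.\n")
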