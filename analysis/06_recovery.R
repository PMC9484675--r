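#!/usr/bin/env Rscript
# Parameter recovery at the generative values: 200 replicate populations
# of 273 subjects, fixed-links variances and the standardized
# timing-to-g coefficient re-estimated in each.

suppressMessages(library(trpsupp))
dir.create("results", showWarnings = FALSE)

t0 <- Sys.time()
recov <- recovery_experiment(population_spec(n_subjects = 273),
                             n_reps = 200, seed = 42)
cat(sprintf("200 replicates in %.1f s (nonconvergence %.1f%%)\n",
            as.numeric(Sys.time() - t0, units = "secs"),
            100 * attr(recov, "nonconvergence_rate")))
print(recov, digits = 3)
write.csv(recov, "results/recovery.csv", row.names = FALSE)
ok <- abs(recov$bias) < 2 * recov$mc_se_mean
cat(ifelse(all(ok), "\nAll parameters recovered without detectable bias.\n",
           "\nWARNING: bias detected beyond 2 Monte-Carlo SEs.\n"))
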