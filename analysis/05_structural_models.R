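#!/usr/bin/env Rscript
# Structural models: g regressed on the timing factor, g regressed on
# the two suppression components, the timing-suppression correlation
# model, and the combined model in which all three predictors compete.

suppressMessages(library(trpsupp))
dat <- read_measures_csv("results/measures.csv")
n <- nrow(dat)

z <- function(x) as.numeric(scale(x))
fd <- data.frame(dl_empty = z(dat$dl_empty), dl_filled = z(dat$dl_filled),
                 tg_inverted = z(dat$tg_inverted),
                 rp_threshold = z(dat$rp_threshold),
                 mdd_1 = dat$mdd_1, mdd_2 = dat$mdd_2, mdd_3 = dat$mdd_3,
                 mdd_4 = dat$mdd_4,
                 bis_capacity = z(dat$bis_capacity),
                 bis_speed = z(dat$bis_speed),
                 bis_memory = z(dat$bis_memory))
trp <- c("dl_empty", "dl_filled", "tg_inverted", "rp_threshold")
mdd <- paste0("mdd_", 1:4)
bis <- c("bis_capacity", "bis_speed", "bis_memory")

fit_trp_g <- latent_regression(build_model("trp_g"), cov(fd[c(trp, bis)]), n)
cat(sprintf("timing -> g: beta = %.3f, R2 = %.2f, chi2(%d) = %.2f, CFI %.3f\n",
            fit_trp_g$standardized$beta["g", "trp"], fit_trp_g$r2["g"],
            fit_trp_g$df, fit_trp_g$T, fit_trp_g$cfi))

fit_ss_g <- latent_regression(build_model("ss_g"), cov(fd[c(mdd, bis)]), n)
cat(sprintf("suppression -> g: beta_ssc = %.3f, beta_ssi = %.3f, R2 = %.2f\n",
            fit_ss_g$standardized$beta["g", "ssc"],
            fit_ss_g$standardized$beta["g", "ssi"], fit_ss_g$r2["g"]))

fit_corr <- fit_ml(build_model("trp_ss_corr"), cov(fd[c(trp, mdd)]), n)
cat(sprintf("timing-suppression correlations: r(trp,ssc) = %.3f, r(trp,ssi) = %.3f\n",
            fit_corr$standardized$psi["trp", "ssc"],
            fit_corr$standardized$psi["trp", "ssi"]))

fit_comb <- latent_regression(build_model("combined"),
                              cov(fd[c(trp, mdd, bis)]), n)
b <- fit_comb$standardized$beta["g", ]
cat(sprintf("combined model: beta_trp = %.3f, beta_ssc = %.3f, beta_ssi = %.3f, R2 = %.2f\n",
            b["trp"], b["ssc"], b["ssi"], fit_comb$r2["g"]))
cat(sprintf("  chi2(%d) = %.2f, CFI %.3f, RMSEA %.3f, SRMR %.3f\n",
            fit_comb$df, fit_comb$T, fit_comb$cfi, fit_comb$rmsea,
            fit_comb$srmr))

write_fit_json(fit_trp_g, "results/fit_trp_g.json")
write_fit_json(fit_ss_g, "results/fit_ss_g.json")
write_fit_json(fit_corr, "results/fit_trp_ss_corr.json")
write_fit_json(fit_comb, "results/fit_combined.json")
cat("\nThe suppression paths shrink toward zero in the combined model while\n")
cat("the timing path persists: the suppression-intelligence association is\n")
cat("carried by the shared timing variance in this generative regime.\n")
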