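#!/usr/bin/env Rscript
# Parameter-recovery study: how reliably does the simulate-and-fit pipeline
# return the generating parameters at the study noise level? 10 synthetic
# experiments per condition; per-parameter bias, RMSE and the fraction
# recovered within max(2 x reported SE, 15%) relative.

library(atpasekin)

for (cond in c("detergent", "nanodiscs", "proteoliposomes")) {
  out <- file.path("results/recovery", cond)
  rep <- run_recover(run_config("recover", out, condition = cond,
                                n_sims = 10, seed = 100, force = TRUE))
  cat(sprintf("\n== %s ==\n", cond))
  print(rep)
}
cat("\nNote: for nanodiscs, alpha and beta recover with wide scatter -- the\n")
cat("activator saturation (alpha*K_S ~ 97 mM) lies far above the top GSSG\n")
cat("concentration (20 mM), so their curvature is weakly constrained.\n")
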