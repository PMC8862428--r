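#!/usr/bin/env Rscript
# Per-GSSG-level Michaelis-Menten fits of the simulated assays: for every
# activator concentration, kcat and Km for MgATP hydrolysis with asymptotic
# standard errors. Shows the concentration-dependent stimulation of kcat
# before any global modelling. Requires 01_simulate_assays.R output.

library(atpasekin)

dir.create("results/tables", recursive = TRUE, showWarnings = FALSE)

for (cond in c("detergent", "nanodiscs", "proteoliposomes")) {
  rates <- file.path("results/data", sprintf("rates_%s.csv", cond))
  res <- run_fit(run_config("fit-mm", "results/tables", condition = cond,
                            input = rates, force = TRUE))
  file.rename(file.path("results/tables", "fit_michaelis_per_gssg.csv"),
              file.path("results/tables",
                        sprintf("michaelis_per_gssg_%s.csv", cond)))
  tbl <- res$michaelis
  cat(sprintf("\n%s: basal kcat = %.1f min^-1; at 20 mM GSSG kcat = %.1f (x%.0f)\n",
              cond, tbl$kcat[tbl$gssg_mM == 0], tbl$kcat[tbl$gssg_mM == 20],
              tbl$kcat[tbl$gssg_mM == 20] / tbl$kcat[tbl$gssg_mM == 0]))
  print(tbl, digits = 3)
}
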