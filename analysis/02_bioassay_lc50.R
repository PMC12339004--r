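#!/usr/bin/env Rscript
# Probit dose-response fits: LC50 with 95% CI per population, bimodal
# susceptible/resistant classification, and the fold-resistance contrast.

suppressPackageStartupMessages(library(mitesweep))
assays <- read.csv("results/bioassays.csv")

fits <- do.call(rbind, lapply(split(assays, assays$population), function(d) {
  f <- fit_probit(d[, c("conc_mg_L", "n", "dead")])
  data.frame(population = d$population[1], lc50 = f$lc50,
             ci_low = f$lc50_ci[1], ci_high = f$lc50_ci[2],
             slope = f$beta, status = f$status,
             class = classify_population(
               if (is.na(f$lc50)) f$bound else f$lc50,
               censored_above = f$status == "censored_above" && is.na(f$lc50)))
}))
rownames(fits) <- NULL
write.table(fits, "results/lc50_fits.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)
print(fits, digits = 4)
ok <- !is.na(fits$lc50)
if (sum(ok) == 2)
  message("fold resistance: ",
          fold_change(max(fits$lc50[ok]), min(fits$lc50[ok]), rounded = TRUE),
          "-fold")
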