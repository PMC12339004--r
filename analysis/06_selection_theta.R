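#!/usr/bin/env Rscript
# Selection inference: per-allele and joint selection coefficients from
# simulated allele-frequency trajectories, the recurrent-mutation Theta and
# implied Ne, the survival-association metrics, and the isolation-by-distance
# Mantel test.

suppressPackageStartupMessages(library(mitesweep))
set.seed(20240806)

## allele-frequency trajectories for three resistance alleles
years <- 0:5
rows <- do.call(rbind, lapply(1:3, function(a) {
  do.call(rbind, lapply(1:12, function(i) {
    cfg <- sim_config(N = 1e5, s_true = 0.035, h = 0.5,
                      generations = max(years) * 20, p0 = 0.02, n_sites = 1)
    f <- simulate_wf(cfg)$freq[years * 20 + 1, 1]
    k <- rbinom(length(f), 50, f)
    data.frame(allele = paste0("allele", a), population = paste0("pop", i),
               year = 2017 + years, freq = k / 50, n_chromosomes = 50)
  }))
}))
fit <- fit_selection(rows, joint = TRUE, gens_per_year = 20)
write.table(fit, "results/selection_fits.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)
joint <- fit[fit$allele == ".joint", ]
message("joint selective strength: ", round(joint$s, 3), " per year (Z = ",
        round(joint$z, 2), ", p = ", signif(joint$p, 2), "); ",
        round(joint$s_per_generation, 4), " per generation")

## recurrent-mutation rate: 2.7 mutations per population over 7 years
est <- recurrent_mutation_estimate(2.7, 7, 20, 2.8e-9, 3)
print(est)
jsonlite::write_json(unclass(est), "results/theta_ne.json",
                     auto_unbox = TRUE, digits = NA)

## survival association across 25 populations
n <- 25
f <- runif(n, 0, 1)
tab <- data.frame(survival = pmin(pmax(f + rnorm(n, 0, 0.1), 0), 1),
                  predominant_freq = pmin(pmax(f * runif(n, 0.5, 0.9), 0), 1),
                  any_carrier_freq = f,
                  homozygote_freq = pmin(pmax(f^2 + rnorm(n, 0, 0.1), 0), 1))
assoc <- survival_association(tab)
write.table(assoc$univariate, "results/survival_association.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
print(assoc$univariate, digits = 3)

## isolation by distance of resistance allele frequencies
coords <- data.frame(lon = runif(15, 100, 122), lat = runif(15, 20, 45))
freqs <- matrix(runif(15 * 3, 0, 0.8), 15,
                dimnames = list(paste0("pop", 1:15), NULL))
ibd <- resistance_fst_ibd(freqs, coords, permutations = 999, seed = 7)
message("Mantel r = ", round(ibd$mantel_r, 3), ", p = ", ibd$p_value,
        " (no isolation by distance expected for shuffled frequencies)")
jsonlite::write_json(list(mantel_r = ibd$mantel_r, p_value = ibd$p_value),
                     "results/ibd_mantel.json", auto_unbox = TRUE, digits = NA)
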