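#!/usr/bin/env Rscript
# Generate the synthetic study inputs: a three-population pooled-sequencing
# panel (one resistant population carrying a selective sweep at the focal
# locus, two susceptible references), dose-mortality bioassay tables, and
# Sanger-style genotypes for the haplotype work.  Everything downstream
# (02-06) reads from results/.

suppressPackageStartupMessages(library(mitesweep))
dir.create("results", showWarnings = FALSE)
set.seed(20240801)

## pooled panel: sweep at the "sdhB-like" locus in the focal population
genome <- simulate_genome(n_pops = 3, swept = c(TRUE, FALSE, FALSE),
                          n_snps = 2000, genome_length = 5e5, N = 200,
                          generations = 40, s_true = 0.5)
pools <- pool_genome(genome, pool_size = 100, depth = 80,
                     pool_names = c("resistant1", "susceptibleA", "susceptibleB"))
write_sync(pools, "results/pools.sync")
message("sync: 3 pools, ", nrow(pools$sites), " sites, sweep at ",
        genome$sweep_pos, " (final freq ",
        round(genome$sweep_final[1], 3), ")")

## bioassays: one susceptible and one resistant population, plus a control
## row; concentrations pre-estimated around each population's expected LC50
sus <- generate_bioassay(6.7, 2.1, signif(6.7 * 10^seq(-1.25, 1.25, by = 0.5), 2),
                         n_per_dose = 30, control_mortality = 0.02, seed = 11)
res <- generate_bioassay(3000, 1.8, signif(3000 * 10^seq(-1.25, 1.25, by = 0.5), 2),
                         n_per_dose = 30, control_mortality = 0.02, seed = 12)
sus$population <- "fieldS"; res$population <- "fieldR"
assays <- rbind(sus, res)[, c("population", "conc_mg_L", "n", "dead")]
write.csv(assays, "results/bioassays.csv", row.names = FALSE)
message("bioassays: ", nrow(assays), " rows, true LC50s 6.7 and 3000 mg/L")

## Sanger genotypes: centre-dominant haplotype pool, resistant leaf at SNP 3
haps <- c("AAAAA", "TAAAA", "ATAAA", "AATAA")
freqs <- c(0.70, 0.12, 0.10, 0.08)
geno <- generate_sanger_genotypes(haps, freqs, 400, population = "fieldR",
                                  year = 2024, seed = 13)
write.csv(geno, "results/sanger_genotypes.csv", row.names = FALSE)
message("genotypes: 400 individuals over ", length(haps), " true haplotypes")

truth <- list(sweep_pos = genome$sweep_pos,
              sweep_final_freq = genome$sweep_final[1],
              s_true = 0.5, lc50_true = c(fieldS = 6.7, fieldR = 3000),
              haplotypes = haps, haplotype_freqs = freqs)
jsonlite::write_json(truth, "results/ground_truth.json", auto_unbox = TRUE,
                     digits = NA)
message("ground truth written to results/ground_truth.json")
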