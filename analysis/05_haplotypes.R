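#!/usr/bin/env Rscript
# Haplotype work: resolve haplotypes from the Sanger genotypes under the
# one-heterozygote rule, build the minimum-spanning network, classify
# ancestral versus derived haplotypes, enumerate single-crossover
# explanations of each derived haplotype, and put the recombination rate
# argument in numbers.

suppressPackageStartupMessages(library(mitesweep))

geno <- read.csv("results/sanger_genotypes.csv")
rs <- resolve_haplotypes(geno)
write.table(rs$haplotypes, "results/haplotypes.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
message(nrow(rs$haplotypes), " haplotypes from ",
        length(unique(rs$carriers$individual)), " resolved individuals (",
        nrow(rs$excluded), " excluded: ",
        paste(names(table(rs$excluded$reason)),
              table(rs$excluded$reason), collapse = ", "), ")")

net <- build_network(rs)
edges <- igraph::as_data_frame(net, what = "edges")
write.table(edges, "results/haplotype_network_edges.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cl <- classify_ancestral(net)
write.table(cl, "results/haplotype_classification.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
message("ancestral: ", paste(cl$id[cl$ancestral], collapse = ", "),
        "; every derived haplotype at distance ",
        paste(unique(cl$dist_to_ancestral[!cl$ancestral]), collapse = "/"),
        " from its nearest ancestral node")

## single-crossover explanations for each derived haplotype
pos <- c(5, 18, 36, 44, 59)   # bp positions of the 5 panel SNPs
pool <- stats::setNames(rs$haplotypes$hap, rs$haplotypes$id)
recomb <- do.call(rbind, lapply(cl$id[!cl$ancestral], function(id) {
  out <- enumerate_recombinants(pool[[id]], pool[names(pool) != id], pos)
  if (nrow(out)) cbind(target = id, out) else NULL
}))
if (!is.null(recomb)) {
  write.table(recomb, "results/recombinant_explanations.tsv", sep = "\t",
              row.names = FALSE, quote = FALSE)
  message(nrow(recomb), " candidate single-crossover explanations enumerated")
} else message("no derived haplotype is explicable by a single crossover")

## how often would recombination actually produce one, per generation?
er <- expected_recombinants(r = 1e-7, d = max(pos) - min(pos), c_ploidy = 3,
                            Ne = 2.29e6)
message("rho = 2 c Ne r d = ", signif(er$rho, 3),
        " expected crossovers per generation across ", max(pos) - min(pos),
        " bp (", signif(er$individuals_per_event, 3),
        " generations per event)")
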