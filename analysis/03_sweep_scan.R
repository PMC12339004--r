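#!/usr/bin/env Rscript
# Pool-seq sweep scan: subsample every pool to uniform depth 50, compute
# windowed diversity (pi, Watterson's theta, Tajima's D), pairwise FST,
# PBS and PBE with the resistant population as focal, call top-1% outlier
# windows, and summarize the evidence at the focal gene.

suppressPackageStartupMessages(library(mitesweep))
set.seed(20240803)

sync <- read_sync("results/pools.sync",
                  pool_names = c("resistant1", "susceptibleA", "susceptibleB"))
truth <- jsonlite::read_json("results/ground_truth.json")
subs <- lapply(sync$counts, subsample_pool, b = 50)

scan <- pbe_scan(sync$sites$pos, subs$resistant1, subs$susceptibleA,
                 subs$susceptibleB, b = 50, window = 5000, quantile = 0.01)
write.table(scan, "results/pbe_scan.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)

genes <- data.frame(gene = "sdh_locus", chrom = "chr1",
                    start = truth$sweep_pos - 500, end = truth$sweep_pos + 500)
report <- sweep_report(scan, genes, flank = 25000)
write.table(report, "results/sweep_report.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)

n_out <- sum(scan$outlier, na.rm = TRUE)
top <- scan[which.max(scan$pbe), ]
message(nrow(scan), " windows scanned; ", n_out, " outlier window(s); ",
        "max PBE = ", round(top$pbe, 3), " at ", top$start, "-", top$end,
        " (true sweep at ", truth$sweep_pos, ")")
message("signal at focal gene: ", report$signal,
        "; pi gene vs flank: ", signif(report$pi_gene, 3), " vs ",
        signif(report$pi_flank, 3),
        "; Tajima's D gene vs flank: ", signif(report$d_gene, 3), " vs ",
        signif(report$d_flank, 3))
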