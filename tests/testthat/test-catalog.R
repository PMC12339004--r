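test_that("the target-site catalog carries the published substitution inventory", {
  cat_ <- load_catalog()
  expect_equal(length(unique(cat_$label)), 15L)
  b <- cat_[cat_$gene == "sdhB", ]
  d <- cat_[cat_$gene == "sdhD", ]
  expect_equal(length(unique(b$label)), 6L)
  expect_equal(length(unique(b$residue)), 5L)
  expect_equal(length(unique(d$label)), 9L)
  expect_equal(length(unique(d$residue)), 3L)
  expect_equal(length(unique(d$label[d$residue == 119])), 5L)
  # D116E is the one entry with two alternative wild codons
  e <- cat_[cat_$label == "D116E", ]
  expect_equal(sort(e$wild_codon), c("GAC", "GAT"))
  expect_true(all(e$mutant_codon == "GAA"))
  # every row is a single-nucleotide codon change
  ndiff <- mapply(function(a, b)
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]),
    cat_$wild_codon, cat_$mutant_codon)
  expect_true(all(ndiff == 1L))
})

# a synthetic coding sequence with specified codons planted at specified residues
synth_cds <- function(n_codons, planted, seed = 1) {
  set.seed(seed)
  safe <- c("GCT", "GGT", "CTG", "AAA", "GAA", "TTC", "ACT", "CCG")
  codons <- sample(safe, n_codons, replace = TRUE)
  codons[1] <- "ATG"
  for (i in seq_along(planted)) codons[as.integer(names(planted)[i])] <- planted[i]
  paste(codons, collapse = "")
}

test_that("SNPs inside the gene model are annotated to the published labels", {
  cds <- synth_cds(300, c(`260` = "ATC"))
  gm <- gene_model("sdhB", "chr1", cds_start = 1001, cds_end = 1000 + 900,
                   strand = "+", cds_seq = cds)
  # first codon position of residue 260: ATC -> GTC is I260V
  pos1 <- 1000 + (260 - 1) * 3 + 1
  ann <- annotate_snp(pos1, ref = "A", alt = "G", gm)
  expect_equal(ann$label, "I260V")
  expect_equal(ann$effect, "missense")
  expect_equal(ann$residue, 260L)
  # third-position ATC -> ATT is synonymous
  syn <- annotate_snp(pos1 + 2, ref = "C", alt = "T", gm)
  expect_equal(syn$effect, "synonymous")
  expect_equal(syn$wild_aa, "I")
  # outside the CDS
  expect_equal(annotate_snp(50, "A", "G", gm)$effect, "non-coding")
  # reference mismatch is an error naming the offset
  expect_error(annotate_snp(pos1, ref = "T", alt = "G", gm), "mismatch")
})

test_that("reverse-strand annotation matches the forward-strand call", {
  set.seed(61)
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  for (i in 1:20) {
    cds <- synth_cds(40, character(0), seed = i)
    fwd <- gene_model("g", "chr1", 101, 100 + 120, "+", cds)
    rev <- gene_model("g", "chr1", 101, 100 + 120, "-", cds)
    off <- sample(120, 1)
    ref_f <- substr(cds, off, off)
    alt_f <- sample(setdiff(c("A", "C", "G", "T"), ref_f), 1)
    a_f <- annotate_snp(100 + off, ref_f, alt_f, fwd)
    # same biological change seen from the minus strand: genomic position
    # mirrors within the CDS and bases complement
    a_r <- annotate_snp(100 + (120 - off + 1), comp[ref_f], comp[alt_f], rev)
    expect_equal(a_r$label, a_f$label)
    expect_equal(a_r$effect, a_f$effect)
  }
})

test_that("annotation round-trips every catalog entry", {
  cat_ <- load_catalog()
  for (i in seq_len(nrow(cat_))) {
    row <- cat_[i, ]
    planted <- stats::setNames(row$wild_codon, row$residue)
    cds <- synth_cds(row$residue + 10, planted, seed = i)
    gm <- gene_model(row$gene, "chr1", 1, nchar(cds), "+", cds)
    diffpos <- which(strsplit(row$wild_codon, "")[[1]] !=
                       strsplit(row$mutant_codon, "")[[1]])
    gpos <- (row$residue - 1) * 3 + diffpos
    ann <- annotate_snp(gpos, substr(row$wild_codon, diffpos, diffpos),
                        substr(row$mutant_codon, diffpos, diffpos), gm)
    expect_equal(ann$label, row$label)
    expect_equal(ann$mutant_codon, row$mutant_codon)
  }
})

test_that("codon neighbourhoods expose the saturation of R119", {
  acc <- accessible_substitutions("CGT")
  expect_equal(nrow(acc), 9L)
  pos2 <- acc[acc$position == 2, ]
  expect_setequal(pos2$mutant_aa, c("H", "P", "L"))
  pos1 <- acc[acc$position == 1, ]
  expect_setequal(pos1$mutant_aa, c("C", "G", "S"))
  catalog_aas <- unique(load_catalog()$mutant_aa[load_catalog()$residue == 119])
  expect_true(all(pos2$mutant_aa %in% catalog_aas))       # position 2 saturated
  expect_setequal(intersect(pos1$mutant_aa, catalog_aas), c("C", "G"))
  # stop codons are flagged
  w <- accessible_substitutions("TGG")
  expect_equal(sum(w$is_stop), 2L)
  expect_setequal(w$mutant_codon[w$is_stop], c("TGA", "TAG"))
  expect_error(accessible_substitutions("AXT"), "invalid codon")
})

test_that("per-population mutation summaries average by collection year", {
  zero <- data.frame(population = rep(c("p1", "p2"), each = 2), year = 2020,
                     mutation = c("m1", "m2"), frequency = 0)
  expect_equal(population_mutation_summary(zero)$per_year$mean_mutations, 0)
  # populations carrying {1, 1, 2, 2, 3} mutations -> mean 1.8
  pops <- paste0("p", 1:5)
  nmut <- c(1, 1, 2, 2, 3)
  tab <- do.call(rbind, lapply(1:5, function(i)
    data.frame(population = pops[i], year = 2024, mutation = paste0("m", 1:3),
               frequency = c(rep(0.2, nmut[i]), rep(0, 3 - nmut[i])))))
  s <- population_mutation_summary(tab)
  expect_equal(s$per_year$mean_mutations, 1.8)
  expect_equal(s$per_year$n_populations, 5L)
  # round trip: presence drawn binomially around a true mean of 2.7/5 per mutation
  set.seed(67)
  n_pop <- 40; n_mut <- 5; pr <- 2.7 / n_mut
  tab2 <- expand.grid(population = paste0("q", 1:n_pop),
                      mutation = paste0("m", 1:n_mut))
  tab2$year <- 2024
  tab2$frequency <- stats::rbinom(nrow(tab2), 1, pr) * stats::runif(nrow(tab2), 0.05, 0.5)
  s2 <- population_mutation_summary(tab2)
  se <- sqrt(n_mut * pr * (1 - pr) / n_pop)
  expect_lt(abs(s2$per_year$mean_mutations - 2.7), 3 * se)
})
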