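mk_geno <- function(..., pop = "p1", year = 2024) {
  rows <- list(...)
  g <- do.call(rbind, rows)
  colnames(g) <- paste0("snp", seq_len(ncol(g)))
  data.frame(individual = paste0("i", seq_len(nrow(g))), population = pop,
             year = year, g, stringsAsFactors = FALSE)
}

test_that("the one-heterozygote rule resolves, splits and excludes correctly", {
  geno <- mk_geno(c("A/A", "C/C", "T/T"),        # homozygous: 2 copies of ACT
                  c("A/A", "C/G", "T/T"),        # 1 het: ACT + AGT
                  c("A/T", "C/G", "T/T"),        # 2 het: excluded
                  c("A/A", NA,    "T/T"))        # missing: excluded
  rs <- resolve_haplotypes(geno)
  expect_equal(sum(rs$haplotypes$count), 4L)      # 2 retained individuals
  expect_equal(rs$haplotypes$count[rs$haplotypes$hap == "ACT"], 3L)
  expect_equal(rs$haplotypes$count[rs$haplotypes$hap == "AGT"], 1L)
  expect_setequal(rs$excluded$reason, c("phase-ambiguous", "missing-data"))
  bad <- mk_geno(c("A/A", "C/C", "X/X"))
  expect_error(resolve_haplotypes(bad), "alphabet")
})

test_that("copy counts are conserved over random genotype tables", {
  set.seed(71)
  for (i in 1:20) {
    haps <- unique(replicate(4, paste(sample(c("A", "T"), 5, TRUE), collapse = "")))
    fr <- as.vector(stats::rmultinom(1, 50, rep(1, length(haps)))) / 50
    geno <- generate_sanger_genotypes(haps, fr, 60)
    rs <- resolve_haplotypes(geno)
    retained <- 60 - nrow(rs$excluded)
    expect_equal(sum(rs$haplotypes$count), 2L * retained)
  }
})

test_that("the haplotype network is a minimum-spanning network", {
  chain <- data.frame(id = c("H1", "H2", "H3"), hap = c("AAA", "AAT", "ATT"),
                      count = c(5L, 3L, 2L))
  g <- build_network(chain)
  expect_equal(igraph::ecount(g), 2L)
  expect_equal(unname(sort(igraph::degree(g))), c(1, 1, 2))
  expect_true(all(igraph::E(g)$weight == 1))
  star <- data.frame(id = paste0("H", 1:5),
                     hap = c("AAAA", "TAAA", "ATAA", "AATA", "AAAT"),
                     count = c(20L, 1L, 1L, 1L, 1L))
  gs <- build_network(star)
  expect_equal(unname(igraph::degree(gs)[1]), 4)
  expect_true(igraph::is_connected(gs))
  # MST weight oracle on random haplotype sets
  set.seed(73)
  for (i in 1:30) {
    haps <- unique(replicate(8, paste(sample(c("A", "C", "G", "T"), 6, TRUE),
                                      collapse = "")))
    ht <- data.frame(id = paste0("H", seq_along(haps)), hap = haps,
                     count = seq_along(haps))
    gg <- build_network(ht)
    d <- outer(haps, haps, Vectorize(function(a, b)
      sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])))
    mst_w <- sum(igraph::E(igraph::mst(gg, weights = igraph::E(gg)$weight))$weight)
    expect_equal(mst_w, prim_mst_weight(d))
  }
})

test_that("network edges are invariant to haplotype input order", {
  set.seed(79)
  haps <- unique(replicate(7, paste(sample(c("A", "T", "G"), 5, TRUE), collapse = "")))
  ht <- data.frame(id = paste0("H", seq_along(haps)), hap = haps,
                   count = seq_along(haps))
  g1 <- build_network(ht)
  perm <- sample(nrow(ht))
  ht2 <- ht[perm, ]
  g2 <- build_network(ht2)
  s1 <- edge_signature(g1); s2 <- edge_signature(g2)
  expect_equal(s1[order(s1$a, s1$b), ], s2[order(s2$a, s2$b), ],
               ignore_attr = TRUE)
})

test_that("ancestral classification picks common central haplotypes", {
  star <- data.frame(id = paste0("H", 1:5),
                     hap = c("AAAA", "TAAA", "ATAA", "AATA", "AAAT"),
                     count = c(20L, 2L, 1L, 1L, 1L))
  cl <- classify_ancestral(build_network(star))
  expect_true(cl$ancestral[cl$id == "H1"])
  expect_equal(sum(cl$ancestral), 1L)
  expect_true(all(cl$nearest_ancestral[!cl$ancestral] == "H1"))
  expect_equal(cl$dist_to_ancestral[!cl$ancestral], rep(1, 4))
  # two equal hubs are both ancestral
  two_hub <- data.frame(id = paste0("H", 1:6),
                        hap = c("AAAA", "TTAA", "TAAA", "ATAA", "TTTA", "TTAT"),
                        count = c(10L, 10L, 1L, 1L, 1L, 1L))
  cl2 <- classify_ancestral(build_network(two_hub))
  expect_true(all(cl2$ancestral[cl2$id %in% c("H1", "H2")]))
  expect_equal(sum(cl2$ancestral), 2L)
})

test_that("recombinant enumeration matches exhaustive brute force", {
  pool <- c(P1 = "000", P2 = "111")
  pos <- c(10, 40, 70)
  got <- enumerate_recombinants("011", pool, pos)
  expect_equal(nrow(got), 1L)
  expect_equal(got$parent_a, "P1")
  expect_equal(got$parent_b, "P2")
  expect_equal(c(got$interval_start, got$interval_end), c(10, 40))
  # a target identical to a pool member has no non-trivial explanation here
  expect_equal(nrow(enumerate_recombinants("000", pool, pos)), 0L)
  set.seed(83)
  for (i in 1:40) {
    L <- sample(3:12, 1)
    pool_i <- unique(replicate(sample(3:6, 1),
                               paste(sample(c("0", "1"), L, TRUE), collapse = "")))
    names(pool_i) <- paste0("P", seq_along(pool_i))
    target <- paste(sample(c("0", "1"), L, TRUE), collapse = "")
    pos_i <- sort(sample.int(500, L))
    got <- enumerate_recombinants(target, pool_i, pos_i)
    want <- brute_recombinants(target, pool_i, pos_i)
    o <- function(d) d[do.call(order, d), , drop = FALSE]
    expect_equal(o(got), o(want), ignore_attr = TRUE)
  }
})

test_that("the population recombination rate scales as rho = 2 c Ne r d", {
  expect_equal(expected_recombinants(r = 0, d = 60, Ne = 1e6)$rho, 0)
  one <- expected_recombinants(r = 1e-7, d = 60, c_ploidy = 3, Ne = 1e6)
  expect_equal(one$rho, 36)
  expect_equal(one$individuals_per_event, 1 / 36)
  two <- expected_recombinants(r = 1e-7, d = 60, c_ploidy = 3, Ne = 2e6)
  expect_equal(two$rho, 2 * one$rho)
  expect_error(expected_recombinants(d = 0, Ne = 1e6), "d must be")
})
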