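geno_cols <- function(genotypes) grep("^snp", names(genotypes), value = TRUE)

#' Resolve haplotypes from unphased Sanger genotypes
#'
#' Applies the at-most-one-heterozygous-site rule: an individual that is
#' homozygous at every panel SNP contributes two copies of one haplotype;
#' an individual heterozygous at exactly one SNP contributes the two
#' haplotypes implied by splitting that site; individuals with two or more
#' heterozygous sites (phase-ambiguous) or with missing genotypes are
#' excluded and reported.  Copy counts are conserved: every retained
#' individual contributes exactly two haplotype copies.
#'
#' @param genotypes data.frame with columns individual, population, year
#'   and snp1..snpL, each genotype an unordered pair "X/Y" (missing coded
#'   NA or containing "N").
#' @return list of class \code{haplotype_set}: \code{haplotypes}
#'   (data.frame id, hap, count), \code{carriers} (long table individual /
#'   population / year / hap) and \code{excluded} (individual, reason).
#' @export
resolve_haplotypes <- function(genotypes) {
  snps <- geno_cols(genotypes)
  if (length(snps) == 0L) stop("no snp* columns found")
  g <- as.matrix(genotypes[, snps, drop = FALSE])
  split_alleles <- function(v) do.call(rbind, strsplit(v, "/", fixed = TRUE))
  hap_rows <- list(); carrier_rows <- list(); excluded <- list()
  for (i in seq_len(nrow(g))) {
    row <- g[i, ]
    if (anyNA(row) || any(grepl("N", row, fixed = TRUE))) {
      excluded[[length(excluded) + 1L]] <-
        data.frame(individual = genotypes$individual[i], reason = "missing-data")
      next
    }
    al <- split_alleles(row)
    if (any(!al[, 1] %in% c("A", "C", "G", "T")) || any(!al[, 2] %in% c("A", "C", "G", "T")))
      stop("genotype symbol outside the A/C/G/T alphabet for ", genotypes$individual[i])
    het <- al[, 1] != al[, 2]
    if (sum(het) > 1L) {
      excluded[[length(excluded) + 1L]] <-
        data.frame(individual = genotypes$individual[i], reason = "phase-ambiguous")
      next
    }
    h1 <- paste(al[, 1], collapse = "")
    h2 <- paste(al[, 2], collapse = "")
    hap_rows[[length(hap_rows) + 1L]] <- c(h1, h2)
    carrier_rows[[length(carrier_rows) + 1L]] <-
      data.frame(individual = genotypes$individual[i],
                 population = genotypes$population[i],
                 year = genotypes$year[i], hap = c(h1, h2))
  }
  copies <- unlist(hap_rows)
  if (length(copies) == 0L)
    return(structure(list(haplotypes = data.frame(id = character(), hap = character(),
                                                  count = integer()),
                          carriers = data.frame(),
                          excluded = do.call(rbind, excluded) %||%
                            data.frame(individual = character(), reason = character())),
                     class = "haplotype_set"))
  tab <- sort(table(copies), decreasing = TRUE)
  haplotypes <- data.frame(id = paste0("H", seq_along(tab)),
                           hap = names(tab), count = as.integer(tab))
  structure(list(haplotypes = haplotypes,
                 carriers = do.call(rbind, carrier_rows),
                 excluded = do.call(rbind, excluded) %||%
                   data.frame(individual = character(), reason = character())),
            class = "haplotype_set")
}

hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

hamming_matrix <- function(haps) {
  m <- do.call(rbind, strsplit(haps, ""))
  n <- length(haps)
  d <- matrix(0L, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    d[i, j] <- d[j, i] <- sum(m[i, ] != m[j, ])
  dimnames(d) <- list(haps, haps)
  d
}

#' Minimum-spanning haplotype network
#'
#' Builds the minimum-spanning network on Hamming distances: edges are
#' added in increasing distance order, and within each distance class every
#' edge joining two components (as they stood at the start of the class) is
#' retained, so co-minimal alternative connections are kept rather than
#' broken arbitrarily.  The minimal spanning subgraph of the result has the
#' weight of a minimum spanning tree.
#'
#' @param haplotypes a \code{haplotype_set} from
#'   \code{\link{resolve_haplotypes}}, or a data.frame with columns id, hap
#'   and count.
#' @return an \code{igraph} graph; vertices carry \code{name} (id),
#'   \code{hap} and \code{count}, edges carry \code{weight} (Hamming
#'   distance).
#' @export
build_network <- function(haplotypes) {
  ht <- if (inherits(haplotypes, "haplotype_set")) haplotypes$haplotypes else haplotypes
  stopifnot(all(c("id", "hap", "count") %in% names(ht)), nrow(ht) >= 1L)
  n <- nrow(ht)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  igraph::V(g)$name <- ht$id
  igraph::V(g)$hap <- ht$hap
  igraph::V(g)$count <- ht$count
  if (n == 1L) return(g)
  d <- hamming_matrix(ht$hap)
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  ord <- order(d[pairs])
  pairs <- pairs[ord, , drop = FALSE]
  dists <- d[pairs]
  for (lev in unique(dists)) {
    comp <- igraph::components(g)$membership
    if (max(comp) == 1L) break
    sel <- which(dists == lev)
    for (k in sel) {
      i <- pairs[k, 1L]; j <- pairs[k, 2L]
      if (comp[i] != comp[j])
        g <- igraph::add_edges(g, c(i, j), weight = lev)
    }
  }
  g
}

#' Classify haplotypes as ancestral or derived
#'
#' Ancestral haplotypes are those that are both common (carrier count in
#' the top frequency stratum) and central (network degree >=
#' \code{min_degree}); every other haplotype is derived and assigned its
#' nearest ancestral node by shortest weighted path.  If no node satisfies
#' both criteria the single most frequent haplotype is taken as ancestral.
#'
#' @param network graph from \code{\link{build_network}}.
#' @param freq_quantile carrier-count quantile defining the top stratum
#'   (default 0.75, i.e. top quartile).
#' @param min_degree minimum network degree for an ancestral node.
#' @return data.frame: id, hap, count, degree, ancestral (logical),
#'   nearest_ancestral (id, NA for ancestral nodes), dist_to_ancestral.
#' @export
classify_ancestral <- function(network, freq_quantile = 0.75, min_degree = 2L) {
  counts <- igraph::V(network)$count
  deg <- igraph::degree(network)
  thr <- stats::quantile(counts, freq_quantile, names = FALSE)
  anc <- counts >= thr & deg >= min_degree
  if (!any(anc)) anc <- counts == max(counts) & seq_along(counts) == which.max(counts)
  dmat <- igraph::distances(network, weights = igraph::E(network)$weight)
  ids <- igraph::V(network)$name
  nearest <- rep(NA_character_, length(ids))
  dist_to <- rep(NA_real_, length(ids))
  for (i in which(!anc)) {
    da <- dmat[i, anc]
    j <- which.min(da)
    nearest[i] <- ids[which(anc)[j]]
    dist_to[i] <- da[j]
  }
  data.frame(id = ids, hap = igraph::V(network)$hap, count = counts,
             degree = deg, ancestral = anc, nearest_ancestral = nearest,
             dist_to_ancestral = dist_to)
}

#' Enumerate single-crossover explanations of a haplotype
#'
#' Lists every ordered parent pair and breakpoint such that the target
#' haplotype equals a prefix of parent A followed by a suffix of parent B
#' (one crossover).  Trivial self-explanations are excluded by requiring
#' both parents to differ from the target.
#'
#' @param target haplotype string.
#' @param pool character vector of candidate parent haplotypes (may be
#'   named with ids).
#' @param positions physical positions of the panel SNPs (bp), used to
#'   report the breakpoint interval.
#' @return data.frame: parent_a, parent_b, break_after (SNP index),
#'   interval_start, interval_end (bp, the interval between the flanking
#'   SNPs).  Zero rows if no single crossover explains the target.
#' @export
enumerate_recombinants <- function(target, pool, positions) {
  L <- nchar(target)
  stopifnot(all(nchar(pool) == L), length(positions) == L)
  ids <- names(pool) %||% pool
  out <- list()
  tv <- strsplit(target, "")[[1]]
  pv <- do.call(rbind, strsplit(pool, ""))
  for (k in seq_len(L - 1L)) {
    pre_ok <- which(rowSums(pv[, seq_len(k), drop = FALSE] !=
                              matrix(tv[seq_len(k)], nrow(pv), k, byrow = TRUE)) == 0L)
    suf_ok <- which(rowSums(pv[, (k + 1L):L, drop = FALSE] !=
                              matrix(tv[(k + 1L):L], nrow(pv), L - k, byrow = TRUE)) == 0L)
    for (a in pre_ok) for (b in suf_ok) {
      if (pool[a] == target || pool[b] == target) next
      out[[length(out) + 1L]] <-
        data.frame(parent_a = ids[a], parent_b = ids[b], break_after = k,
                   interval_start = positions[k], interval_end = positions[k + 1L])
    }
  }
  if (length(out) == 0L)
    return(data.frame(parent_a = character(), parent_b = character(),
                      break_after = integer(), interval_start = numeric(),
                      interval_end = numeric()))
  unique(do.call(rbind, out))
}

#' Expected recombination events between two sites
#'
#' The population recombination rate across a distance \code{d} is
#' \eqn{\rho = 2 c N_e r d} per generation, with \code{c} the genome copies
#' per mating pair (3 in haplodiploids), \code{Ne} the effective size and
#' \code{r} the per-bp per-generation recombination rate.  Also returned is
#' \code{1/\rho}, the expected number of effective individuals per single
#' recombination event in the interval.
#'
#' @param r recombination rate per bp per generation (1e-7 = 10 cM/Mb).
#' @param d distance between the sites in bp (> 0).
#' @param c_ploidy genome copies per mating pair (default 3).
#' @param Ne effective population size.
#' @return list: rho (events per generation), individuals_per_event.
#' @export
expected_recombinants <- function(r = 1e-7, d, c_ploidy = 3, Ne) {
  if (any(c(r, c_ploidy, Ne) < 0)) stop("model fields must be non-negative")
  if (d <= 0) stop("d must be > 0")
  rho <- 2 * c_ploidy * Ne * r * d
  list(rho = rho,
       individuals_per_event = if (rho > 0) 1 / rho else Inf)
}
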