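SYNC_BASES <- c("A", "T", "C", "G", "N", "del")

#' Simulate pooled sequencing read counts
#'
#' Emulates pooled whole-genome resequencing of a population sample: a pool
#' of \code{pool_size} diploid females is drawn from the population
#' (binomial sampling of 2 * pool_size chromosomes per site), then reads are
#' drawn binomially from the pool's allele proportions at a per-site depth
#' that is Poisson-distributed around \code{depth} (or fixed, with
#' \code{depth_model = "fixed"}).
#'
#' @param freqs per-site population frequencies of the alternate allele.
#' @param pool_size number of diploid individuals in the pool.
#' @param depth mean sequencing depth per site.
#' @param ref,alt reference / alternate base per site (recycled).
#' @param chrom,pos site coordinates (recycled / defaulted to 1..n).
#' @param depth_model "poisson" (default) or "fixed".
#' @param seed integer seed.
#' @return a list of class \code{pool_sample}: \code{sites} (data.frame
#'   chrom, pos, ref, alt), \code{counts} (sites x 6 matrix, columns
#'   A, T, C, G, N, del) and \code{pool_freq} (the realized pool allele
#'   frequencies, for unbiasedness checks).
#' @export
sample_pool_reads <- function(freqs, pool_size, depth, ref = "A", alt = "T",
                              chrom = "chr1", pos = seq_along(freqs),
                              depth_model = c("poisson", "fixed"),
                              seed = NULL) {
  stop_if_not_scalar_prob(freqs, "freqs")
  if (pool_size < 1) stop("pool_size must be >= 1")
  depth_model <- match.arg(depth_model)
  n <- length(freqs)
  ref <- rep_len(ref, n); alt <- rep_len(alt, n)
  if (any(ref == alt)) stop("ref and alt bases must differ")
  with_seed(seed, {
    chroms <- 2L * pool_size
    k_pool <- stats::rbinom(n, chroms, freqs)
    p_pool <- k_pool / chroms
    d <- if (depth_model == "poisson") stats::rpois(n, depth) else rep.int(as.integer(depth), n)
    n_alt <- stats::rbinom(n, d, p_pool)
    counts <- matrix(0L, n, 6L, dimnames = list(NULL, SYNC_BASES))
    ridx <- cbind(seq_len(n), match(ref, SYNC_BASES))
    aidx <- cbind(seq_len(n), match(alt, SYNC_BASES))
    counts[ridx] <- d - n_alt
    counts[aidx] <- counts[aidx] + n_alt
    structure(list(sites = data.frame(chrom = rep_len(chrom, n), pos = pos,
                                      ref = ref, alt = alt),
                   counts = counts, pool_freq = p_pool),
              class = "pool_sample")
  })
}

#' Pooled read counts for every population of a simulated genome
#'
#' Convenience wrapper around \code{\link{sample_pool_reads}}: assigns
#' random reference/alternate bases to the SNPs of a
#' \code{\link{simulate_genome}} result and draws one pooled sample per
#' population.
#'
#' @param genome result of \code{\link{simulate_genome}}.
#' @param pool_size,depth,depth_model see \code{\link{sample_pool_reads}}.
#' @param pool_names names for the pools (default pop1, pop2, ...).
#' @param seed integer seed.
#' @return a list of class \code{sync_set}: \code{sites} (chrom, pos, ref,
#'   alt) and \code{counts}, a list (one per pool) of sites x 6 count
#'   matrices.
#' @export
pool_genome <- function(genome, pool_size = 100L, depth = 80,
                        depth_model = "poisson", pool_names = NULL,
                        seed = NULL) {
  n <- length(genome$pos)
  n_pops <- ncol(genome$freq)
  pool_names <- pool_names %||% paste0("pop", seq_len(n_pops))
  with_seed(seed, {
    ref <- sample(c("A", "T", "C", "G"), n, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(c("A", "T", "C", "G"), b), 1L), "")
    counts <- lapply(seq_len(n_pops), function(k)
      sample_pool_reads(genome$freq[, k], pool_size, depth, ref = ref,
                        alt = alt, pos = genome$pos,
                        depth_model = depth_model)$counts)
    names(counts) <- pool_names
    structure(list(sites = data.frame(chrom = "chr1", pos = genome$pos,
                                      ref = ref, alt = alt),
                   counts = counts),
              class = "sync_set")
  })
}

#' Simulate a dose-mortality bioassay table
#'
#' Draws binomial kill counts for a population with a known LC50 under the
#' probit dose-response model
#' \eqn{p = c_0 + (1 - c_0) \Phi(\beta (\log_{10} d - \log_{10} LC50))},
#' mirroring a leaf-disc spray assay of 30 adult females per concentration
#' plus an adjuvant-only control.
#'
#' @param lc50 true LC50 in mg/L.
#' @param slope probit slope per log10 mg/L.
#' @param doses treatment concentrations in mg/L (all > 0).
#' @param n_per_dose individuals exposed per concentration.
#' @param control_mortality baseline mortality in the control.
#' @param include_control prepend a concentration-0 control row.
#' @param seed integer seed.
#' @return data.frame with columns conc_mg_L, n, dead (control row has
#'   conc_mg_L = 0).
#' @export
generate_bioassay <- function(lc50, slope, doses, n_per_dose = 30L,
                              control_mortality = 0, include_control = TRUE,
                              seed = NULL) {
  if (length(doses) == 0) stop("at least one dose is required")
  if (lc50 <= 0 || slope <= 0 || any(doses <= 0))
    stop("lc50, slope and doses must be positive")
  stop_if_not_scalar_prob(control_mortality, "control_mortality")
  with_seed(seed, {
    p <- control_mortality +
      (1 - control_mortality) * stats::pnorm(slope * (log10(doses) - log10(lc50)))
    dead <- stats::rbinom(length(doses), n_per_dose, p)
    out <- data.frame(conc_mg_L = doses, n = n_per_dose, dead = dead)
    if (include_control) {
      cdead <- stats::rbinom(1L, n_per_dose, control_mortality)
      out <- rbind(data.frame(conc_mg_L = 0, n = n_per_dose, dead = cdead), out)
    }
    out
  })
}

#' Simulate Sanger-style unphased genotypes from a haplotype pool
#'
#' Each diploid individual is two independent draws from the haplotype pool;
#' per SNP the genotype is recorded as the unordered base pair (sorted
#' alphabetically, e.g. "A/T").  The true phased pair is kept as an
#' attribute for round-trip tests.
#'
#' @param haplotypes character vector of haplotype strings (equal length,
#'   one character per SNP).
#' @param freqs haplotype frequencies (must sum to 1).
#' @param n_individuals number of diploid individuals to draw.
#' @param population,year labels stamped on every individual.
#' @param seed integer seed.
#' @return data.frame (individual, population, year, snp1..snpL genotypes)
#'   with attribute \code{"truth"}: an n x 2 matrix of the drawn haplotype
#'   strings.
#' @export
generate_sanger_genotypes <- function(haplotypes, freqs, n_individuals,
                                      population = "pop1", year = 2024L,
                                      seed = NULL) {
  if (length(haplotypes) != length(freqs)) stop("haplotypes and freqs differ in length")
  if (abs(sum(freqs) - 1) > 1e-8) stop("haplotype frequencies must sum to 1")
  L <- unique(nchar(haplotypes))
  if (length(L) != 1L) stop("haplotypes must have equal length")
  with_seed(seed, {
    a <- sample(haplotypes, n_individuals, replace = TRUE, prob = freqs)
    b <- sample(haplotypes, n_individuals, replace = TRUE, prob = freqs)
    am <- do.call(rbind, strsplit(a, ""))
    bm <- do.call(rbind, strsplit(b, ""))
    geno <- matrix(paste(pmin(am, bm), pmax(am, bm), sep = "/"),
                   n_individuals, L)
    colnames(geno) <- paste0("snp", seq_len(L))
    out <- data.frame(individual = sprintf("%s_%03d", population, seq_len(n_individuals)),
                      population = population, year = year, geno,
                      stringsAsFactors = FALSE)
    attr(out, "truth") <- cbind(a, b)
    out
  })
}
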