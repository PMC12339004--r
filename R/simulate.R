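#' Configuration for the haplodiploid Wright-Fisher simulator
#'
#' Bundles the demographic and genetic parameters of the forward simulation.
#' Spider mites are haplodiploid: females are diploid, males are haploid and
#' develop from unfertilized eggs, so a mating pair carries \code{c_ploidy = 3}
#' genome copies.  Defaults follow the field system being emulated: a
#' per-base mutation rate of 2.8e-9 per generation and 20 generations per
#' year.
#'
#' @param n_populations number of replicate populations.
#' @param N census number of females per population (males are kept at the
#'   same census, i.e. a constant 1:1 sex ratio).
#' @param c_ploidy genome copies per mating pair (3 for haplodiploids).
#' @param mu per-site per-gamete mutation rate towards the resistant allele.
#' @param s_true selection coefficient of the resistant allele per generation.
#' @param h dominance of the resistant allele in diploid females; female
#'   genotype fitnesses are 1, 1 + h s, 1 + s and male hemizygote fitnesses
#'   are 1, 1 + s.
#' @param generations number of generations to iterate.
#' @param gens_per_year generations per calendar year (used to stamp years
#'   on trajectories).
#' @param genome_length length in bp of the simulated genome segment.
#' @param p0 initial resistant-allele frequency at each target site.
#' @param n_sites number of (unlinked) target sites to track.
#' @param select_males apply selection in males as well as females (default
#'   TRUE; exposed as a switch because hemizygous selection is a modelling
#'   choice).
#' @param seed integer seed; fully determines the simulation.
#'
#' @return an object of class \code{sim_config} (a validated list).
#' @export
sim_config <- function(n_populations = 1L, N = 1e4, c_ploidy = 3, mu = 2.8e-9,
                       s_true = 0, h = 0.5, generations = 140L,
                       gens_per_year = 20L, genome_length = 5e5,
                       p0 = 0, n_sites = 1L, select_males = TRUE,
                       seed = NULL) {
  if (N < 1) stop("N must be >= 1")
  if (mu < 0 || mu > 1) stop("mu must be in [0, 1]")
  if (s_true <= -1) stop("s_true must be > -1 (fitness must stay positive)")
  if (generations < 1) stop("generations must be >= 1")
  stop_if_not_scalar_prob(p0, "p0")
  structure(list(n_populations = as.integer(n_populations), N = N,
                 c_ploidy = c_ploidy, mu = mu, s_true = s_true, h = h,
                 generations = as.integer(generations),
                 gens_per_year = as.integer(gens_per_year),
                 genome_length = genome_length, p0 = p0,
                 n_sites = as.integer(n_sites),
                 select_males = isTRUE(select_males), seed = seed),
            class = "sim_config")
}

#' Forward haplodiploid Wright-Fisher simulation
#'
#' Iterates a single population of \code{N} diploid females and \code{N}
#' haploid males.  Each generation: viability selection weights adult
#' genotypes (females 1, 1 + h s, 1 + s; males 1, 1 + s), egg and sperm
#' gamete pools are formed from the selected adults, recurrent mutation
#' converts wild-type gametes to the resistant allele at rate \code{mu} per
#' gamete, daughters are random unions of one egg and one sperm, and sons
#' develop from unfertilized eggs.  All sites are treated as unlinked.
#'
#' @param config a \code{\link{sim_config}}.
#' @return a list of class \code{wf_sim} with elements:
#'   \item{freq}{matrix (generations + 1) x n_sites of population allele
#'     frequencies, copies weighted 2:1 female:male;}
#'   \item{female,male}{final genotype count tables;}
#'   \item{new_mutations}{matrix of de novo mutation events (new resistant
#'     gamete copies) per generation and site;}
#'   \item{config}{the input configuration.}
#' @export
simulate_wf <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    N <- config$N
    L <- config$n_sites
    s <- config$s_true
    h <- config$h
    mu <- config$mu
    wf <- c(1, 1 + h * s, 1 + s)       # female AA / Aa / aa (a = resistant)
    wm <- if (config$select_males) c(1, 1 + s) else c(1, 1)
    if (any(!is.finite(c(wf, wm))) || any(c(wf, wm) < 0))
      stop("non-finite or negative fitness; check s_true and h")

    p0 <- rep_len(config$p0, L)
    # initial state: Hardy-Weinberg females, binomial males
    n_aa <- stats::rbinom(L, N, p0^2)
    n_Aa <- stats::rbinom(L, N - n_aa, ifelse(p0 < 1, 2 * p0 * (1 - p0) / (1 - p0^2), 0))
    n_am <- stats::rbinom(L, N, p0)

    G <- config$generations
    freq <- matrix(NA_real_, G + 1L, L)
    newmut <- matrix(0L, G, L)
    pop_freq <- function(n_Aa, n_aa, n_am) (n_Aa + 2 * n_aa + n_am) / (3 * N)
    freq[1L, ] <- pop_freq(n_Aa, n_aa, n_am)

    for (g in seq_len(G)) {
      n_AA <- N - n_Aa - n_aa
      wsum <- n_AA * wf[1] + n_Aa * wf[2] + n_aa * wf[3]
      p_egg <- (0.5 * n_Aa * wf[2] + n_aa * wf[3]) / wsum
      p_sperm <- (n_am * wm[2]) / ((N - n_am) * wm[1] + n_am * wm[2])

      # egg pool: N eggs become daughters, N eggs become sons
      k_egg <- stats::rbinom(L, 2L * N, p_egg)
      m_egg <- stats::rbinom(L, 2L * N - k_egg, mu)
      k_egg <- k_egg + m_egg
      k_sperm <- stats::rbinom(L, N, p_sperm)
      m_sperm <- stats::rbinom(L, N - k_sperm, mu)
      k_sperm <- k_sperm + m_sperm
      newmut[g, ] <- m_egg + m_sperm

      # which resistant eggs end up in the N daughter eggs
      k_egg_f <- stats::rhyper(L, k_egg, 2L * N - k_egg, N)
      k_egg_m <- k_egg - k_egg_f
      # random pairing of daughter eggs with sperm
      n_aa <- stats::rhyper(L, k_sperm, N - k_sperm, k_egg_f)
      n_Aa <- k_egg_f + k_sperm - 2L * n_aa
      n_am <- k_egg_m
      freq[g + 1L, ] <- pop_freq(n_Aa, n_aa, n_am)
    }
    structure(list(freq = freq,
                   female = cbind(AA = N - n_Aa - n_aa, Aa = n_Aa, aa = n_aa),
                   male = cbind(A = N - n_am, a = n_am),
                   new_mutations = newmut, config = config),
              class = "wf_sim")
  })
}

#' Deterministic (infinite-N) haplodiploid selection recursion
#'
#' Iterates the expected gamete-frequency recursion of
#' \code{\link{simulate_wf}} with drift and mutation switched off.  Used as
#' the analytic oracle for trajectory shape and for converting a
#' per-generation selection coefficient into an expected per-year logit
#' slope.
#'
#' @inheritParams sim_config
#' @param p0 initial allele frequency.
#' @return numeric vector of length \code{generations + 1}: the expected
#'   population allele frequency (2:1 female:male weighting) per generation.
#' @export
wf_deterministic <- function(p0, s_true, h = 0.5, generations = 100L,
                             select_males = TRUE) {
  wf <- c(1, 1 + h * s_true, 1 + s_true)
  wm <- if (select_males) c(1, 1 + s_true) else c(1, 1)
  pe <- ps <- pm <- p0                 # egg, sperm, male frequencies
  out <- numeric(generations + 1L)
  out[1L] <- p0
  for (g in seq_len(generations)) {
    gAA <- (1 - pe) * (1 - ps); gaa <- pe * ps
    gAa <- 1 - gAA - gaa
    wbar <- gAA * wf[1] + gAa * wf[2] + gaa * wf[3]
    pe_next <- (0.5 * gAa * wf[2] + gaa * wf[3]) / wbar
    ps_next <- pm * wm[2] / ((1 - pm) * wm[1] + pm * wm[2])
    pm <- pe_next                       # sons develop from the selected egg pool
    pe <- pe_next; ps <- ps_next
    ff <- (pe + ps) / 2                 # female allele frequency next gen
    out[g + 1L] <- (2 * ff + pm) / 3
  }
  out
}

#' Multi-population genome simulation with an optional selective sweep
#'
#' Generates per-population allele frequencies for a panel of biallelic SNPs
#' on a single chromosome, emulating a set of field populations that share
#' ancestral variation and have since drifted apart, with a recent selective
#' sweep at a focal locus in designated populations.
#'
#' Neutral sites: ancestral frequencies are drawn from a 1/p-shaped spectrum
#' truncated to \code{[p_min, 1 - p_min]}, then each population drifts
#' independently for \code{generations} generations by binomial resampling
#' of the 3N haploid genome copies of a haplodiploid population.  The sweep:
#' the resistant allele at \code{sweep_pos} follows a forward
#' \code{\link{simulate_wf}} trajectory from \code{sweep_p0}; linked neutral
#' sites hitchhike with probability \code{exp(-d / (s_true * hitch_bp))}
#' at distance \code{d}, becoming fixed (within the swept fraction of the
#' population) for the allele carried by the sweeping haplotype.  This is a
#' deliberately light-weight hitchhiking approximation: it reproduces the
#' local loss of diversity and excess differentiation of a hard sweep
#' without simulating recombination explicitly.
#'
#' @param n_pops number of populations; population 1 is the focal one.
#' @param swept logical vector of length \code{n_pops}: which populations
#'   carry the sweep.
#' @param n_snps number of neutral SNPs.
#' @param genome_length chromosome length in bp.
#' @param N census females per population (drift scale: 3N copies).
#' @param generations generations of independent drift.
#' @param s_true,h selection parameters of the sweeping allele.
#' @param sweep_pos position of the selected site (default: middle).
#' @param sweep_p0 frequency of the resistant allele when selection starts
#'   (an established low-frequency mutation).
#' @param hitch_bp hitchhiking length scale per unit of s (bp).
#' @param p_min truncation of the ancestral frequency spectrum.
#' @param seed integer seed.
#' @return list with \code{pos} (SNP positions, sorted), \code{freq}
#'   (n_snps x n_pops matrix of derived-allele frequencies),
#'   \code{sweep_pos}, \code{sweep_final} (final frequency of the selected
#'   allele per population) and the arguments.
#' @export
simulate_genome <- function(n_pops = 3L, swept = c(TRUE, FALSE, FALSE),
                            n_snps = 2000L, genome_length = 5e5,
                            N = 200L, generations = 40L,
                            s_true = 0.5, h = 0.5,
                            sweep_pos = NULL, sweep_p0 = 0.05,
                            hitch_bp = 4e4, p_min = 0.02, seed = NULL) {
  stopifnot(length(swept) == n_pops)
  with_seed(seed, {
    pos <- sort(sample.int(genome_length, n_snps))
    sweep_pos <- sweep_pos %||% round(genome_length / 2)
    u <- stats::runif(n_snps)
    p_anc <- p_min * ((1 - p_min) / p_min)^u   # density proportional to 1/p
    C <- 3L * N                                 # haploid copies, haplodiploid
    freq <- matrix(NA_real_, n_snps, n_pops)
    sweep_final <- numeric(n_pops)
    for (k in seq_len(n_pops)) {
      p <- p_anc
      for (g in seq_len(generations)) p <- stats::rbinom(n_snps, C, p) / C
      if (swept[k]) {
        cfg <- sim_config(N = N, s_true = s_true, h = h,
                          generations = generations, p0 = sweep_p0,
                          n_sites = 1L, mu = 0)
        pf <- simulate_wf(cfg)$freq
        pf <- pf[nrow(pf), 1L]
        sweep_final[k] <- pf
        d <- abs(pos - sweep_pos)
        w_hitch <- pf * exp(-d / (max(s_true, 1e-6) * hitch_bp))
        founder <- stats::rbinom(n_snps, 1L, p_anc)  # alleles on the swept haplotype
        p <- (1 - w_hitch) * p + w_hitch * founder
      }
      freq[, k] <- p
    }
    list(pos = pos, freq = freq, sweep_pos = sweep_pos,
         sweep_final = sweep_final, swept = swept, N = N,
         generations = generations, s_true = s_true,
         genome_length = genome_length)
  })
}
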