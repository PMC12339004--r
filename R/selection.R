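#' Selection coefficients from allele-frequency trajectories
#'
#' Binomial logistic regression of allele counts on calendar year: the
#' fitted year slope is the per-year selection coefficient s (under
#' logistic allele-frequency growth the logit frequency increases linearly
#' at rate s).  Per-allele fits give each allele's s; the joint fit pools
#' all alleles with allele-specific intercepts and one shared year slope,
#' giving the collective selective strength.  Counts are
#' \code{round(freq * n_chromosomes)}, weighting populations by the number
#' of chromosomes sampled.
#'
#' @param trajectories data.frame with columns allele, population, year,
#'   freq, n_chromosomes.
#' @param joint also fit the shared-slope joint model (default TRUE).
#' @param gens_per_year used to convert the per-year slope to a
#'   per-generation scale in the output.
#' @return data.frame of class \code{selection_fit}: allele (".joint" for
#'   the pooled fit), s (per year), se, z, p, s_per_generation, n_points,
#'   status ("ok", "non-estimable" for alleles observed in fewer than two
#'   distinct years, "separation" when every point is at frequency 0 or 1).
#' @export
fit_selection <- function(trajectories, joint = TRUE, gens_per_year = 20L) {
  need <- c("allele", "population", "year", "freq", "n_chromosomes")
  stopifnot(all(need %in% names(trajectories)))
  tr <- trajectories
  stop_if_not_scalar_prob(tr$freq, "freq")
  if (any(tr$n_chromosomes < 1)) stop("n_chromosomes must be >= 1")
  tr$k <- round(tr$freq * tr$n_chromosomes)
  tr$year0 <- tr$year - min(tr$year)

  fit_one <- function(d, formula_rhs) {
    if (all(d$k == 0 | d$k == d$n_chromosomes))
      return(list(s = NA_real_, se = NA_real_, z = NA_real_, p = NA_real_,
                  status = "separation"))
    fml <- stats::as.formula(paste("cbind(k, n_chromosomes - k) ~", formula_rhs))
    fit <- suppressWarnings(stats::glm(fml, data = d, family = stats::binomial()))
    sm <- summary(fit)$coefficients
    row <- sm["year0", ]
    list(s = unname(row[1L]), se = unname(row[2L]), z = unname(row[3L]),
         p = unname(row[4L]), status = "ok")
  }

  rows <- list()
  for (al in unique(tr$allele)) {
    d <- tr[tr$allele == al, ]
    if (length(unique(d$year)) < 2L) {
      rows[[al]] <- data.frame(allele = al, s = NA_real_, se = NA_real_,
                               z = NA_real_, p = NA_real_,
                               n_points = nrow(d), status = "non-estimable")
      next
    }
    r <- fit_one(d, "year0")
    rows[[al]] <- data.frame(allele = al, s = r$s, se = r$se, z = r$z,
                             p = r$p, n_points = nrow(d), status = r$status)
  }
  if (joint && length(unique(tr$allele)) >= 1L) {
    d <- tr[ave(tr$year, tr$allele, FUN = function(y) length(unique(y))) >= 2L, ]
    rhs <- if (length(unique(d$allele)) > 1L) "0 + allele + year0" else "year0"
    r <- fit_one(d, rhs)
    rows[[".joint"]] <- data.frame(allele = ".joint", s = r$s, se = r$se,
                                   z = r$z, p = r$p, n_points = nrow(d),
                                   status = r$status)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$s_per_generation <- out$s / gens_per_year
  class(out) <- c("selection_fit", class(out))
  out
}

#' Recurrent-mutation rate and implied effective population size
#'
#' From the mean number of distinct resistance mutations per population
#' accumulated since the pesticide's release, the population-scaled
#' mutation rate is \eqn{\Theta = \bar k / (\mathrm{years} \times
#' \mathrm{generations/year})} (new resistance mutations per population per
#' generation), and the effective population size required to supply them
#' is \eqn{N_e = \Theta / (c \mu)} with \eqn{c = 3} genome copies per
#' mating pair in a haplodiploid (\eqn{\Theta = 3 N_e \mu}).
#'
#' @param k_bar mean distinct resistance mutations per population.
#' @param years_elapsed years since the selection pressure began.
#' @param gens_per_year generations per year (default 20).
#' @param mu per-bp per-generation mutation rate (default 2.8e-9).
#' @param c_ploidy genome copies per mating pair (default 3).
#' @return list of class \code{recurrent_mutation_estimate}: k_bar,
#'   years_elapsed, gens_per_year, theta, mu, c_ploidy, ne_implied.
#' @export
recurrent_mutation_estimate <- function(k_bar, years_elapsed,
                                        gens_per_year = 20L, mu = 2.8e-9,
                                        c_ploidy = 3) {
  if (years_elapsed <= 0 || gens_per_year <= 0) stop("zero generations")
  if (mu <= 0 || c_ploidy <= 0) stop("mu and c_ploidy must be > 0")
  if (k_bar < 0) stop("k_bar must be >= 0")
  theta <- k_bar / (years_elapsed * gens_per_year)
  structure(list(k_bar = k_bar, years_elapsed = years_elapsed,
                 gens_per_year = gens_per_year, theta = theta, mu = mu,
                 c_ploidy = c_ploidy, ne_implied = theta / (c_ploidy * mu)),
            class = "recurrent_mutation_estimate")
}

#' @export
print.recurrent_mutation_estimate <- function(x, ...) {
  cat(sprintf("Theta = %.4g new resistance mutations per population per generation\n",
              x$theta))
  cat(sprintf("Implied Ne = %.3g (Theta = %g * Ne * mu, mu = %g)\n",
              x$ne_implied, x$c_ploidy, x$mu))
  invisible(x)
}

#' Association between mutation-frequency metrics and survival
#'
#' Ordinary least-squares fits of population survival at the diagnostic
#' dose on each frequency metric (predominant-allele frequency,
#' any-resistant-carrier frequency, homozygous-carrier frequency), plus one
#' multivariate fit of survival on the individual mutation frequencies.
#'
#' @param pop_table data.frame with a \code{survival} column in [0, 1], one
#'   column per metric named in \code{metrics}, and the per-mutation
#'   frequency columns named in \code{mutations}.
#' @param metrics names of the univariate metric columns.
#' @param mutations names of the per-mutation frequency columns for the
#'   multivariate fit (NULL to skip).
#' @return list of class \code{association_result}: \code{univariate}
#'   (data.frame metric, slope, intercept, r_squared, n; constant
#'   predictors are flagged with NA r_squared) and \code{multivariate}
#'   (coefficient table with p-values, or NULL).
#' @export
survival_association <- function(pop_table,
                                 metrics = c("predominant_freq",
                                             "any_carrier_freq",
                                             "homozygote_freq"),
                                 mutations = NULL) {
  stopifnot("survival" %in% names(pop_table), nrow(pop_table) >= 3L)
  stop_if_not_scalar_prob(pop_table$survival, "survival")
  uni <- do.call(rbind, lapply(metrics, function(m) {
    x <- pop_table[[m]]
    if (is.null(x)) stop("missing metric column: ", m)
    if (stats::sd(x) == 0)
      return(data.frame(metric = m, slope = NA_real_, intercept = NA_real_,
                        r_squared = NA_real_, n = nrow(pop_table)))
    fit <- stats::lm(pop_table$survival ~ x)
    data.frame(metric = m, slope = unname(stats::coef(fit)[2L]),
               intercept = unname(stats::coef(fit)[1L]),
               r_squared = summary(fit)$r.squared, n = nrow(pop_table))
  }))
  multi <- NULL
  if (!is.null(mutations)) {
    fml <- stats::as.formula(paste("survival ~", paste(mutations, collapse = " + ")))
    mfit <- stats::lm(fml, data = pop_table)
    multi <- as.data.frame(summary(mfit)$coefficients)
    names(multi) <- c("estimate", "se", "t", "p")
    multi$term <- rownames(multi); rownames(multi) <- NULL
  }
  structure(list(univariate = uni, multivariate = multi),
            class = "association_result")
}

#' Hudson-style FST from allele frequencies
#'
#' For two populations with resistance-allele frequencies \code{p} and
#' \code{q} over a set of alleles, \eqn{F_{ST} = 1 - H_w / H_b} with
#' \eqn{H_w} the mean within-population heterozygosity
#' (\eqn{(2p(1-p) + 2q(1-q)) / 2}) and \eqn{H_b} the between-population
#' heterozygosity (\eqn{p(1-q) + q(1-p)}), ratio-of-sums over alleles.
#'
#' @param p,q frequency vectors (one entry per allele).
#' @return scalar FST (NaN when both populations are monomorphic at every
#'   allele).
#' @export
hudson_fst <- function(p, q) {
  stopifnot(length(p) == length(q))
  hw <- sum(p * (1 - p) + q * (1 - q))       # = sum of (2p(1-p)+2q(1-q))/2
  hb <- sum(p * (1 - q) + q * (1 - p))
  1 - hw / hb
}

#' Isolation by distance of resistance-allele frequencies
#'
#' Pairwise Hudson-style FST computed from resistance-allele frequencies,
#' great-circle distances from population coordinates, and a Mantel test
#' (Pearson correlation, one-sided, permutation p-value).
#'
#' @param freqs populations x alleles matrix (or data.frame) of
#'   resistance-allele frequencies; rownames are population ids.
#' @param coords data.frame or matrix with columns \code{lon}, \code{lat}
#'   in decimal degrees, rows matching \code{freqs}.
#' @param permutations number of Mantel permutations (default 999).
#' @param seed integer seed for the permutations.
#' @return list of class \code{ibd_result}: fst (dist), distance_km (dist),
#'   mantel_r, p_value, permutations.
#' @export
resistance_fst_ibd <- function(freqs, coords, permutations = 999L,
                               seed = NULL) {
  freqs <- as.matrix(freqs)
  n <- nrow(freqs)
  if (n < 4L) stop("need >= 4 populations")
  coords <- as.matrix(coords[, c("lon", "lat")])
  if (nrow(unique(coords)) == 1L) stop("identical coordinates for all populations")
  fst <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    v <- hudson_fst(freqs[i, ], freqs[j, ])
    fst[i, j] <- fst[j, i] <- if (is.finite(v)) max(v, 0) else 0
  }
  dkm <- geosphere::distm(coords, fun = geosphere::distHaversine) / 1000
  dimnames(fst) <- dimnames(dkm) <- list(rownames(freqs), rownames(freqs))
  if (stats::sd(stats::as.dist(fst)) == 0) {
    # undifferentiated populations: no signal to correlate with distance
    mantel_r <- NA_real_; p_value <- NA_real_
  } else {
    mt <- with_seed(seed,
      vegan::mantel(stats::as.dist(fst), stats::as.dist(dkm),
                    method = "pearson", permutations = permutations))
    mantel_r <- unname(mt$statistic); p_value <- mt$signif
  }
  structure(list(fst = stats::as.dist(fst), distance_km = stats::as.dist(dkm),
                 mantel_r = mantel_r, p_value = p_value,
                 permutations = permutations),
            class = "ibd_result")
}
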