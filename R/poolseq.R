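ACGT <- c("A", "T", "C", "G")

#' Subsample one site's reads to uniform depth
#'
#' Draws exactly \code{b} reads without replacement from a site's base
#' counts (a multivariate hypergeometric / urn draw over the A, T, C, G
#' columns; N and deletion reads are excluded).  Depth-dependent bias in
#' diversity estimators is removed by computing every statistic at this
#' uniform depth.
#'
#' @param counts named vector or 1-row slice with at least the A, T, C, G
#'   counts.
#' @param b target depth (default 50).
#' @param seed integer seed.
#' @return integer vector (A, T, C, G) summing to \code{b}, or \code{NULL}
#'   (masked-site sentinel) if total depth < b.
#' @export
subsample_site <- function(counts, b = 50L, seed = NULL) {
  if (b < 2L) stop("b must be >= 2")
  cnt <- as.integer(counts[ACGT])
  if (anyNA(cnt) || any(cnt < 0)) stop("counts must be non-negative A/T/C/G values")
  if (sum(cnt) < b) return(NULL)
  with_seed(seed, {
    urn <- rep.int(seq_len(4L), cnt)
    draw <- sample(urn, b)
    out <- tabulate(draw, 4L)
    names(out) <- ACGT
    out
  })
}

#' Subsample a whole pool's count matrix to uniform depth
#'
#' Applies \code{\link{subsample_site}} to every site of a sites x 6 (or
#' sites x 4) count matrix.  Sites below depth \code{b} are masked (all-NA
#' rows).
#'
#' @param counts matrix with columns A, T, C, G (N/del ignored).
#' @param b target depth.
#' @param seed integer seed.
#' @return sites x 4 integer matrix at depth \code{b}; masked rows are NA.
#' @export
subsample_pool <- function(counts, b = 50L, seed = NULL) {
  m <- counts[, ACGT, drop = FALSE]
  with_seed(seed, {
    out <- matrix(NA_integer_, nrow(m), 4L, dimnames = list(NULL, ACGT))
    depth <- rowSums(m)
    ok <- which(depth >= b)
    for (i in ok) out[i, ] <- subsample_site(m[i, ], b)
    out
  })
}

#' Per-site nucleotide diversity from uniform-depth counts
#'
#' The pooled estimator with the small-depth correction:
#' \eqn{\pi = b/(b-1) (1 - \sum_a p_a^2)} over the four bases, reads treated
#' as sampled sequences at depth \code{b}.
#'
#' @param counts vector (A, T, C, G) at uniform depth, or a matrix of such
#'   rows.
#' @param b the uniform depth (must equal the row sums).
#' @return per-site diversity (vectorized over rows).
#' @export
site_pi <- function(counts, b = 50L) {
  if (b < 2L) stop("b must be >= 2")
  m <- if (is.matrix(counts)) counts else matrix(counts, nrow = 1L)
  if (any(abs(rowSums(m) - b) > 0, na.rm = TRUE))
    stop("counts must sum to b at every site")
  p2 <- rowSums((m / b)^2)
  (b / (b - 1)) * (1 - p2)
}

# Tajima (1989) constants for sample size n
tajima_constants <- function(n) {
  i <- seq_len(n - 1L)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  list(a1 = a1, a2 = a2, e1 = e1, e2 = e2)
}

window_grid <- function(pos, window) {
  start <- (ceiling(pos / window) - 1L) * window + 1L
  start
}

#' Windowed diversity statistics for one pool
#'
#' Computes nucleotide diversity, Watterson's theta and Tajima's D in
#' non-overlapping windows (default 5 kb, aligned to the k*window+1 grid)
#' from uniform-depth subsampled counts.  A site is a SNP if its minor
#' allele has at least \code{min_count} reads after subsampling.  Per-site
#' pi and theta are sums over SNPs divided by the number of covered
#' (unmasked) sites in the window; Tajima's D uses the classical constants
#' with sample size n = b (reads-as-sequences after uniform subsampling).
#' Windows whose covered fraction is below \code{min_cover} are masked.
#'
#' @param pos 1-based site positions (sorted, one chromosome).
#' @param counts sites x 4 uniform-depth matrix from
#'   \code{\link{subsample_pool}} (masked rows NA).
#' @param b the uniform depth.
#' @param min_count minor-allele read count to call a SNP (default 2).
#' @param window window span in bp (default 5000).
#' @param min_cover minimum covered fraction of assayed sites for a window
#'   to be reported (relative to sites present in the input).
#' @param chrom chromosome label.
#' @return data.frame: chrom, start, end, n_sites_covered, n_snps, pi,
#'   theta_w, tajimas_d (NA where masked or undefined).
#' @export
window_stats <- function(pos, counts, b = 50L, min_count = 2L,
                         window = 5000L, min_cover = 0, chrom = "chr1") {
  if (is.unsorted(pos, strictly = TRUE)) stop("positions must be sorted, strictly increasing")
  stopifnot(nrow(counts) == length(pos))
  covered <- !is.na(counts[, 1L])
  minor <- ifelse(covered, b - apply(counts, 1L, max), NA_integer_)
  is_snp <- covered & minor >= min_count
  pi_site <- numeric(length(pos))
  pi_site[is_snp] <- site_pi(counts[is_snp, , drop = FALSE], b)
  tc <- tajima_constants(b)
  win <- window_grid(pos, window)
  out <- do.call(rbind, lapply(split(seq_along(pos), win), function(ix) {
    n_cov <- sum(covered[ix])
    S <- sum(is_snp[ix])
    n_tot <- length(ix)
    if (n_cov == 0 || n_cov / n_tot < min_cover)
      return(data.frame(start = win[ix[1L]], n_sites_covered = n_cov,
                        n_snps = NA_integer_, pi = NA_real_,
                        theta_w = NA_real_, tajimas_d = NA_real_))
    pi_sum <- sum(pi_site[ix])
    th_sum <- S / tc$a1
    D <- if (S > 0) (pi_sum - th_sum) / sqrt(tc$e1 * S + tc$e2 * S * (S - 1))
         else NA_real_
    data.frame(start = win[ix[1L]], n_sites_covered = n_cov, n_snps = S,
               pi = pi_sum / n_cov, theta_w = th_sum / n_cov, tajimas_d = D)
  }))
  rownames(out) <- NULL
  data.frame(chrom = chrom, start = out$start, end = out$start + window - 1L,
             out[, -1L, drop = FALSE])
}

#' Windowed pairwise FST between two pools
#'
#' Per window, \eqn{F_{ST} = (\pi_{total} - \pi_{within}) / \pi_{total}}
#' where \eqn{\pi_{within}} is the mean of the two pools' per-site
#' diversities and \eqn{\pi_{total}} is the diversity of the pooled counts
#' (depth 2b), both summed over sites covered in both pools.  Windows with
#' \eqn{\pi_{total} = 0} are masked.  At most two alleles per site enter:
#' the two globally (both pools combined) most frequent bases.
#'
#' @param pos sorted 1-based positions (one chromosome).
#' @param counts_a,counts_b sites x 4 uniform-depth matrices (same sites).
#' @param b the uniform depth of each pool.
#' @param window window span in bp.
#' @param chrom chromosome label.
#' @param clamp clamp the ratio to [0, 1] (default TRUE; set FALSE to keep
#'   the raw, possibly negative, estimator, e.g. for unbiasedness checks).
#' @return data.frame: chrom, start, end, n_sites_covered, fst (NA where
#'   masked).  Note the estimator sees the pools, not the source
#'   populations: two finite pools drawn from one population differ by
#'   sampling, so the null expectation of the raw estimator is about
#'   1/(4 * pool_size), not 0.
#' @export
window_fst <- function(pos, counts_a, counts_b, b = 50L, window = 5000L,
                       chrom = "chr1", clamp = TRUE) {
  if (is.unsorted(pos, strictly = TRUE)) stop("positions must be sorted, strictly increasing")
  stopifnot(nrow(counts_a) == length(pos), nrow(counts_b) == length(pos))
  covered <- !is.na(counts_a[, 1L]) & !is.na(counts_b[, 1L])
  # restrict each site to the two most frequent alleles overall
  tot <- counts_a + counts_b
  top2 <- t(apply(tot, 1L, function(r) order(r, decreasing = TRUE)[1:2]))
  take2 <- function(m) {
    cbind(m[cbind(seq_len(nrow(m)), top2[, 1L])],
          m[cbind(seq_len(nrow(m)), top2[, 2L])])
  }
  a2 <- take2(counts_a); b2 <- take2(counts_b)
  # renormalize to depth b within the two chosen alleles (drop third-allele reads)
  da <- rowSums(a2); db <- rowSums(b2)
  pi2 <- function(m, d) ifelse(d >= 2, (d / (d - 1)) * (1 - rowSums((m / d)^2)), NA_real_)
  pi_a <- pi2(a2, da); pi_b <- pi2(b2, db)
  dt <- da + db
  pi_t <- pi2(a2 + b2, dt)
  win <- window_grid(pos, window)
  out <- do.call(rbind, lapply(split(seq_along(pos), win), function(ix) {
    ok <- ix[covered[ix] & !is.na(pi_a[ix]) & !is.na(pi_b[ix]) & !is.na(pi_t[ix])]
    n_cov <- length(ok)
    if (n_cov == 0)
      return(data.frame(start = win[ix[1L]], n_sites_covered = 0L, fst = NA_real_))
    st <- sum(pi_t[ok]); sw <- sum((pi_a[ok] + pi_b[ok]) / 2)
    fst <- if (st > 0) (st - sw) / st else NA_real_
    if (!is.na(fst) && clamp) fst <- min(max(fst, 0), 1)
    data.frame(start = win[ix[1L]], n_sites_covered = n_cov, fst = fst)
  }))
  rownames(out) <- NULL
  data.frame(chrom = chrom, start = out$start, end = out$start + window - 1L,
             out[, -1L, drop = FALSE])
}
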