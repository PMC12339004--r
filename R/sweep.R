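#' Log-transformed population branch length
#'
#' Converts a pairwise FST into an additive branch length,
#' \eqn{T = -\ln(1 - F_{ST})}, clamping FST just below 1 so fixed
#' differences stay finite.
#'
#' @param fst FST values in [0, 1] (vectorized; values within 1e-6 outside
#'   the range are clamped, anything further is an error).
#' @param eps clamp distance from 1.
#' @return branch lengths T >= 0.
#' @export
branch_length <- function(fst, eps = 1e-9) {
  if (any(fst < -1e-6 | fst > 1 + 1e-6, na.rm = TRUE))
    stop("fst must lie in [0, 1]")
  fst <- pmin(pmax(fst, 0), 1 - eps)
  -log(1 - fst)
}

#' Population branch statistic
#'
#' The focal population's branch length in the three-population tree:
#' \eqn{PBS = (T_{f1} + T_{f2} - T_{12}) / 2}, where f is the focal
#' population and 1, 2 the two non-focal references.  May be negative.
#'
#' @param t_f1,t_f2 focal-vs-reference branch lengths.
#' @param t_12 reference-vs-reference branch length.
#' @return PBS (vectorized).
#' @export
pbs <- function(t_f1, t_f2, t_12) {
  if (any(c(t_f1, t_f2, t_12) < 0, na.rm = TRUE))
    stop("branch lengths must be non-negative")
  (t_f1 + t_f2 - t_12) / 2
}

#' Population branch excess
#'
#' Corrects PBS for the genome-wide expectation given the non-focal
#' divergence: \eqn{PBE_w = PBS_w - T_{12,w} \cdot med}, where \code{med} is
#' the genome-wide median of \code{PBS / T_12} over windows with
#' \code{T_12 > 0}.  Windows with \code{T_12 = 0} keep their raw PBS.
#' The median (rather than the mean) makes the genome-wide ratio robust to
#' the very outlier windows the statistic is meant to find.
#'
#' @param pbs_w per-window PBS.
#' @param t_12 per-window non-focal branch length.
#' @param min_windows minimum usable windows (T_12 > 0) to estimate the
#'   ratio.
#' @return numeric vector of PBE values (NA propagates).
#' @export
pbe <- function(pbs_w, t_12, min_windows = 20L) {
  stopifnot(length(pbs_w) == length(t_12))
  usable <- !is.na(pbs_w) & !is.na(t_12) & t_12 > 0
  if (sum(usable) < min_windows)
    stop("fewer than ", min_windows, " windows with T_12 > 0")
  med <- stats::median(pbs_w[usable] / t_12[usable])
  out <- pbs_w - t_12 * med
  zero <- !is.na(t_12) & t_12 == 0
  out[zero] <- pbs_w[zero]
  out
}

#' Call PBE outlier windows
#'
#' Windows at or above the empirical (1 - quantile) threshold of PBE.
#' Ties at the threshold are all flagged; ranks break ties by genomic
#' order.
#'
#' @param pbe_w per-window PBE (NA windows are excluded).
#' @param quantile outlier tail mass (default 0.01; 0.05 is the common
#'   alternative).
#' @return logical vector \code{outlier} with attributes
#'   \code{"threshold"} and \code{"rank"} (rank 1 = largest PBE, NA for
#'   non-outliers).
#' @export
call_outliers <- function(pbe_w, quantile = 0.01) {
  if (quantile <= 0 || quantile >= 1) stop("quantile must be in (0, 1)")
  ok <- !is.na(pbe_w)
  thr <- stats::quantile(pbe_w[ok], 1 - quantile, names = FALSE, type = 7)
  out <- ok & pbe_w >= thr
  rk <- rep(NA_integer_, length(pbe_w))
  ord <- order(-pbe_w[out], which(out))   # ties broken by genomic order
  rk[which(out)[ord]] <- seq_len(sum(out))
  attr(out, "threshold") <- thr
  attr(out, "rank") <- rk
  out
}

#' Three-population PBE scan from subsampled pool counts
#'
#' Convenience pipeline: windowed FST for the three population pairs,
#' branch lengths, PBS, PBE and outlier calls, plus the focal population's
#' windowed diversity statistics.
#'
#' @param pos sorted positions (one chromosome).
#' @param focal,ref1,ref2 sites x 4 uniform-depth count matrices
#'   (\code{\link{subsample_pool}}) for the focal population and the two
#'   susceptible references.
#' @param b uniform depth.
#' @param window window span in bp.
#' @param quantile outlier tail mass.
#' @param min_count SNP minor-allele count for the diversity statistics.
#' @param chrom chromosome label.
#' @return data.frame per window: chrom, start, end, fst_f1, fst_f2,
#'   fst_12, t_f1, t_f2, t_12, pbs, pbe, outlier, pi, theta_w, tajimas_d.
#'   Windows with masked FST in any pair have NA PBE and are excluded from
#'   both the median estimation and the outlier calling.
#' @export
pbe_scan <- function(pos, focal, ref1, ref2, b = 50L, window = 5000L,
                     quantile = 0.01, min_count = 2L, chrom = "chr1") {
  f1 <- window_fst(pos, focal, ref1, b = b, window = window, chrom = chrom)
  f2 <- window_fst(pos, focal, ref2, b = b, window = window, chrom = chrom)
  f12 <- window_fst(pos, ref1, ref2, b = b, window = window, chrom = chrom)
  ws <- window_stats(pos, focal, b = b, min_count = min_count,
                     window = window, chrom = chrom)
  # estimator noise can leave window FST slightly negative; floor at 0
  t_f1 <- branch_length(pmax(f1$fst, 0)); t_f2 <- branch_length(pmax(f2$fst, 0))
  t_12 <- branch_length(pmax(f12$fst, 0))
  pbs_w <- pbs(t_f1, t_f2, t_12)
  pbe_w <- pbe(pbs_w, t_12)
  outlier <- rep(NA, length(pbe_w))
  ok <- !is.na(pbe_w)
  calls <- call_outliers(pbe_w[ok], quantile = quantile)
  outlier[ok] <- calls
  data.frame(chrom = f1$chrom, start = f1$start, end = f1$end,
             fst_f1 = f1$fst, fst_f2 = f2$fst, fst_12 = f12$fst,
             t_f1 = t_f1, t_f2 = t_f2, t_12 = t_12,
             pbs = pbs_w, pbe = pbe_w, outlier = outlier,
             pi = ws$pi, theta_w = ws$theta_w, tajimas_d = ws$tajimas_d)
}

#' Per-gene sweep evidence summary
#'
#' For each gene region, summarizes the scan in the gene's neighbourhood:
#' maximum PBE, whether any outlier window falls within the gene body
#' +/- \code{flank}, and the contrast of pi and Tajima's D between
#' gene-proximal windows and the rest of the scanned flank.  The
#' per-population call is "signal" when at least one outlier window lies
#' within the gene +/- \code{flank}.
#'
#' @param scan data.frame from \code{\link{pbe_scan}}.
#' @param genes data.frame with columns gene, chrom, start, end (1-based
#'   inclusive).
#' @param flank bp around the gene body counted as gene-proximal
#'   (default 25000).
#' @return data.frame per gene: gene, max_pbe, n_outliers, signal,
#'   pi_gene, pi_flank, d_gene, d_flank.
#' @export
sweep_report <- function(scan, genes, flank = 25000L) {
  stopifnot(all(c("gene", "chrom", "start", "end") %in% names(genes)))
  out <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    on_chr <- scan$chrom == g$chrom
    if (!any(on_chr)) stop("gene ", g$gene, " outside scanned contigs")
    near <- on_chr & scan$end >= g$start - flank & scan$start <= g$end + flank
    far <- on_chr & !near
    data.frame(gene = g$gene,
               max_pbe = suppressWarnings(max(scan$pbe[near], na.rm = TRUE)),
               n_outliers = sum(scan$outlier[near], na.rm = TRUE),
               signal = any(scan$outlier[near], na.rm = TRUE),
               pi_gene = mean(scan$pi[near], na.rm = TRUE),
               pi_flank = mean(scan$pi[far], na.rm = TRUE),
               d_gene = mean(scan$tajimas_d[near], na.rm = TRUE),
               d_flank = mean(scan$tajimas_d[far], na.rm = TRUE))
  })
  do.call(rbind, out)
}
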