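#' Abbott's control-mortality correction
#'
#' Rescales treatment mortality by the mortality observed in an
#' adjuvant-only control: \code{(p_treated - p_control) / (1 - p_control)},
#' floored at 0.
#'
#' @param p_treated observed treatment mortality (proportion, vectorized).
#' @param p_control control mortality (proportion, < 1).
#' @return corrected mortality in [0, 1].
#' @export
abbott_correct <- function(p_treated, p_control) {
  stop_if_not_scalar_prob(p_treated, "p_treated")
  if (!is.numeric(p_control) || any(p_control < 0) || any(p_control >= 1))
    stop("p_control must be in [0, 1)")
  pmax(0, (p_treated - p_control) / (1 - p_control))
}

#' Probit dose-response fit and LC50
#'
#' Maximum-likelihood binomial regression of Abbott-corrected mortality on
#' log10 concentration with a probit link.  The LC50 is
#' \code{10^(-alpha/beta)}; its 95\% confidence interval comes from the
#' delta method on \code{-alpha/beta} on the log10 scale (Fieller's interval
#' available via \code{ci = "fieller"}).  Control rows (concentration 0)
#' supply the pooled control mortality for the correction and are dropped
#' from the regression.
#'
#' Populations so resistant that no tested concentration kills half the
#' animals are reported with status \code{"censored_above"} and the highest
#' tested concentration as a lower bound, mirroring the ">top dose"
#' convention of resistance monitoring; fully susceptible tables (every
#' dose kills everything) get \code{"censored_below"}.
#'
#' @param records data.frame with columns \code{conc_mg_L}, \code{n},
#'   \code{dead}; rows with \code{conc_mg_L == 0} are controls.
#' @param ci "delta" (default) or "fieller".
#' @param conf confidence level (default 0.95).
#' @return object of class \code{probit_fit}: list with \code{alpha},
#'   \code{beta} (per log10 mg/L), \code{lc50}, \code{lc50_ci},
#'   \code{deviance}, \code{n_doses}, \code{status} (\code{"ok"},
#'   \code{"censored_above"}, \code{"censored_below"} or \code{"failed"}),
#'   \code{bound} (censoring bound in mg/L or NA) and the fitted model.
#' @export
fit_probit <- function(records, ci = c("delta", "fieller"), conf = 0.95) {
  ci <- match.arg(ci)
  stopifnot(all(c("conc_mg_L", "n", "dead") %in% names(records)))
  if (any(records$dead < 0 | records$dead > records$n))
    stop("dead must be between 0 and n")
  ctrl <- records$conc_mg_L == 0
  p_control <- if (any(ctrl)) sum(records$dead[ctrl]) / sum(records$n[ctrl]) else 0
  trt <- records[!ctrl, , drop = FALSE]
  if (length(unique(trt$conc_mg_L)) < 3L)
    stop("need >= 3 distinct treatment concentrations")
  p_corr <- abbott_correct(trt$dead / trt$n, p_control)

  fail <- function(status, bound = NA_real_, msg = NULL)
    structure(list(alpha = NA_real_, beta = NA_real_, lc50 = NA_real_,
                   lc50_ci = c(NA_real_, NA_real_), deviance = NA_real_,
                   n_doses = nrow(trt), status = status, bound = bound,
                   p_control = p_control, message = msg, model = NULL),
              class = "probit_fit")
  if (all(p_corr >= 1)) return(fail("censored_below", min(trt$conc_mg_L)))
  if (all(p_corr <= 0)) return(fail("censored_above", max(trt$conc_mg_L)))

  x <- log10(trt$conc_mg_L)
  fit <- tryCatch(
    suppressWarnings(stats::glm(p_corr ~ x, weights = trt$n,
                                family = stats::binomial(link = "probit"))),
    error = function(e) NULL)
  if (is.null(fit) || !fit$converged)
    return(fail("failed", msg = "probit ML did not converge"))
  cf <- stats::coef(fit)
  alpha <- unname(cf[1L]); beta <- unname(cf[2L])
  if (!is.finite(beta) || beta <= 0)
    return(fail("failed", msg = "non-positive slope: mortality does not increase with dose"))
  V <- stats::vcov(fit)
  m <- -alpha / beta                       # log10 LC50
  z <- stats::qnorm(1 - (1 - conf) / 2)
  ci_log10 <- if (ci == "delta") {
    g <- c(-1 / beta, alpha / beta^2)
    se <- sqrt(drop(t(g) %*% V %*% g))
    c(m - z * se, m + z * se)
  } else {
    # Fieller: solve (alpha + beta m)^2 = z^2 var(alpha + beta m)
    a2 <- beta^2 - z^2 * V[2, 2]
    a1 <- 2 * (alpha * beta - z^2 * V[1, 2])
    a0 <- alpha^2 - z^2 * V[1, 1]
    disc <- a1^2 - 4 * a2 * a0
    if (a2 <= 0 || disc < 0) c(NA_real_, NA_real_)
    else sort(-(-a1 + c(-1, 1) * sqrt(disc)) / (2 * a2))
  }
  lc50 <- 10^m
  status <- "ok"; bound <- NA_real_
  if (lc50 > max(trt$conc_mg_L)) { status <- "censored_above"; bound <- max(trt$conc_mg_L) }
  structure(list(alpha = alpha, beta = beta, lc50 = lc50,
                 lc50_ci = 10^ci_log10, deviance = stats::deviance(fit),
                 n_doses = nrow(trt), status = status, bound = bound,
                 p_control = p_control, message = NULL, model = fit),
            class = "probit_fit")
}

#' @export
print.probit_fit <- function(x, ...) {
  if (x$status %in% c("ok", "censored_above") && is.finite(x$lc50)) {
    cat(sprintf("Probit fit: LC50 = %.4g mg/L (95%% CI %.4g-%.4g), slope = %.3f\n",
                x$lc50, x$lc50_ci[1], x$lc50_ci[2], x$beta))
    if (x$status == "censored_above")
      cat(sprintf("  note: LC50 beyond highest tested dose (> %.4g mg/L)\n", x$bound))
  } else {
    cat(sprintf("Probit fit: LC50 not estimable (%s%s)\n", x$status,
                if (is.finite(x$bound)) sprintf(", bound %.4g mg/L", x$bound) else ""))
  }
  invisible(x)
}

#' Fold-resistance ratio
#'
#' Ratio of two LC50s; the conventional reporting rounds to the nearest
#' integer fold (use \code{rounded = TRUE}).
#'
#' @param lc50_num,lc50_den LC50s in mg/L (numerator, denominator), both > 0.
#' @param rounded round to nearest integer fold.
#' @return the ratio.
#' @export
fold_change <- function(lc50_num, lc50_den, rounded = FALSE) {
  if (any(lc50_den <= 0) || any(lc50_num <= 0))
    stop("LC50 values must be positive")
  r <- lc50_num / lc50_den
  if (rounded) round(r) else r
}

#' Classify a population as susceptible or resistant
#'
#' Field susceptibility to the acaricide is bimodal; populations are called
#' susceptible below a ceiling and resistant above a floor, with the
#' (empirically empty) gap flagged as unclassified.
#'
#' @param lc50 LC50 point estimate, or a censoring bound.
#' @param censored_above is \code{lc50} a lower bound (">x" reporting)?
#' @param susceptible_max,resistant_min classification thresholds in mg/L.
#' @return "susceptible", "resistant" or "unclassified" (vectorized).
#' @export
classify_population <- function(lc50, censored_above = FALSE,
                                susceptible_max = 30.1,
                                resistant_min = 1498.6) {
  censored_above <- rep_len(censored_above, length(lc50))
  out <- ifelse(lc50 >= resistant_min, "resistant",
         ifelse(!censored_above & lc50 <= susceptible_max, "susceptible",
                "unclassified"))
  out
}

#' Group mean LC50 with censoring flag
#'
#' Mean of the point estimates; if any member is censored above, the mean is
#' flagged as a lower bound (the ">mean" reporting convention).
#'
#' @param lc50 LC50 estimates (point estimates or censoring bounds).
#' @param censored_above logical, which values are lower bounds.
#' @return list(mean, censored) where \code{censored} is TRUE if the mean is
#'   itself a lower bound.
#' @export
group_mean_lc50 <- function(lc50, censored_above = FALSE) {
  censored_above <- rep_len(censored_above, length(lc50))
  list(mean = mean(lc50), censored = any(censored_above))
}
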