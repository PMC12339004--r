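traj <- function(years, freq, allele = "m1", n = 100, pop = "p1") {
  data.frame(allele = allele, population = pop, year = years, freq = freq,
             n_chromosomes = n)
}

test_that("trajectory regression recovers flat and exactly logistic signals", {
  flat <- fit_selection(traj(2017:2022, rep(0.4, 6)), joint = FALSE)
  expect_equal(flat$s[1], 0, tolerance = 1e-8)
  expect_lt(abs(flat$z[1]), 1e-6)
  # noiseless logistic: logit(p) = -3 + 0.7 (year - 2017)
  years <- 2017:2023
  p <- stats::plogis(-3 + 0.7 * (years - 2017))
  exact <- fit_selection(traj(years, p, n = 1e7), joint = FALSE)
  expect_lt(abs(exact$s[1] - 0.7) / 0.7, 1e-6)
  expect_equal(exact$s_per_generation[1], exact$s[1] / 20)
})

test_that("joint and per-allele estimates coincide for a single allele", {
  set.seed(89)
  years <- 2017:2022
  p <- stats::plogis(-2 + 0.5 * (years - 2017)) + stats::rnorm(6, 0, 0.02)
  p <- pmin(pmax(p, 0), 1)
  fit <- fit_selection(traj(years, p), joint = TRUE)
  expect_equal(fit$s[fit$allele == "m1"], fit$s[fit$allele == ".joint"])
  expect_equal(fit$se[fit$allele == "m1"], fit$se[fit$allele == ".joint"])
})

test_that("degenerate trajectories are flagged rather than fitted", {
  sep <- fit_selection(traj(2017:2020, c(0, 0, 1, 1)), joint = FALSE)
  expect_equal(sep$status[1], "separation")
  one_year <- fit_selection(traj(rep(2020, 3), c(0.1, 0.2, 0.3)), joint = FALSE)
  expect_equal(one_year$status[1], "non-estimable")
})

test_that("the joint fit pools alleles with a shared year slope", {
  set.seed(97)
  years <- 2017:2023
  rows <- do.call(rbind, lapply(1:4, function(i) {
    p <- stats::plogis(-4 + 0.4 * i / 4 + 0.6 * (years - 2017))
    k <- stats::rbinom(length(p), 400, p)
    traj(years, k / 400, allele = paste0("m", i), n = 400)
  }))
  fit <- fit_selection(rows)
  joint <- fit[fit$allele == ".joint", ]
  expect_equal(joint$s, 0.6, tolerance = 0.05)
  expect_gt(joint$z, 2)
})

test_that("the recurrent-mutation calculation is dimensionally exact", {
  est <- recurrent_mutation_estimate(2.7, 7, 20, 2.8e-9, 3)
  expect_equal(est$theta * est$years_elapsed * est$gens_per_year, est$k_bar)
  zero <- recurrent_mutation_estimate(0, 7, 20, 2.8e-9, 3)
  expect_equal(zero$theta, 0)
  expect_equal(zero$ne_implied, 0)
  half <- recurrent_mutation_estimate(2.7, 7, 20, 2 * 2.8e-9, 3)
  expect_equal(half$ne_implied, est$ne_implied / 2)
  expect_error(recurrent_mutation_estimate(2.7, 0, 20, 2.8e-9, 3), "zero generations")
})

test_that("survival association reduces to squared Pearson correlation", {
  set.seed(101)
  n <- 20
  x <- stats::runif(n)
  tab <- data.frame(survival = x, predominant_freq = x,
                    any_carrier_freq = pmin(x + stats::rnorm(n, 0, 0.1), 1),
                    homozygote_freq = stats::runif(n))
  tab$any_carrier_freq <- pmax(tab$any_carrier_freq, 0)
  res <- suppressWarnings(survival_association(tab))
  uni <- res$univariate
  expect_equal(uni$r_squared[uni$metric == "predominant_freq"], 1)
  expect_equal(uni$slope[uni$metric == "predominant_freq"], 1)
  for (m in uni$metric)
    expect_equal(uni$r_squared[uni$metric == m],
                 stats::cor(tab$survival, tab[[m]])^2)
  # constant predictor flagged
  tab$homozygote_freq <- 0.5
  expect_true(is.na(suppressWarnings(survival_association(tab))$univariate$r_squared[3]))
})

test_that("the permutation null of R^2 sits at the 1/(n-1) bias", {
  set.seed(103)
  n <- 20
  x <- stats::runif(n); y <- stats::runif(n)
  r2 <- replicate(1000, stats::cor(y, sample(x))^2)
  expect_lt(abs(mean(r2) - 1 / (n - 1)), 3 * stats::sd(r2) / sqrt(1000))
  # and the generative ordering: survival built from any-carrier frequency
  hits <- replicate(200, {
    f <- stats::runif(25)
    tab <- data.frame(survival = pmin(pmax(f + stats::rnorm(25, 0, 0.1), 0), 1),
                      predominant_freq = pmin(pmax(f * stats::runif(25, 0.4, 0.9), 0), 1),
                      any_carrier_freq = f,
                      homozygote_freq = pmin(pmax(f^2 + stats::rnorm(25, 0, 0.15), 0), 1))
    u <- survival_association(tab)$univariate
    u$metric[which.max(u$r_squared)] == "any_carrier_freq"
  })
  expect_gte(mean(hits), 0.9)
})

test_that("Mantel IBD detects a cline and stays calibrated under the null", {
  set.seed(107)
  n <- 15
  lon <- seq(100, 120, length.out = n) + stats::rnorm(n, 0, 0.1)
  lat <- rep(30, n)
  coords <- data.frame(lon = lon, lat = lat)
  cline <- matrix(stats::plogis(seq(-3, 3, length.out = n)), ncol = 1)
  cline <- cbind(cline, 1 - cline)
  rownames(cline) <- paste0("p", 1:n)
  res <- resistance_fst_ibd(cline, coords, permutations = 999, seed = 1)
  expect_lte(res$p_value, 0.005)
  expect_gt(res$mantel_r, 0.5)
  # identical frequencies: FST ~ 0 everywhere
  flat <- matrix(0.3, n, 2, dimnames = list(paste0("p", 1:n), NULL))
  res0 <- resistance_fst_ibd(flat, coords, permutations = 99, seed = 2)
  expect_equal(max(res0$fst), 0)
  expect_error(resistance_fst_ibd(cline[1:3, ], coords[1:3, ]), ">= 4")
  expect_error(resistance_fst_ibd(cline, data.frame(lon = rep(1, n), lat = rep(2, n))),
               "identical coordinates")
})

test_that("the Mantel permutation test keeps its nominal type-I error", {
  set.seed(109)
  n <- 15
  coords <- data.frame(lon = stats::runif(n, 100, 120), lat = stats::runif(n, 20, 45))
  rej <- replicate(400, {
    fr <- matrix(stats::runif(n * 3), n, 3, dimnames = list(paste0("p", 1:n), NULL))
    resistance_fst_ibd(fr, coords, permutations = 199)$p_value <= 0.05
  })
  expect_lte(mean(rej), 0.07)
  expect_gte(mean(!rej), 0.90)   # shuffled geography: mostly non-significant
})
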