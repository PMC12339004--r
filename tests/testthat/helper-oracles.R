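# Independent oracles used across tests; deliberately written from the
# definitions, not by calling the package's own code paths.

# Prim's algorithm on a distance matrix: total weight of a minimum spanning tree
prim_mst_weight <- function(d) {
  n <- nrow(d)
  in_tree <- c(TRUE, rep(FALSE, n - 1L))
  total <- 0
  while (!all(in_tree)) {
    sub <- d[in_tree, !in_tree, drop = FALSE]
    total <- total + min(sub)
    j <- which(!in_tree)[which(sub == min(sub), arr.ind = TRUE)[1L, 2L]]
    in_tree[j] <- TRUE
  }
  total
}

# direct textbook evaluation of pi / theta_w / Tajima's D on one window of
# uniform-depth counts (rows summing to b), SNP rule: minor count >= min_count
brute_window_stats <- function(counts, b, min_count = 2L) {
  covered <- !is.na(counts[, 1L])
  m <- counts[covered, , drop = FALSE]
  snp <- apply(m, 1L, function(r) (b - max(r)) >= min_count)
  pi_sum <- 0
  for (i in which(snp)) {
    p <- m[i, ] / b
    pi_sum <- pi_sum + (b / (b - 1)) * (1 - sum(p^2))
  }
  S <- sum(snp)
  i <- seq_len(b - 1L)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (b + 1) / (3 * (b - 1)); b2 <- 2 * (b^2 + b + 3) / (9 * b * (b - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (b + 2) / (a1 * b) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  D <- if (S > 0) (pi_sum - S / a1) / sqrt(e1 * S + e2 * S * (S - 1)) else NA_real_
  list(n_cov = sum(covered), S = S, pi = pi_sum / sum(covered),
       theta_w = (S / a1) / sum(covered), D = D)
}

# brute-force window FST from the definition (two most frequent alleles
# overall per site, sums over sites)
brute_window_fst <- function(ca, cb, b) {
  st <- sw <- 0
  for (i in seq_len(nrow(ca))) {
    if (is.na(ca[i, 1L]) || is.na(cb[i, 1L])) next
    tot <- ca[i, ] + cb[i, ]
    keep <- order(tot, decreasing = TRUE)[1:2]
    a <- ca[i, keep]; bb <- cb[i, keep]
    da <- sum(a); db <- sum(bb)
    if (da < 2 || db < 2) next
    pi1 <- (da / (da - 1)) * (1 - sum((a / da)^2))
    pi2 <- (db / (db - 1)) * (1 - sum((bb / db)^2))
    dt <- da + db
    pit <- (dt / (dt - 1)) * (1 - sum(((a + bb) / dt)^2))
    st <- st + pit; sw <- sw + (pi1 + pi2) / 2
  }
  if (st <= 0) return(NA_real_)
  min(max((st - sw) / st, 0), 1)
}

# exhaustive single-crossover enumeration over all (ordered pair, breakpoint)
brute_recombinants <- function(target, pool, positions) {
  L <- nchar(target)
  tv <- strsplit(target, "")[[1]]
  out <- list()
  ids <- names(pool)
  for (k in seq_len(L - 1L)) for (a in seq_along(pool)) for (b in seq_along(pool)) {
    if (pool[a] == target || pool[b] == target) next
    av <- strsplit(pool[a], "")[[1]]; bv <- strsplit(pool[b], "")[[1]]
    if (all(av[1:k] == tv[1:k]) && all(bv[(k + 1):L] == tv[(k + 1):L]))
      out[[length(out) + 1L]] <- data.frame(parent_a = ids[a], parent_b = ids[b],
                                            break_after = k,
                                            interval_start = positions[k],
                                            interval_end = positions[k + 1L])
  }
  if (length(out) == 0L)
    return(data.frame(parent_a = character(), parent_b = character(),
                      break_after = integer(), interval_start = numeric(),
                      interval_end = numeric()))
  unique(do.call(rbind, out))
}

# grid-search ML for the probit dose-mortality model on corrected proportions
grid_probit <- function(x, p, w, a_range = c(-8, 8), b_range = c(0.05, 8)) {
  loglik <- function(a, b) {
    mu <- pnorm(a + b * x)
    mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
    sum(w * (p * log(mu) + (1 - p) * log(1 - mu)))
  }
  best <- c(NA, NA, -Inf)
  for (pass in 1:3) {
    as <- seq(a_range[1], a_range[2], length.out = 80)
    bs <- seq(b_range[1], b_range[2], length.out = 80)
    ll <- outer(as, bs, Vectorize(loglik))
    ij <- which(ll == max(ll), arr.ind = TRUE)[1L, ]
    best <- c(as[ij[1]], bs[ij[2]], max(ll))
    da <- diff(a_range) / 79; db <- diff(b_range) / 79
    a_range <- best[1] + c(-2, 2) * da
    b_range <- pmax(best[2] + c(-2, 2) * db, 1e-4)
  }
  list(alpha = best[1], beta = best[2])
}

# sorted edge list (id pairs + weight) of an igraph network, for
# order-invariance comparisons
edge_signature <- function(g) {
  e <- igraph::as_data_frame(g, what = "edges")
  if (nrow(e) == 0L) return(e)
  sig <- data.frame(a = pmin(e$from, e$to), b = pmax(e$from, e$to), w = e$weight)
  sig[order(sig$a, sig$b), ]
}
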