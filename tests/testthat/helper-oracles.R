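# Independent brute-force oracles. Each recomputes a quantity by the most
# literal route available (full sorts, double loops, explicit
# enumeration), sharing no code with the package implementation it checks.

# Exhaustive nearest-neighbour scan: full sort of every stored record.
oracle_knn <- function(vectors, ids, labels, query, k) {
  d <- apply(vectors, 1L, function(v) 1 - sum(v * query))
  d[d < 0] <- 0
  ord <- order(d, ids, method = "radix")
  take <- ord[seq_len(min(k, length(ids)))]
  data.frame(object_id = ids[take], label = labels[take],
             distance = d[take], stringsAsFactors = FALSE)
}

# Mean pairwise cosine distance by explicit double loop.
oracle_mean_intra <- function(vectors) {
  n <- nrow(vectors)
  tot <- 0
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      tot <- tot + (1 - sum(vectors[i, ] * vectors[j, ]))
    }
  }
  tot / (n * (n - 1) / 2)
}

# Average precision at 5 for one query, from first principles.
oracle_ap5 <- function(vectors, labels, query, query_label) {
  d <- apply(vectors, 1L, function(v) 1 - sum(v * query))
  ord <- order(d)
  top <- labels[ord[seq_len(min(5L, length(labels)))]]
  hits <- 0; s <- 0
  for (i in seq_along(top)) {
    if (top[i] == query_label) {
      hits <- hits + 1
      s <- s + hits / i
    }
  }
  if (hits == 0) 0 else s / hits
}

# Exact two-sided signed-rank p by explicit loop over every sign pattern
# (grown via expand.grid, unlike the package's bitmask accumulation).
oracle_signrank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  grid <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  w_null <- apply(grid, 1L, function(pos) sum(r[pos]))
  p_lo <- mean(w_null <= w_obs + 1e-9)
  p_hi <- mean(w_null >= w_obs - 1e-9)
  min(1, 2 * min(p_lo, p_hi))
}

# Exact two-sided rank-sum p by explicit loop over every assignment of the
# pooled values to the first group, recomputing U as a pair count.
oracle_ranksum <- function(x, y) {
  pool <- c(x, y)
  n <- length(x)
  count_u <- function(a, b) {
    u <- 0
    for (ai in a) for (bi in b) {
      u <- u + (ai > bi) + 0.5 * (ai == bi)
    }
    u
  }
  u_obs <- count_u(x, y)
  ch <- utils::combn(length(pool), n)
  u_null <- apply(ch, 2L, function(ix) count_u(pool[ix], pool[-ix]))
  p_lo <- mean(u_null <= u_obs + 1e-9)
  p_hi <- mean(u_null >= u_obs - 1e-9)
  list(U = u_obs, p = min(1, 2 * min(p_lo, p_hi)))
}

# Exhaustive sign-flip permutation p for the summed-difference statistic.
oracle_signflip_p <- function(d) {
  n <- length(d)
  t_obs <- abs(sum(d))
  grid <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  t_null <- apply(grid, 1L, function(s) abs(sum(s * d)))
  mean(t_null >= t_obs - 1e-9)
}
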