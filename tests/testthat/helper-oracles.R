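# Independent oracles used across the suite. Each is a deliberately naive
# implementation kept separate from the package's code paths.

# Connected-component count by union-find over all pairs.
union_find_components <- function(ids, pairs, r2, threshold) {
  parent <- seq_along(ids)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (nrow(pairs) > 0) {
    for (r in seq_len(nrow(pairs))) {
      if (r2[r] > threshold) {
        i <- match(pairs[r, 1], ids); j <- match(pairs[r, 2], ids)
        if (!is.na(i) && !is.na(j)) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[ri] <- rj
        }
      }
    }
  }
  length(unique(vapply(seq_along(ids), find, integer(1))))
}

# Topological overlap by direct triple loop.
tom_triple_loop <- function(a) {
  n <- nrow(a)
  diag(a) <- 0
  k <- rowSums(a)
  out <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
    out[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  out
}

# Benjamini-Hochberg step-up by hand.
bh_by_hand <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  prev <- 1
  for (r in seq(m, 1)) {
    prev <- min(prev, p[ord[r]] * m / r)
    q[ord[r]] <- prev
  }
  q
}

# Exact two-sided Mann-Whitney p by full enumeration of group assignments.
mw_exact_enum <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- combn(n, n1)
  us <- apply(combs, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  mu <- n1 * (n - n1) / 2
  mean(abs(us - mu) >= abs(u_obs - mu))
}

# Fisher two-sided p by hypergeometric enumeration (sum of tables with
# probability <= observed, within a relative tolerance for ties).
fisher_p_enum <- function(tab) {
  a <- tab[1, 1]; r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  lo <- max(0, r1 + c1 - n); hi <- min(r1, c1)
  probs <- stats::dhyper(lo:hi, c1, n - c1, r1)
  obs <- stats::dhyper(a, c1, n - c1, r1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Classical two-sample KS statistic between hit and miss rank positions.
ks_stat_ranks <- function(hit_pos, miss_pos) {
  grid <- sort(c(hit_pos, miss_pos))
  f1 <- vapply(grid, function(g) mean(hit_pos <= g), numeric(1))
  f2 <- vapply(grid, function(g) mean(miss_pos <= g), numeric(1))
  max(abs(f1 - f2))
}

# Adjusted Rand index from the contingency table.
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  expected <- si * sj / choose(n, 2)
  maxi <- (si + sj) / 2
  (sij - expected) / (maxi - expected)
}
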