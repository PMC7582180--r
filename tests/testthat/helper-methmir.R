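# shared fixtures and independent oracles used across test files

toy_sample_sheet <- function(n_ad = 5L, n_hc = 5L) {
  data.frame(
    sample_id = c(sprintf("A%02d", seq_len(n_ad)), sprintf("H%02d", seq_len(n_hc))),
    group = rep(c("AD", "HC"), c(n_ad, n_hc)),
    age = seq(25, 55, length.out = n_ad + n_hc),
    subject_id = paste0("S", seq_len(n_ad + n_hc)),
    stringsAsFactors = FALSE
  )
}

# brute-force BH step-up: sort, multiply by m/rank, enforce monotonicity
bh_brute <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- p[ord] * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) adj[i] <- min(adj[i], adj[i + 1])
  pmin(adj, 1)[order(ord)]
}

# O(n^2) connected components under the gap relation
cluster_brute <- function(pos, maxgap) {
  n <- length(pos)
  adj <- abs(outer(pos, pos, "-")) <= maxgap
  # transitive closure over the chain relation via repeated expansion
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (adj[i, j] && comp[j] != comp[i]) {
        comp[comp == comp[j]] <- comp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  comp
}

# all set partitions of 1..n (restricted growth strings)
all_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, maxlab) {
    k <- length(prefix)
    if (k == n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (lab in seq_len(maxlab + 1L)) {
      rec(c(prefix, lab), max(maxlab, lab))
    }
  }
  rec(integer(0), 0L)
  out
}

# exhaustive modularity maximization over all partitions (n <= 8)
best_modularity <- function(adj) {
  parts <- all_partitions(nrow(adj))
  max(vapply(parts, function(m) modularity_matrix(adj, m), numeric(1L)))
}

# Spearman rho by the explicit average-rank formula (Pearson on ranks)
spearman_brute <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# exact upper-tail hypergeometric sum P[X >= k]
hyper_brute <- function(k, K, n, N) {
  if (k <= 0) return(1)
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}
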