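#' All-pairs Spearman correlation table
#'
#' Computes the Spearman rank correlation (average ranks for ties) for
#' every unordered pair of features, with missing values excluded
#' pairwise. Two-sided p-values use the t approximation on `n - 2` degrees
#' of freedom; BH FDR is computed jointly over all tested pairs (one
#' family). Pairs with fewer than `min_shared` complete sample pairs are
#' skipped and counted in the `n_skipped` attribute.
#'
#' @param x Feature-by-sample matrix (features from both layers stacked).
#' @param layers Optional named character vector tagging each feature with
#'   its layer (`"cpg"` or `"mirna"`); defaults to `"feature"`.
#' @param min_shared Minimum shared samples per pair (default 5).
#' @return data.frame: `node_a`, `node_b`, `layer_a`, `layer_b`, `n`,
#'   `rho`, `p`, `fdr`; one row per unordered pair.
#' @export
spearman_all_pairs <- function(x, layers = NULL, min_shared = 5L) {
  stopifnot(is.matrix(x), nrow(x) >= 2L)
  ids <- rownames(x)
  if (is.null(layers)) layers <- stats::setNames(rep("feature", nrow(x)), ids)
  rho <- suppressWarnings(
    stats::cor(t(x), method = "spearman", use = "pairwise.complete.obs")
  )
  obs <- crossprod(!is.na(t(x)))
  iu <- which(upper.tri(rho), arr.ind = TRUE)
  n <- obs[iu]
  r <- rho[iu]
  ok <- n >= min_shared & !is.na(r)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 0))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[abs(r) >= 1] <- 0
  edges <- data.frame(
    node_a = ids[iu[, 1L]],
    node_b = ids[iu[, 2L]],
    layer_a = unname(layers[ids[iu[, 1L]]]),
    layer_b = unname(layers[ids[iu[, 2L]]]),
    n = as.integer(n),
    rho = r,
    p = p,
    stringsAsFactors = FALSE
  )
  edges <- edges[ok, , drop = FALSE]
  edges$fdr <- bh_adjust(edges$p)
  attr(edges, "n_skipped") <- sum(!ok)
  edges
}

#' Threshold the edge table
#'
#' Keeps edges with `|rho| > rho_min` and `fdr < fdr_max`; when
#' `positive_only = TRUE` (the community graph) additionally `rho > 0`.
#' The signed full table should be kept separately for antagonism
#' analysis.
#'
#' @param edges Edge table from [spearman_all_pairs()].
#' @param rho_min Absolute correlation threshold (default 0.75).
#' @param fdr_max FDR threshold (default 0.001).
#' @param positive_only Keep positive edges only (default `TRUE`).
#' @return Filtered edge table.
#' @export
retain_edges <- function(edges, rho_min = 0.75, fdr_max = 0.001,
                         positive_only = TRUE) {
  keep <- abs(edges$rho) > rho_min & edges$fdr < fdr_max
  if (positive_only) keep <- keep & edges$rho > 0
  edges[keep, , drop = FALSE]
}

#' Build an igraph from a retained edge table
#'
#' Undirected graph; edge weight is the Spearman rho (or 1 when
#' `weighted = FALSE`). Vertices carry a `layer` attribute.
#'
#' @param edges Retained (positive) edge table.
#' @param weighted Use rho as edge weight (default `TRUE`).
#' @return igraph object.
#' @export
build_network_graph <- function(edges, weighted = TRUE) {
  if (nrow(edges) == 0L) return(igraph::make_empty_graph(directed = FALSE))
  g <- igraph::graph_from_data_frame(
    edges[, c("node_a", "node_b")], directed = FALSE
  )
  igraph::E(g)$weight <- if (weighted) edges$rho else rep(1, nrow(edges))
  layer <- c(stats::setNames(edges$layer_a, edges$node_a),
             stats::setNames(edges$layer_b, edges$node_b))
  igraph::V(g)$layer <- unname(layer[igraph::V(g)$name])
  g
}

#' Detect communities by Leiden modularity optimization
#'
#' Partitions the positive-weight graph with the Leiden algorithm (local
#' moving, refinement, aggregation) under the modularity objective, with a
#' fixed random seed for reproducibility. Returns the membership, the
#' modularity Q of the partition, and per-community layer counts.
#'
#' @param graph igraph object (undirected, positive weights).
#' @param resolution Resolution parameter (default 1; modularity proper).
#' @param seed Integer seed (mandatory for deterministic output).
#' @param n_iterations Leiden iterations per restart (default 10).
#' @param n_restarts Independent seeded restarts; the partition with the
#'   highest modularity is kept (default 5; the local-moving phase is
#'   stochastic, so restarts guard against local optima).
#' @return List of class `"community_partition"`: `membership` (named
#'   integer vector), `modularity`, `sizes` (data.frame community x layer
#'   counts), `n_nodes`.
#' @export
detect_communities <- function(graph, resolution = 1, seed,
                               n_iterations = 10L, n_restarts = 5L) {
  if (missing(seed)) stop("a seed is required for reproducible community detection")
  if (igraph::vcount(graph) == 0L) {
    return(structure(list(membership = integer(0), modularity = NA_real_,
                          sizes = data.frame(), n_nodes = 0L),
                     class = "community_partition"))
  }
  w <- igraph::E(graph)$weight
  memb <- NULL
  q <- -Inf
  for (r in seq_len(n_restarts)) {
    set.seed(seed + r - 1L)
    cl <- igraph::cluster_leiden(graph, objective_function = "modularity",
                                 resolution = resolution,
                                 n_iterations = n_iterations)
    m_r <- igraph::membership(cl)
    q_r <- igraph::modularity(graph, m_r, weights = w)
    if (q_r > q) { q <- q_r; memb <- m_r }
  }
  layer <- igraph::V(graph)$layer
  if (is.null(layer)) layer <- rep("feature", igraph::vcount(graph))
  sizes <- as.data.frame.matrix(table(community = as.integer(memb), layer = layer))
  sizes <- cbind(community = as.integer(rownames(sizes)), sizes)
  rownames(sizes) <- NULL
  structure(
    list(membership = stats::setNames(as.integer(memb), names(memb)),
         modularity = q, sizes = sizes, n_nodes = igraph::vcount(graph)),
    class = "community_partition"
  )
}

#' @export
print.community_partition <- function(x, ...) {
  cat("Community partition:", length(unique(x$membership)), "communities over",
      x$n_nodes, "nodes; modularity Q =", format(signif(x$modularity, 4)), "\n")
  if (nrow(x$sizes)) print.data.frame(x$sizes)
  invisible(x)
}

#' Modularity of a partition (direct formula)
#'
#' Computes `Q = (1/2W) * sum_ij (A_ij - k_i k_j / 2W) delta(c_i, c_j)`
#' from the weighted adjacency matrix. Kept as an explicit formula so
#' partition quality can be audited independently of the detection route.
#'
#' @param adj Symmetric weighted adjacency matrix (zero diagonal).
#' @param membership Integer community labels, one per row of `adj`.
#' @return Modularity Q.
#' @export
modularity_matrix <- function(adj, membership) {
  stopifnot(is.matrix(adj), nrow(adj) == ncol(adj),
            length(membership) == nrow(adj))
  w2 <- sum(adj)   # 2W for undirected
  if (w2 == 0) return(NA_real_)
  k <- rowSums(adj)
  same <- outer(membership, membership, `==`)
  sum((adj - outer(k, k) / w2)[same]) / w2
}

#' Scan community pairs for antagonistic correlation structure
#'
#' For every pair of communities, summarises the signed correlations of
#' all cross-community feature pairs (median rho, fraction negative) and
#' flags the pair as antagonistic iff the median is at or below
#' `flag_threshold` and a permutation test (node-label shuffles across the
#' partitioned nodes, seeded) gives p < `alpha`.
#'
#' @param partition A `"community_partition"`.
#' @param edges Full signed edge table from [spearman_all_pairs()]
#'   (all pairs, before thresholding).
#' @param flag_threshold Median cross-correlation at or below which a pair
#'   can be flagged (default -0.5).
#' @param n_perm Number of label permutations (default 1000).
#' @param seed Integer seed for the permutations.
#' @param alpha Permutation p threshold (default 0.01).
#' @return data.frame: `community_a`, `community_b`, `median_rho`,
#'   `frac_negative`, `n_pairs`, `p_perm`, `flag`.
#' @export
antagonism_scan <- function(partition, edges, flag_threshold = -0.5,
                            n_perm = 1000L, seed = 1L, alpha = 0.01) {
  memb <- partition$membership
  nodes <- names(memb)
  comms <- sort(unique(memb))
  if (length(comms) < 2L) {
    return(data.frame(community_a = integer(0), community_b = integer(0),
                      median_rho = numeric(0), frac_negative = numeric(0),
                      n_pairs = integer(0), p_perm = numeric(0),
                      flag = logical(0)))
  }
  rho <- matrix(NA_real_, length(nodes), length(nodes),
                dimnames = list(nodes, nodes))
  ia <- match(edges$node_a, nodes)
  ib <- match(edges$node_b, nodes)
  ok <- !is.na(ia) & !is.na(ib)
  rho[cbind(ia[ok], ib[ok])] <- edges$rho[ok]
  rho[cbind(ib[ok], ia[ok])] <- edges$rho[ok]

  pair_stats <- function(m) {
    res <- list()
    for (i in seq_along(comms)) {
      for (j in seq_along(comms)) {
        if (j <= i) next
        vals <- rho[m == comms[i], m == comms[j]]
        vals <- vals[!is.na(vals)]
        res[[length(res) + 1L]] <- c(i = comms[i], j = comms[j],
                                     med = stats::median(vals),
                                     neg = mean(vals < 0),
                                     n = length(vals))
      }
    }
    do.call(rbind, res)
  }
  obs <- pair_stats(memb)
  set.seed(seed)
  perm_med <- matrix(NA_real_, n_perm, nrow(obs))
  for (b in seq_len(n_perm)) {
    perm_med[b, ] <- pair_stats(sample(memb))[, "med"]
  }
  p_perm <- vapply(seq_len(nrow(obs)), function(k) {
    (1 + sum(perm_med[, k] <= obs[k, "med"], na.rm = TRUE)) / (n_perm + 1)
  }, numeric(1L))
  data.frame(
    community_a = as.integer(obs[, "i"]),
    community_b = as.integer(obs[, "j"]),
    median_rho = obs[, "med"],
    frac_negative = obs[, "neg"],
    n_pairs = as.integer(obs[, "n"]),
    p_perm = p_perm,
    flag = obs[, "med"] <= flag_threshold & p_perm < alpha
  )
}

#' Differential recapitulation per community
#'
#' For each community, counts member features called significantly up or
#' down per layer and tests their over-representation by a one-sided
#' hypergeometric test (background: partitioned nodes of that layer),
#' BH-corrected over all (community, layer, direction) tests.
#'
#' @param partition A `"community_partition"`.
#' @param diff_tables Named list of `"diff_table"`s keyed by layer (e.g.
#'   `list(cpg = ..., mirna = ...)`).
#' @param layers Named character vector: layer per node id.
#' @param alpha Significance threshold on `p_bh` for calling members
#'   (default 0.05).
#' @return data.frame: `community`, `layer`, `direction`, `n_members`,
#'   `n_sig`, `K_sig_layer`, `N_layer`, `p_hyper`, `p_bh`.
#' @export
community_recapitulation <- function(partition, diff_tables, layers,
                                     alpha = 0.05) {
  memb <- partition$membership
  nodes <- names(memb)
  out <- list()
  for (layer in names(diff_tables)) {
    dt <- diff_tables[[layer]]
    in_layer <- nodes[unname(layers[nodes]) == layer]
    N <- length(in_layer)
    if (N == 0L) next
    for (dir in c(1, -1)) {
      sig <- dt$feature_id[!is.na(dt$p_bh) & dt$p_bh < alpha &
                             dt$direction == dir]
      K <- sum(in_layer %in% sig)
      for (cm in sort(unique(memb))) {
        members <- intersect(nodes[memb == cm], in_layer)
        n <- length(members)
        k <- sum(members %in% sig)
        p <- if (n == 0L || K == 0L) 1 else
          stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
        out[[length(out) + 1L]] <- data.frame(
          community = cm, layer = layer,
          direction = ifelse(dir > 0, "up", "down"),
          n_members = n, n_sig = k, K_sig_layer = K, N_layer = N,
          p_hyper = p, stringsAsFactors = FALSE
        )
      }
    }
  }
  res <- do.call(rbind, out)
  res$p_bh <- bh_adjust(res$p_hyper)
  res
}
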