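test_that("Spearman all-pairs handles monotone transforms and ties", {
  x <- rbind(a = 1:10, b = 2 * (1:10) + 1, c = -(1:10)^3)
  colnames(x) <- paste0("s", 1:10)
  e <- spearman_all_pairs(x)
  get <- function(i, j) e$rho[e$node_a == i & e$node_b == j]
  expect_equal(get("a", "b"), 1)
  expect_equal(get("a", "c"), -1)
  expect_true(all(e$p[abs(e$rho) > 0.999] < 1e-12))

  # tie handling against the explicit average-rank formula
  xt <- rbind(u = c(1, 2, 2, 4, 5, 1, 3), v = c(3, 1, 4, 4, 2, 5, 5))
  colnames(xt) <- paste0("s", 1:7)
  et <- spearman_all_pairs(xt)
  expect_equal(et$rho, spearman_brute(xt[1, ], xt[2, ]), tolerance = 1e-12)

  # symmetry / invariance under strictly monotone transforms
  set.seed(12)
  y <- matrix(rnorm(40), 4, 10, dimnames = list(letters[1:4], paste0("s", 1:10)))
  y2 <- y; y2[1, ] <- exp(y2[1, ])
  expect_equal(spearman_all_pairs(y)$rho, spearman_all_pairs(y2)$rho,
               tolerance = 1e-12)

  # t-approximation p agrees with cor.test's AS89-free route
  ct <- cor.test(y[1, ], y[2, ], method = "spearman", exact = FALSE)
  e2 <- spearman_all_pairs(y)
  expect_equal(e2$p[e2$node_a == "a" & e2$node_b == "b"], ct$p.value,
               tolerance = 1e-10)
})

test_that("pairs with too few shared samples are skipped", {
  x <- matrix(rnorm(30), 3, 10, dimnames = list(c("a", "b", "c"), paste0("s", 1:10)))
  x[1, 1:6] <- NA          # a shares only 4 samples with anything
  e <- spearman_all_pairs(x)
  expect_identical(nrow(e), 1L)      # only (b, c) tested
  expect_identical(attr(e, "n_skipped"), 2L)
})

test_that("edge retention applies rho, FDR and sign rules", {
  e <- data.frame(node_a = c("a", "b", "c"), node_b = c("b", "c", "d"),
                  layer_a = "cpg", layer_b = "cpg",
                  rho = c(0.8, -0.9, 0.8), fdr = c(1e-4, 1e-5, 0.05))
  kept <- retain_edges(e)
  expect_identical(kept$node_a, "a")          # negative and high-FDR excluded
  signed <- retain_edges(e, positive_only = FALSE)
  expect_identical(nrow(signed), 2L)          # the -0.9 edge stays in the signed set
})

test_that("Leiden partition maximizes modularity on small graphs", {
  # two disjoint triangles: 2 communities, Q = 0.5
  tri2 <- igraph::make_graph(c(1,2, 2,3, 3,1, 4,5, 5,6, 6,4), directed = FALSE)
  igraph::E(tri2)$weight <- 1
  p <- detect_communities(tri2, seed = 1L)
  expect_identical(length(unique(p$membership)), 2L)
  expect_equal(p$modularity, 0.5)

  # complete graph: a single community
  k5 <- igraph::make_full_graph(5)
  igraph::E(k5)$weight <- 1
  expect_identical(length(unique(detect_communities(k5, seed = 1L)$membership)), 1L)

  # battery of graphs with <= 8 nodes vs exhaustive modularity search
  battery <- list(
    igraph::make_graph(c(1,2, 2,3, 3,1, 4,5, 5,6, 6,4, 3,4), directed = FALSE),
    igraph::make_ring(7),
    igraph::make_star(6, mode = "undirected"),
    igraph::make_lattice(c(2, 4)),
    igraph::make_full_bipartite_graph(3, 4),
    igraph::sample_gnp(8, 0.45),
    igraph::sample_gnp(8, 0.6),
    igraph::make_graph(c(1,2, 3,4, 5,6, 7,8), directed = FALSE)
  )
  set.seed(99)
  for (g in battery) {
    if (igraph::ecount(g) == 0) next
    igraph::E(g)$weight <- 1
    p <- detect_communities(g, seed = 7L)
    adj <- as.matrix(igraph::as_adjacency_matrix(g, attr = "weight", sparse = FALSE))
    expect_equal(p$modularity, best_modularity(adj), tolerance = 1e-12)
  }

  # empty graph: empty partition
  expect_identical(detect_communities(igraph::make_empty_graph(directed = FALSE),
                                      seed = 1L)$n_nodes, 0L)
})

test_that("antagonism scan flags mirrored communities and respects thresholds", {
  # mirrored communities (f and -f, noise-free) next to an independent one;
  # label shuffles that mix in the independent nodes pull the null median up,
  # so the planted pair stands out
  set.seed(31)
  f <- rnorm(12)
  g <- rnorm(12)
  x <- rbind(
    matrix(rep(f, each = 8) * runif(8, 0.8, 1.2), 8, byrow = FALSE),
    matrix(rep(-f, each = 8) * runif(8, 0.8, 1.2), 8, byrow = FALSE),
    matrix(rep(g, each = 8) * runif(8, 0.8, 1.2), 8, byrow = FALSE) +
      matrix(rnorm(96, sd = 0.2), 8)
  )
  rownames(x) <- paste0("n", 1:24); colnames(x) <- paste0("s", 1:12)
  edges <- spearman_all_pairs(x)
  part <- structure(list(membership = setNames(rep(1:3, each = 8), rownames(x)),
                         n_nodes = 24L), class = "community_partition")
  rep <- antagonism_scan(part, edges, n_perm = 200L, seed = 5L)
  pair12 <- rep[rep$community_a == 1 & rep$community_b == 2, ]
  expect_equal(pair12$median_rho, -1)
  expect_equal(pair12$frac_negative, 1)
  expect_true(pair12$flag)
  expect_false(any(rep$flag[rep$community_b == 3]))

  # unattainable threshold flags nothing
  rep2 <- antagonism_scan(part, edges, flag_threshold = -1.01,
                          n_perm = 200L, seed = 5L)
  expect_false(any(rep2$flag))

  # reproducible for a fixed seed
  rep3 <- antagonism_scan(part, edges, n_perm = 200L, seed = 5L)
  expect_identical(rep$p_perm, rep3$p_perm)
})

test_that("independent communities are almost never flagged", {
  hits <- 0L
  for (s in 1:60) {
    cfg <- sim_config(seed = 1000L + s, n_probes = 120L, n_mirnas = 40L,
                      n_dmps = 0L, n_dmr_clusters = 0L,
                      n_diff_mirnas_up = 2L, n_diff_mirnas_down = 2L,
                      mirna_effect = 0, community_group_shift = 0,
                      n_communities = 3L, community_size_cpg = 12L,
                      community_size_mirna = 6L,
                      antagonist_noise_sd = 1e6)  # pair decoupled: all independent
    st <- simulate_study(cfg)
    members <- names(st$truth$community_assignment)
    x <- rbind(st$meth, st$mirna)[members, ]
    edges <- spearman_all_pairs(x)
    part <- structure(list(membership = st$truth$community_assignment,
                           n_nodes = length(members)),
                      class = "community_partition")
    rep <- antagonism_scan(part, edges, n_perm = 300L, seed = s)
    if (any(rep$flag)) hits <- hits + 1L
  }
  expect_lte(hits / 60, 0.05)
})

test_that("community recapitulation counts and enriches by direction", {
  memb <- setNames(c(rep(1L, 6), rep(2L, 6)), paste0("m", 1:12))
  layers <- setNames(rep("mirna", 12), names(memb))
  dt <- data.frame(feature_id = names(memb),
                   p_bh = c(rep(0.001, 6), rep(0.9, 6)),
                   direction = 1)
  part <- structure(list(membership = memb, n_nodes = 12L),
                    class = "community_partition")
  rec <- community_recapitulation(part, list(mirna = dt), layers)
  up1 <- rec[rec$community == 1 & rec$direction == "up", ]
  expect_identical(up1$n_sig, 6L)
  expect_lt(up1$p_hyper, 0.01)
  up2 <- rec[rec$community == 2 & rec$direction == "up", ]
  expect_identical(up2$n_sig, 0L)
  expect_equal(rec[rec$direction == "down", "n_sig"], rep(0L, 2))
})
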