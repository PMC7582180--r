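test_that("generation is bit-reproducible under a fixed seed", {
  a <- simulate_study(sim_config(seed = 5L, n_probes = 300L, n_mirnas = 60L))
  b <- simulate_study(sim_config(seed = 5L, n_probes = 300L, n_mirnas = 60L))
  expect_identical(a$meth, b$meth)
  expect_identical(a$mirna, b$mirna)
  expect_identical(a$dct, b$dct)
  expect_identical(a$annotation, b$annotation)
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(n_diff_mirnas_up = 400L, n_diff_mirnas_down = 100L,
                          n_mirnas = 455L), "exceed")
  expect_error(sim_config(antagonistic_pair = c(1L, 9L)), "antagonistic")
  expect_error(sim_config(n_probes = 50L, n_communities = 4L,
                          community_size_cpg = 25L), "exceed n_probes")
})

test_that("null configuration has identical group means at zero noise", {
  cfg <- sim_config(seed = 3L, n_probes = 50L, n_mirnas = 20L,
                    n_dmps = 0L, n_dmr_clusters = 0L,
                    n_diff_mirnas_up = 0L, n_diff_mirnas_down = 0L,
                    n_communities = 0L, noise_sd = 0,
                    il13_case_m = -1, il13_ctrl_m = -1,
                    il13_case_m_sd = 0, il13_ctrl_m_sd = 0)
  st <- simulate_study(cfg)
  is_ad <- st$sample_sheet$group == "AD"
  expect_equal(rowMeans(st$meth[, is_ad]), rowMeans(st$meth[, !is_ad]),
               tolerance = 1e-12)
  expect_equal(rowMeans(st$mirna[, is_ad]), rowMeans(st$mirna[, !is_ad]),
               tolerance = 1e-12)
  expect_length(st$truth$diff_cpg_effects, 0L)
})

test_that("planted effects are realized exactly at zero noise", {
  cfg <- sim_config(seed = 6L, n_probes = 60L, n_mirnas = 30L,
                    n_dmps = 4L, dmp_effect_range = c(1, 1),
                    prop_dmp_down = 1, n_dmr_clusters = 0L,
                    n_communities = 0L, noise_sd = 0, mirna_effect = 1)
  st <- simulate_study(cfg)
  is_ad <- st$sample_sheet$group == "AD"
  d <- rowMeans(st$meth[, is_ad]) - rowMeans(st$meth[, !is_ad])
  expect_equal(unname(d[st$truth$dmp_ids]), rep(-1, 4), tolerance = 1e-12)

  dm <- rowMeans(st$mirna[, is_ad]) - rowMeans(st$mirna[, !is_ad])
  expect_equal(unname(dm[st$truth$mirna_up]), rep(1, 10), tolerance = 1e-12)
  expect_equal(unname(dm[st$truth$mirna_down]), rep(-1, 6), tolerance = 1e-12)
})

test_that("truth identifiers always exist in the emitted matrices", {
  st <- simulate_study(sim_config(seed = 8L, n_probes = 400L, n_mirnas = 80L,
                                  n_diff_mirnas_up = 5L, n_diff_mirnas_down = 3L))
  tr <- st$truth
  expect_true(all(tr$dmp_ids %in% rownames(st$meth)))
  expect_true(all(unlist(lapply(tr$dmr_regions, `[[`, "probe_ids")) %in%
                    rownames(st$meth)))
  expect_true(all(c(tr$mirna_up, tr$mirna_down) %in% rownames(st$mirna)))
  expect_true(all(names(tr$community_assignment) %in%
                    c(rownames(st$meth), rownames(st$mirna))))
  expect_true(tr$il13_like$probe_id %in% rownames(st$meth))
})

test_that("realized DMP effects fall in the configured range", {
  cfg <- sim_config(seed = 10L, n_probes = 1000L, n_mirnas = 50L,
                    n_diff_mirnas_up = 5L, n_diff_mirnas_down = 3L)
  st <- simulate_study(cfg)
  is_ad <- st$sample_sheet$group == "AD"
  d <- rowMeans(st$meth[, is_ad]) - rowMeans(st$meth[, !is_ad])
  mean_abs <- mean(abs(d[st$truth$dmp_ids]))
  expect_gte(mean_abs, cfg$dmp_effect_range[1])
  expect_lte(mean_abs, cfg$dmp_effect_range[2])
})

test_that("DMR probes sit within the distance rule and share their effect", {
  cfg <- sim_config(seed = 12L, n_probes = 500L, n_mirnas = 30L,
                    n_diff_mirnas_up = 3L, n_diff_mirnas_down = 2L)
  st <- simulate_study(cfg)
  for (reg in st$truth$dmr_regions) {
    pos <- sort(st$annotation$pos[match(reg$probe_ids, st$annotation$probe_id)])
    expect_true(all(diff(pos) < cfg$dmr_gap_bp))
    expect_identical(length(unique(
      st$annotation$chrom[match(reg$probe_ids, st$annotation$probe_id)])), 1L)
    expect_lt(reg$effect, 0)
  }
})

test_that("community factors induce the designed correlation structure", {
  cfg <- sim_config(seed = 15L, n_probes = 400L, n_mirnas = 80L)
  st <- simulate_study(cfg)
  memb <- st$truth$community_assignment
  x <- rbind(st$meth, st$mirna)[names(memb), ]
  rho <- cor(t(x), method = "spearman")
  within <- outer(memb, memb, "==") & upper.tri(rho)
  expect_gt(median(abs(rho[within])), 0.75)

  pair <- st$truth$antagonistic_pair
  cross <- outer(memb == pair[1], memb == pair[2], "&")
  expect_lt(median(rho[cross]), -0.5)

  # zero loadings: cross-layer correlations center on zero
  cfg0 <- sim_config(seed = 16L, n_probes = 200L, n_mirnas = 40L,
                     within_community_loading = 0, community_group_shift = 0,
                     mirna_effect = 0, n_dmps = 0L, n_dmr_clusters = 0L)
  st0 <- simulate_study(cfg0)
  rho0 <- cor(t(st0$meth[1:50, ]), t(st0$mirna), method = "spearman")
  expect_lt(abs(median(rho0)), 0.1)
})

test_that("mirrored factors give perfectly anticorrelated members at zero noise", {
  cfg <- sim_config(seed = 18L, n_probes = 200L, n_mirnas = 40L,
                    member_noise_sd = 0, antagonist_noise_sd = 0,
                    n_dmps = 0L, n_dmr_clusters = 0L)
  st <- simulate_study(cfg)
  memb <- st$truth$cpg_community
  a <- names(memb)[memb == cfg$antagonistic_pair[1]][1:5]
  b <- names(memb)[memb == cfg$antagonistic_pair[2]][1:5]
  rho <- cor(t(st$meth[c(a, b), ]), method = "spearman")
  expect_equal(unname(rho[a, a][upper.tri(rho[a, a])]), rep(1, 10))
  expect_equal(unname(as.vector(rho[a, b])), rep(-1, 25))
})

test_that("the coupled probe behaves as designed within and across groups", {
  cfg <- sim_config(seed = 20L, n_probes = 50L, n_mirnas = 20L,
                    n_dmps = 0L, n_dmr_clusters = 0L, n_communities = 0L)
  st <- simulate_study(cfg)
  m <- st$meth[st$truth$il13_like$probe_id, names(st$dct)]
  ad <- grepl("^AD", names(st$dct))
  # pooled correlation negative (cases hypomethylated, transcript higher)
  expect_lt(cor(m, st$dct, method = "spearman"), 0)

  # zero within-case noise gives within-case Spearman exactly -1
  cfg0 <- sim_config(seed = 21L, n_probes = 50L, n_mirnas = 20L,
                     n_dmps = 0L, n_dmr_clusters = 0L, n_communities = 0L,
                     il13_noise_sd = 0)
  st0 <- simulate_study(cfg0)
  m0 <- st0$meth[st0$truth$il13_like$probe_id, names(st0$dct)]
  ad0 <- grepl("^AD", names(st0$dct))
  expect_equal(cor(m0[ad0], st0$dct[ad0], method = "spearman"), -1)
})
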