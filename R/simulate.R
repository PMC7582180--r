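#' Simulation configuration
#'
#' Assembles the study conditions the generator emulates: two groups of
#' adult male donors (10 cases vs 9 controls for the CLA+ analyses), a CpG
#' M-value matrix with a small set of planted differential probes whose
#' effects span the observed range on the M scale, planted clustered
#' regions sharing a hypomethylation effect, 455 miRNAs with 10
#' up-regulated and 6 down-regulated in cases, latent-factor-driven
#' miRNA/CpG communities with one antagonistic (anti-correlated) pair that
#' is also group-linked, and one CpG whose gene's delta-Ct is strongly
#' negatively coupled to its M-value inside the case group only.
#'
#' @param n_ad,n_hc Samples per group (default 10 vs 9).
#' @param n_probes Number of CpG probes (default 2000).
#' @param n_mirnas Number of miRNAs (default 455).
#' @param n_dmps Planted singleton differential probes (default 30).
#' @param dmp_effect_range Absolute effect range on the M scale (default
#'   `c(0.46, 3.23)`).
#' @param prop_dmp_down Fraction of planted DMPs hypomethylated in cases
#'   (default 0.75, matching 37/49).
#' @param n_dmr_clusters,probes_per_dmr Planted regions (default 3 x 4).
#' @param dmr_gap_bp Within-region probe gaps are drawn below this bound
#'   (default 500 bp, the distance rule).
#' @param dmr_effect_range Absolute shared region effect (default
#'   `c(1.0, 2.0)`; applied with negative sign, hypomethylation).
#' @param n_diff_mirnas_up,n_diff_mirnas_down Planted differential miRNAs
#'   (default 10 and 6).
#' @param mirna_effect Explicit log2 group shift for differential miRNAs
#'   (default 1), on top of the community factor shift.
#' @param n_communities Number of latent communities (default 4).
#' @param community_size_cpg CpG members per community (default 25).
#' @param community_size_mirna miRNA members per non-differential
#'   community (default 10).
#' @param within_community_loading Loading of members on their factor
#'   (default 1.2; with member noise 0.5 the expected within-community
#'   Spearman rho is about 0.84).
#' @param member_noise_sd Member-level noise (default 0.5).
#' @param antagonistic_pair Indices of the anti-correlated community pair
#'   (default `c(1, 2)`).
#' @param antagonist_noise_sd Noise on the mirrored factor (default 0.1).
#' @param community_group_shift Group difference (AD - HC) of the
#'   antagonistic pair's factor (default 2), which propagates a
#'   `loading * shift` effect to members and makes the pair recapitulate
#'   the case/control contrast.
#' @param age_slope True age effect on M-values (default 0; ages are
#'   simulated Uniform(20, 60) so the covariate is exercised without
#'   confounding).
#' @param noise_sd Residual noise of non-member features (default 0.5).
#' @param il13_slope Within-case slope of delta-Ct on M (default -3).
#' @param il13_case_m,il13_case_m_sd,il13_ctrl_m,il13_ctrl_m_sd M-value
#'   distribution of the coupled probe (cases hypomethylated).
#' @param il13_noise_sd Within-case residual of the coupling (default
#'   0.4, giving a design R^2 of about 0.97 and an expected within-case
#'   Spearman rho near -0.95).
#' @param n_hc_qpcr Controls with qPCR expression (default 7).
#' @param seed Integer seed.
#' @return List of class `"sim_config"`.
#' @export
sim_config <- function(n_ad = 10L, n_hc = 9L,
                       n_probes = 2000L, n_mirnas = 455L,
                       n_dmps = 30L, dmp_effect_range = c(0.46, 3.23),
                       prop_dmp_down = 0.75,
                       n_dmr_clusters = 3L, probes_per_dmr = 4L,
                       dmr_gap_bp = 500, dmr_effect_range = c(1.0, 2.0),
                       n_diff_mirnas_up = 10L, n_diff_mirnas_down = 6L,
                       mirna_effect = 1,
                       n_communities = 4L, community_size_cpg = 25L,
                       community_size_mirna = 10L,
                       within_community_loading = 1.2,
                       member_noise_sd = 0.5,
                       antagonistic_pair = c(1L, 2L),
                       antagonist_noise_sd = 0.1,
                       community_group_shift = 2,
                       age_slope = 0, noise_sd = 0.5,
                       il13_slope = -3,
                       il13_case_m = -2.2, il13_case_m_sd = 0.8,
                       il13_ctrl_m = -0.8, il13_ctrl_m_sd = 0.5,
                       il13_noise_sd = 0.4,
                       n_hc_qpcr = 7L, seed = 1L) {
  cfg <- as.list(environment())
  with(cfg, {
    stopifnot(n_ad >= 2L, n_hc >= 2L, n_probes > 0L, n_mirnas > 0L,
              n_dmps >= 0L, all(dmp_effect_range > 0),
              dmr_gap_bp > 0, noise_sd >= 0, member_noise_sd >= 0)
    if (n_diff_mirnas_up + n_diff_mirnas_down > n_mirnas) {
      stop("requested differential miRNAs exceed n_mirnas")
    }
    if (n_communities > 0L &&
        (any(antagonistic_pair < 1L) || any(antagonistic_pair > n_communities))) {
      stop("antagonistic pair not among communities")
    }
    need <- n_dmps + n_dmr_clusters * probes_per_dmr +
      n_communities * community_size_cpg + 1L
    if (need > n_probes) stop("community/planted feature counts exceed n_probes")
  })
  structure(cfg, class = "sim_config")
}

op_seed <- function(config, offset) {
  as.integer((config$seed + 97003 * offset) %% (.Machine$integer.max - 1L)) + 1L
}

#' Simulate the sample sheet
#'
#' Ages are Uniform(20, 60); one sample per subject.
#' @param config A `"sim_config"`.
#' @return Sample sheet data.frame.
#' @export
simulate_sample_sheet <- function(config) {
  set.seed(op_seed(config, 1L))
  ids <- c(sprintf("AD%02d", seq_len(config$n_ad)),
           sprintf("HC%02d", seq_len(config$n_hc)))
  ss <- data.frame(
    sample_id = ids,
    group = rep(c("AD", "HC"), c(config$n_ad, config$n_hc)),
    age = round(stats::runif(length(ids), 20, 60), 1),
    subject_id = paste0("S", ids),
    stringsAsFactors = FALSE
  )
  validate_sample_sheet(ss)
}

#' Simulate latent community factors
#'
#' One standard-normal factor per community per sample. The designated
#' antagonistic pair satisfies `f_b = -f_a + noise`, and that pair's
#' factor carries the configured group shift (AD minus HC difference
#' `community_group_shift` on `f_a`, mirrored on `f_b`).
#'
#' @param config A `"sim_config"`.
#' @param sample_sheet Sample sheet (default: simulated from `config`).
#' @return Matrix (communities x samples) of factor values; attribute
#'   `antagonistic_pair`.
#' @export
simulate_communities <- function(config, sample_sheet = simulate_sample_sheet(config)) {
  set.seed(op_seed(config, 2L))
  k <- config$n_communities
  ns <- nrow(sample_sheet)
  f <- matrix(stats::rnorm(max(k, 0L) * ns), nrow = max(k, 0L), ncol = ns,
              dimnames = list(NULL, sample_sheet$sample_id))
  if (k >= 2L) {
    a <- config$antagonistic_pair[1L]
    b <- config$antagonistic_pair[2L]
    zg <- ifelse(sample_sheet$group == "AD", 0.5, -0.5) * config$community_group_shift
    f[a, ] <- f[a, ] + zg
    f[b, ] <- -f[a, ] + stats::rnorm(ns, sd = config$antagonist_noise_sd)
  }
  attr(f, "antagonistic_pair") <- config$antagonistic_pair
  f
}

#' Simulate the methylation matrix, annotation and truth record
#'
#' Baseline per-probe means are drawn from a bimodal distribution
#' (methylated/demethylated poles near +2/-2 on the M scale). Planted
#' singleton DMPs carry signed group effects drawn from
#' `dmp_effect_range`; DMR probes sit at consecutive positions with gaps
#' below `dmr_gap_bp` and share one negative effect; community-member
#' probes load on their community's latent factor (so members of the
#' group-shifted antagonistic pair are themselves differential, with
#' expected effect `loading * community_group_shift`); all other probes
#' are noise. Background probes are spaced more than the distance rule
#' apart, so planted regions are the only multi-probe clusters by design.
#' Positions, synthetic gene symbols, island relations and SNP flags are
#' emitted in the annotation.
#'
#' @param config A `"sim_config"`.
#' @param sample_sheet Sample sheet.
#' @param latents Latent factor matrix from [simulate_communities()].
#' @return List: `m` (M-value matrix), `annotation`, `truth` (list with
#'   planted ids, effects, regions, community assignment).
#' @export
simulate_methylation <- function(config,
                                 sample_sheet = simulate_sample_sheet(config),
                                 latents = simulate_communities(config, sample_sheet)) {
  set.seed(op_seed(config, 3L))
  np <- config$n_probes
  ns <- nrow(sample_sheet)
  is_ad <- sample_sheet$group == "AD"

  probe_ids <- sprintf("cgs%05d", seq_len(np))
  # feature allocation: DMR runs first, then DMPs, the coupled probe,
  # community members, background
  idx <- seq_len(np)
  n_dmr_probes <- config$n_dmr_clusters * config$probes_per_dmr
  dmr_idx <- if (n_dmr_probes > 0L) idx[seq_len(n_dmr_probes)] else integer(0)
  cursor <- n_dmr_probes
  dmp_idx <- if (config$n_dmps > 0L) idx[cursor + seq_len(config$n_dmps)] else integer(0)
  cursor <- cursor + config$n_dmps
  il13_idx <- cursor + 1L
  cursor <- cursor + 1L
  k <- config$n_communities
  comm_idx <- vector("list", max(k, 0L))
  if (k > 0L) for (c in seq_len(k)) {
    comm_idx[[c]] <- idx[cursor + seq_len(config$community_size_cpg)]
    cursor <- cursor + config$community_size_cpg
  }

  # genomic layout: probes spread over chr1..chr22 in order; background
  # gaps in (dmr_gap_bp + 100, 3000], within-region gaps in [50, dmr_gap_bp * 0.4]
  chrom <- paste0("chr", rep(seq_len(22L), each = ceiling(np / 22L))[seq_len(np)])
  in_dmr_run <- rep(FALSE, np)
  if (n_dmr_probes > 0L) {
    run_pos <- matrix(dmr_idx, nrow = config$probes_per_dmr)
    in_dmr_run[as.vector(run_pos[-1L, , drop = FALSE])] <- TRUE
  }
  gaps <- ifelse(in_dmr_run,
                 stats::runif(np, 50, max(51, config$dmr_gap_bp * 0.4)),
                 stats::runif(np, config$dmr_gap_bp + 100, 3000))
  pos <- integer(np)
  for (chr in unique(chrom)) {
    sel <- chrom == chr
    pos[sel] <- as.integer(1e5 + cumsum(round(gaps[sel])))
  }
  # DMR runs must not straddle a chromosome boundary; shift any that do
  if (n_dmr_probes > 0L) {
    for (cl in seq_len(config$n_dmr_clusters)) {
      members <- dmr_idx[(cl - 1L) * config$probes_per_dmr + seq_len(config$probes_per_dmr)]
      if (length(unique(chrom[members])) > 1L) {
        chrom[members] <- chrom[members[1L]]
        base <- pos[members[1L]]
        pos[members] <- as.integer(base + cumsum(c(0, round(stats::runif(
          length(members) - 1L, 50, max(51, config$dmr_gap_bp * 0.4))))))
      }
    }
  }

  genes <- sprintf("GENE%04d", seq_len(np))
  intergenic <- stats::runif(np) < 0.15
  planted <- sort(c(dmr_idx, dmp_idx, il13_idx, unlist(comm_idx)))
  intergenic[planted] <- FALSE
  genes[intergenic] <- ""
  two_gene <- !intergenic & stats::runif(np) < 0.01
  genes[two_gene] <- paste0(genes[two_gene], "/", sprintf("GENE%04dB", which(two_gene)))
  # DMR cluster probes share their region's gene
  if (n_dmr_probes > 0L) for (cl in seq_len(config$n_dmr_clusters)) {
    members <- dmr_idx[(cl - 1L) * config$probes_per_dmr + seq_len(config$probes_per_dmr)]
    genes[members] <- sprintf("DMRGENE%02d", cl)
  }
  island <- sample(c("Island", "N_Shore", "S_Shore", "N_Shelf", "S_Shelf", "OpenSea"),
                   np, replace = TRUE,
                   prob = c(0.3, 0.1, 0.1, 0.05, 0.05, 0.4))
  snp <- stats::runif(np) < 0.05
  snp[planted] <- FALSE

  annotation <- data.frame(
    probe_id = probe_ids, chrom = chrom, pos = pos,
    strand = sample(c("+", "-"), np, replace = TRUE),
    gene = genes, island_relation = island,
    enhancer = stats::runif(np) < 0.2, dhs = stats::runif(np) < 0.2,
    snp_overlap = snp, stringsAsFactors = FALSE
  )

  # effects
  effect <- numeric(np)
  if (config$n_dmps > 0L) {
    mag <- stats::runif(config$n_dmps, config$dmp_effect_range[1L],
                        config$dmp_effect_range[2L])
    sgn <- ifelse(stats::runif(config$n_dmps) < config$prop_dmp_down, -1, 1)
    effect[dmp_idx] <- mag * sgn
  }
  dmr_effects <- numeric(0)
  if (config$n_dmr_clusters > 0L) {
    dmr_effects <- -stats::runif(config$n_dmr_clusters,
                                 config$dmr_effect_range[1L],
                                 config$dmr_effect_range[2L])
    for (cl in seq_len(config$n_dmr_clusters)) {
      members <- dmr_idx[(cl - 1L) * config$probes_per_dmr + seq_len(config$probes_per_dmr)]
      effect[members] <- dmr_effects[cl]
    }
  }

  loading <- numeric(np)
  comm_of <- rep(NA_integer_, np)
  if (k > 0L) for (c in seq_len(k)) {
    loading[comm_idx[[c]]] <- config$within_community_loading *
      stats::runif(config$community_size_cpg, 0.9, 1.1)
    comm_of[comm_idx[[c]]] <- c
  }

  mu <- ifelse(stats::runif(np) < 0.5, 2, -2) + stats::rnorm(np, sd = 0.5)
  age_c <- sample_sheet$age - mean(sample_sheet$age)
  noise_sd <- ifelse(!is.na(comm_of), config$member_noise_sd, config$noise_sd)
  m <- matrix(stats::rnorm(np * ns, sd = noise_sd), np, ns,
              dimnames = list(probe_ids, sample_sheet$sample_id))
  m <- m + mu + outer(effect, as.numeric(is_ad)) +
    outer(rep(config$age_slope, np), age_c)
  if (k > 0L) {
    for (c in seq_len(k)) {
      sel <- comm_idx[[c]]
      m[sel, ] <- m[sel, ] + loading[sel] %o% latents[c, ]
    }
  }
  # the coupled probe: hypomethylated in cases, its own distribution
  m[il13_idx, is_ad] <- stats::rnorm(sum(is_ad), config$il13_case_m,
                                     config$il13_case_m_sd)
  m[il13_idx, !is_ad] <- stats::rnorm(sum(!is_ad), config$il13_ctrl_m,
                                      config$il13_ctrl_m_sd)
  annotation$gene[il13_idx] <- "IL13LIKE"

  # truth bookkeeping: expected effect of shifted community members
  shift_eff <- numeric(np)
  if (k >= 2L) {
    a <- config$antagonistic_pair[1L]
    b <- config$antagonistic_pair[2L]
    shift_eff[comm_idx[[a]]] <- loading[comm_idx[[a]]] * config$community_group_shift
    shift_eff[comm_idx[[b]]] <- -loading[comm_idx[[b]]] * config$community_group_shift
  }
  diff_all <- effect + shift_eff
  diff_all[il13_idx] <- config$il13_case_m - config$il13_ctrl_m

  truth <- list(
    dmp_ids = probe_ids[dmp_idx],
    dmp_effects = stats::setNames(effect[dmp_idx], probe_ids[dmp_idx]),
    dmr_regions = if (config$n_dmr_clusters > 0L) lapply(
      seq_len(config$n_dmr_clusters), function(cl) {
        members <- dmr_idx[(cl - 1L) * config$probes_per_dmr +
                             seq_len(config$probes_per_dmr)]
        list(gene = sprintf("DMRGENE%02d", cl), chrom = chrom[members[1L]],
             probe_ids = probe_ids[members], effect = dmr_effects[cl])
      }) else list(),
    cpg_community = stats::setNames(comm_of[!is.na(comm_of)],
                                    probe_ids[!is.na(comm_of)]),
    diff_cpg_effects = stats::setNames(diff_all[diff_all != 0],
                                       probe_ids[diff_all != 0]),
    il13_like = list(probe_id = probe_ids[il13_idx], gene_id = "IL13LIKE",
                     slope = config$il13_slope)
  )
  list(m = m, annotation = annotation, truth = truth)
}

#' Simulate the miRNA expression matrix
#'
#' Log2 intensities with planted group shifts: the up-regulated miRNAs are
#' members of the first antagonistic community (positive loading on its
#' group-shifted factor) plus an explicit `+mirna_effect` case shift; the
#' down-regulated miRNAs are members of the mirrored community with an
#' explicit `-mirna_effect` shift. Remaining communities receive
#' non-differential miRNA members; all other miRNAs are noise.
#'
#' @param config A `"sim_config"`.
#' @param sample_sheet Sample sheet.
#' @param latents Latent factors from [simulate_communities()].
#' @return List: `expr` (matrix), `truth` (list: `mirna_up`, `mirna_down`,
#'   `mirna_community`).
#' @export
simulate_mirna <- function(config,
                           sample_sheet = simulate_sample_sheet(config),
                           latents = simulate_communities(config, sample_sheet)) {
  set.seed(op_seed(config, 4L))
  nm <- config$n_mirnas
  ns <- nrow(sample_sheet)
  is_ad <- sample_sheet$group == "AD"
  ids <- sprintf("mir.%04d", seq_len(nm))
  n_up <- config$n_diff_mirnas_up
  n_dn <- config$n_diff_mirnas_down
  up_idx <- seq_len(n_up)
  dn_idx <- n_up + seq_len(n_dn)
  cursor <- n_up + n_dn
  k <- config$n_communities
  comm_of <- rep(NA_integer_, nm)
  loading <- numeric(nm)
  if (k >= 2L) {
    a <- config$antagonistic_pair[1L]
    b <- config$antagonistic_pair[2L]
    comm_of[up_idx] <- a
    comm_of[dn_idx] <- b
    loading[c(up_idx, dn_idx)] <- config$within_community_loading *
      stats::runif(n_up + n_dn, 0.9, 1.1)
    others <- setdiff(seq_len(k), c(a, b))
    for (c in others) {
      if (cursor + config$community_size_mirna > nm) break
      sel <- cursor + seq_len(config$community_size_mirna)
      comm_of[sel] <- c
      loading[sel] <- config$within_community_loading *
        stats::runif(config$community_size_mirna, 0.9, 1.1)
      cursor <- cursor + config$community_size_mirna
    }
  }
  effect <- numeric(nm)
  effect[up_idx] <- config$mirna_effect
  effect[dn_idx] <- -config$mirna_effect

  mu <- stats::rnorm(nm, 6, 1.5)
  noise_sd <- ifelse(!is.na(comm_of), config$member_noise_sd, config$noise_sd)
  expr <- matrix(stats::rnorm(nm * ns, sd = noise_sd), nm, ns,
                 dimnames = list(ids, sample_sheet$sample_id))
  expr <- expr + mu + outer(effect, as.numeric(is_ad))
  if (k > 0L) for (c in seq_len(k)) {
    sel <- which(comm_of == c)
    if (length(sel)) expr[sel, ] <- expr[sel, ] + loading[sel] %o% latents[c, ]
  }
  truth <- list(
    mirna_up = ids[up_idx],
    mirna_down = ids[dn_idx],
    mirna_community = stats::setNames(comm_of[!is.na(comm_of)],
                                      ids[!is.na(comm_of)])
  )
  list(expr = expr, truth = truth)
}

#' Simulate the coupled delta-Ct expression of the il13-like gene
#'
#' Within cases, `delta_ct = a + slope * M + noise` with the configured
#' slope (at most -2.5) and a noise level giving an expected within-case
#' R^2 above 0.82; within controls, delta-Ct is independent of M and
#' centred lower (less transcript). Only `n_hc_qpcr` controls have qPCR
#' measurements, emulating partial validation coverage.
#'
#' @param config A `"sim_config"`.
#' @param m_values Named M-value vector of the coupled probe (from the
#'   simulated methylation matrix).
#' @param sample_sheet Sample sheet.
#' @return Named numeric vector of delta-Ct values over the qPCR samples.
#' @export
simulate_il13_like <- function(config, m_values,
                               sample_sheet = simulate_sample_sheet(config)) {
  set.seed(op_seed(config, 5L))
  ss <- sample_sheet
  is_ad <- ss$group == "AD"
  if (sum(is_ad) < 5L) stop("case group of >= 5 samples required")
  hc_q <- ss$sample_id[!is_ad][seq_len(min(config$n_hc_qpcr, sum(!is_ad)))]
  samples <- c(ss$sample_id[is_ad], hc_q)
  dct <- stats::setNames(numeric(length(samples)), samples)
  ad_s <- ss$sample_id[is_ad]
  # intercept places case delta-Ct above control levels (more transcript)
  a0 <- 1.5 - config$il13_slope * config$il13_case_m
  dct[ad_s] <- a0 + config$il13_slope * m_values[ad_s] +
    stats::rnorm(length(ad_s), sd = config$il13_noise_sd)
  dct[hc_q] <- stats::rnorm(length(hc_q), mean = 0.3, sd = 0.8)
  dct
}

#' Simulate the full synthetic study
#'
#' Runs all generator stages under one seed (sub-streams derived
#' deterministically per stage) and additionally emits a miRNA target map
#' and a gene-set collection for the enrichment stage: each miRNA targets
#' a random subset of the annotated genes, and the collection contains
#' random sets plus two sets seeded from the targets of the planted
#' up/down miRNAs.
#'
#' @param config A `"sim_config"` (default: `sim_config()`).
#' @return List of class `"sim_study"`: `config`, `sample_sheet`, `meth`,
#'   `mirna`, `annotation`, `latents`, `dct`, `target_map`, `gene_sets`,
#'   `truth`.
#' @export
simulate_study <- function(config = sim_config()) {
  ss <- simulate_sample_sheet(config)
  latents <- simulate_communities(config, ss)
  meth <- simulate_methylation(config, ss, latents)
  mir <- simulate_mirna(config, ss, latents)
  dct <- simulate_il13_like(config, meth$m[meth$truth$il13_like$probe_id, ], ss)

  set.seed(op_seed(config, 6L))
  genes <- unique(unlist(strsplit(
    meth$annotation$gene[nzchar(meth$annotation$gene)], "/", fixed = TRUE)))
  pick <- function(pool, k) sample(pool, min(length(pool), k))
  target_map <- lapply(stats::setNames(rownames(mir$expr), rownames(mir$expr)),
                       function(i) pick(genes, sample(5:30, 1L)))
  up_targets <- unique(unlist(target_map[mir$truth$mirna_up]))
  dn_targets <- unique(unlist(target_map[mir$truth$mirna_down]))
  gene_sets <- lapply(stats::setNames(seq_len(40L), sprintf("SET%02d", seq_len(40L))),
                      function(i) pick(genes, sample(10:80, 1L)))
  if (length(up_targets)) gene_sets[["SET_UPTARGETS"]] <-
    unique(c(pick(up_targets, 60L), pick(genes, 10L)))
  if (length(dn_targets)) gene_sets[["SET_DOWNTARGETS"]] <-
    unique(c(pick(dn_targets, 60L), pick(genes, 10L)))

  truth <- c(meth$truth, mir$truth)
  truth$antagonistic_pair <- config$antagonistic_pair
  truth$community_assignment <- c(truth$cpg_community, truth$mirna_community)
  structure(
    list(config = config, sample_sheet = ss, meth = meth$m,
         mirna = mir$expr, annotation = meth$annotation, latents = latents,
         dct = dct, target_map = target_map, gene_sets = gene_sets,
         truth = truth),
    class = "sim_study"
  )
}

#' @export
print.sim_study <- function(x, ...) {
  cat("Synthetic study: ", nrow(x$meth), " CpG probes x ", ncol(x$meth),
      " samples; ", nrow(x$mirna), " miRNAs (seed ", x$config$seed, ")\n",
      sep = "")
  cat("  planted: ", length(x$truth$dmp_ids), " DMPs, ",
      length(x$truth$dmr_regions), " DMRs, ",
      length(x$truth$mirna_up), " up / ", length(x$truth$mirna_down),
      " down miRNAs, ", x$config$n_communities, " communities\n", sep = "")
  invisible(x)
}
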