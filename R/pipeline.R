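#' Run the full analysis pipeline on a synthetic study
#'
#' Executes every stage in order on a simulated dataset: probe filtering,
#' differential methylation (empirical-Bayes moderated t, BH < `alpha`),
#' distance-rule DMR collapse, differential miRNA expression, the
#' integrated miRNA-CpG Spearman network (all miRNAs plus CpGs at
#' differential FDR < `network_cpg_fdr`), Leiden communities with
#' antagonism scan and recapitulation summaries, the coupled
#' methylation-expression analysis with qPCR group statistics, and
#' target-gene over-representation. Stage parameter defaults are the
#' conventional analysis thresholds (alpha 0.05; maxgap 500 bp,
#' min_probes 2; |rho| > 0.75 at FDR < 0.001; resolution 1; Jaccard 0.5).
#'
#' @param study A `"sim_study"` from [simulate_study()], or a
#'   `"sim_config"` (which is simulated first).
#' @param alpha BH threshold for differential calls.
#' @param maxgap,min_probes DMR collapse parameters.
#' @param network_cpg_fdr FDR cutoff selecting CpGs into the network.
#' @param rho_min,edge_fdr Edge retention thresholds.
#' @param resolution Leiden resolution parameter.
#' @param jaccard Redundancy-collapse threshold for enrichment.
#' @param seed Seed for community detection and permutation tests
#'   (default: the study's configured seed).
#' @param n_perm Permutations for the antagonism scan.
#' @return List of class `"methmir_run"` with the artifacts of every
#'   stage and a `counts` log of feature numbers per stage.
#' @export
run_pipeline <- function(study, alpha = 0.05, maxgap = 500, min_probes = 2L,
                         network_cpg_fdr = 0.1, rho_min = 0.75,
                         edge_fdr = 0.001, resolution = 1, jaccard = 0.5,
                         seed = NULL, n_perm = 1000L) {
  if (inherits(study, "sim_config")) study <- simulate_study(study)
  stopifnot(inherits(study, "sim_study"))
  if (is.null(seed)) seed <- study$config$seed
  ss <- study$sample_sheet

  flt <- filter_probes(study$meth, study$annotation, drop_snp = TRUE)
  meth <- drop_null_variance(flt$matrix)

  diff_meth <- diff_test(meth, ss)
  dmps <- call_dmps(diff_meth, alpha = alpha)
  dmrs <- find_dmrs(diff_meth, study$annotation, maxgap = maxgap,
                    alpha = alpha, min_probes = min_probes)

  mirna <- drop_null_variance(study$mirna)
  diff_mirna <- diff_test(mirna, ss)
  mirna_calls <- call_dmps(diff_mirna, alpha = alpha)

  cpg_sel <- select_top_differential(diff_meth, fdr_cutoff = network_cpg_fdr)
  net_x <- rbind(meth[cpg_sel, , drop = FALSE], mirna)
  layers <- stats::setNames(rep(c("cpg", "mirna"), c(length(cpg_sel), nrow(mirna))),
                            rownames(net_x))
  edges <- spearman_all_pairs(net_x, layers = layers)
  pos_edges <- retain_edges(edges, rho_min = rho_min, fdr_max = edge_fdr,
                            positive_only = TRUE)
  graph <- build_network_graph(pos_edges)
  partition <- detect_communities(graph, resolution = resolution, seed = seed)
  antagonism <- antagonism_scan(partition, edges, n_perm = n_perm, seed = seed)
  recap <- if (partition$n_nodes > 0L) {
    community_recapitulation(partition,
                             list(cpg = diff_meth, mirna = diff_mirna),
                             layers = layers, alpha = alpha)
  } else data.frame()

  il13 <- study$truth$il13_like
  qpcr_samples <- names(study$dct)
  ss_q <- ss[match(qpcr_samples, ss$sample_id), ]
  coupling <- methylation_expression_coupling(
    study$meth[il13$probe_id, qpcr_samples], study$dct, ss_q,
    probe_id = il13$probe_id, gene_id = il13$gene_id
  )
  dct_mat <- matrix(study$dct, nrow = 1L,
                    dimnames = list(il13$gene_id, qpcr_samples))
  qpcr_test <- compare_groups_delta_ct(dct_mat, ss_q)

  called_mirnas <- mirna_calls$feature_id
  query <- build_query_genes(called_mirnas, study$target_map,
                             probe_ids = dmps$feature_id,
                             annotation = study$annotation)
  background <- build_query_genes(names(study$target_map), study$target_map,
                                  probe_ids = rownames(meth),
                                  annotation = study$annotation)
  enrichment <- if (length(query) > 0L) {
    collapse_redundancy(fisher_enrich(query, study$gene_sets, background),
                        study$gene_sets, jaccard_max = jaccard)
  } else data.frame()

  counts <- data.frame(
    stage = c("probes_input", "probes_after_snp_filter", "probes_tested",
              "dmps_called", "dmr_candidates", "dmrs_called",
              "mirnas_tested", "mirnas_called", "network_cpgs",
              "network_edges_retained", "communities"),
    n = c(nrow(study$meth), nrow(meth), sum(diff_meth$tested),
          nrow(dmps), nrow(dmrs$candidates), nrow(dmrs$regions),
          nrow(mirna), nrow(mirna_calls), length(cpg_sel),
          nrow(pos_edges), length(unique(partition$membership)))
  )
  structure(
    list(study = study, diff_meth = diff_meth, dmps = dmps, dmrs = dmrs,
         diff_mirna = diff_mirna, mirna_calls = mirna_calls,
         edges = edges, pos_edges = pos_edges, graph = graph,
         partition = partition, antagonism = antagonism, recap = recap,
         coupling = coupling, qpcr_test = qpcr_test,
         enrichment = enrichment, counts = counts, seed = seed),
    class = "methmir_run"
  )
}

#' @export
print.methmir_run <- function(x, ...) {
  cat("Pipeline run (seed ", x$seed, ")\n", sep = "")
  print.data.frame(x$counts, row.names = FALSE)
  invisible(x)
}

#' Score a pipeline run against the planted truth
#'
#' Compares the artifacts of [run_pipeline()] with the generator's truth
#' record: sensitivity of DMP calls on strongly planted probes
#' (|effect| >= `strong_effect`), realized false-discovery proportion of
#' all CpG calls against the full set of truly differential probes,
#' Jaccard overlap of called vs planted DMR probe sets, direction
#' accuracy of planted differential miRNAs, adjusted Rand index between
#' detected and planted community assignments (over nodes present in the
#' partition), whether the planted antagonistic pair was flagged (and no
#' other pair), and the coupling-parameter errors.
#'
#' @param run A `"methmir_run"`.
#' @param truth The matching truth record (default: the run's own study
#'   truth).
#' @param strong_effect Effect magnitude defining the sensitivity
#'   denominator (default 1.0).
#' @return One-row data.frame of recovery metrics.
#' @export
score_recovery <- function(run, truth = run$study$truth, strong_effect = 1.0) {
  planted_strong <- names(truth$dmp_effects)[abs(truth$dmp_effects) >= strong_effect]
  called_cpg <- run$dmps$feature_id
  true_diff <- names(truth$diff_cpg_effects)
  sens <- if (length(planted_strong)) mean(planted_strong %in% called_cpg) else NA_real_
  fdp <- if (length(called_cpg)) mean(!(called_cpg %in% true_diff)) else 0

  planted_dmr_probes <- unlist(lapply(truth$dmr_regions, `[[`, "probe_ids"))
  called_dmr_probes <- unlist(run$dmrs$regions$probe_ids)
  dmr_jaccard <- if (length(planted_dmr_probes) || length(called_dmr_probes)) {
    length(intersect(planted_dmr_probes, called_dmr_probes)) /
      length(union(planted_dmr_probes, called_dmr_probes))
  } else NA_real_

  up_ok <- run$mirna_calls$feature_id[run$mirna_calls$direction > 0]
  dn_ok <- run$mirna_calls$feature_id[run$mirna_calls$direction < 0]
  planted_mir <- c(truth$mirna_up, truth$mirna_down)
  mir_acc <- if (length(planted_mir)) {
    (sum(truth$mirna_up %in% up_ok) + sum(truth$mirna_down %in% dn_ok)) /
      length(planted_mir)
  } else NA_real_

  memb <- run$partition$membership
  shared <- intersect(names(memb), names(truth$community_assignment))
  ari <- if (length(shared) >= 2L) {
    mclust::adjustedRandIndex(memb[shared], truth$community_assignment[shared])
  } else NA_real_

  ant_ok <- NA
  if (nrow(run$antagonism) > 0L && length(shared) > 0L) {
    flagged <- run$antagonism[run$antagonism$flag, , drop = FALSE]
    maps_to <- function(det_comm) {
      nodes <- intersect(names(memb)[memb == det_comm], shared)
      if (!length(nodes)) return(NA_integer_)
      as.integer(names(which.max(table(truth$community_assignment[nodes]))))
    }
    truth_pairs <- lapply(seq_len(nrow(flagged)), function(i) {
      c(maps_to(as.integer(flagged$community_a[i])),
        maps_to(as.integer(flagged$community_b[i])))
    })
    planted <- sort(as.integer(truth$antagonistic_pair))
    # judge only flagged pairs whose both sides map to planted communities;
    # flags involving other differential-feature clusters are group-coupled,
    # not spurious
    mapped <- Filter(function(p) !anyNA(p) && p[1L] != p[2L], truth_pairs)
    hit <- any(vapply(mapped, function(p) identical(sort(p), planted), logical(1L)))
    off <- any(vapply(mapped, function(p) !identical(sort(p), planted), logical(1L)))
    ant_ok <- hit && !off
  }

  cg <- run$coupling$by_group
  case <- cg[cg$group == "AD", ]
  ctrl <- cg[cg$group == "HC", ]
  data.frame(
    dmp_sensitivity = sens,
    dmp_fdp = fdp,
    dmr_jaccard = dmr_jaccard,
    mirna_direction_accuracy = mir_acc,
    community_ari = ari,
    antagonism_correct = ant_ok,
    case_rho = case$rho,
    case_slope = case$slope,
    case_r2 = case$r2,
    slope_error = case$slope - truth$il13_like$slope,
    control_slope_p = ctrl$p_slope,
    pooled_rho = run$coupling$pooled$rho
  )
}
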