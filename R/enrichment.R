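#' Assemble a query gene set
#'
#' Builds the gene list to test for over-representation: the union of
#' target genes of the selected miRNAs and, optionally, the genes
#' annotated to a set of CpG probes (slash-separated annotations are split
#' into individual symbols). miRNAs absent from the target map are skipped
#' with a message.
#'
#' @param mirnas Character vector of miRNA ids (possibly empty).
#' @param target_map Named list: miRNA -> character vector of target genes.
#' @param probe_ids Optional CpG probe ids whose annotated genes are added.
#' @param annotation Probe annotation (needed when `probe_ids` given).
#' @return Character vector of unique gene symbols.
#' @export
build_query_genes <- function(mirnas = character(0), target_map = list(),
                              probe_ids = NULL, annotation = NULL) {
  missing_mir <- setdiff(mirnas, names(target_map))
  if (length(missing_mir) > 0L) {
    message(length(missing_mir), " miRNA(s) absent from target map, skipped: ",
            paste(utils::head(missing_mir, 5L), collapse = ", "))
  }
  genes <- unlist(target_map[intersect(mirnas, names(target_map))],
                  use.names = FALSE)
  if (!is.null(probe_ids)) {
    if (is.null(annotation)) stop("annotation required when probe_ids are given")
    g <- annotation$gene[match(probe_ids, annotation$probe_id)]
    g <- g[!is.na(g) & nzchar(g)]
    genes <- c(genes, unlist(strsplit(g, "/", fixed = TRUE)))
  }
  unique(genes)
}

#' One-sided hypergeometric over-representation test
#'
#' Tests each gene set for over-representation of the query within an
#' explicit background (upper tail including the observed overlap,
#' `P[X >= k]`). Sets are intersected with the background before testing;
#' the query must be a subset of the background. The odds ratio comes from
#' the 2x2 table with a Haldane 0.5 correction when a margin is zero. BH
#' correction is applied over all tested sets.
#'
#' @param query Character vector of query gene symbols.
#' @param gene_sets Named list of gene sets (e.g. from [read_gmt()]).
#' @param background Character vector of background genes (e.g. all
#'   possible miRNA targets plus CpG-annotated genes).
#' @return data.frame sorted by p: `set_id`, `k`, `K`, `n`, `N`,
#'   `odds_ratio`, `p`, `fdr`, `overlap_genes` (list column).
#' @export
fisher_enrich <- function(query, gene_sets, background) {
  background <- unique(background)
  if (length(background) == 0L) stop("empty background")
  query <- unique(query)
  extra <- setdiff(query, background)
  if (length(extra) > 0L) stop("query genes outside the background: ",
                               paste(utils::head(extra, 5L), collapse = ", "))
  N <- length(background)
  n <- length(query)
  out <- lapply(names(gene_sets), function(sid) {
    set <- intersect(unique(gene_sets[[sid]]), background)
    K <- length(set)
    overlap <- intersect(query, set)
    k <- length(overlap)
    p <- if (K == 0L) 1 else stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    a <- k; b <- n - k; cc <- K - k; d <- N - K - n + k
    if (min(a, b, cc, d) == 0L) { a <- a + 0.5; b <- b + 0.5; cc <- cc + 0.5; d <- d + 0.5 }
    data.frame(set_id = sid, k = k, K = K, n = n, N = N,
               odds_ratio = (a * d) / (b * cc), p = p,
               overlap_genes = I(list(overlap)), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res$fdr <- bh_adjust(res$p)
  res[order(res$p, res$set_id), , drop = FALSE]
}

#' Greedy redundancy collapse of enriched sets
#'
#' Walks the results in ascending p order (ties broken by set id) and
#' keeps a set only if its member Jaccard similarity with every
#' already-kept set is below `jaccard_max`. Discarded sets keep their
#' statistics and are flagged `kept_after_redundancy = FALSE`. This is an
#' overlap-based stand-in for ontology-graph semantic filtering.
#'
#' @param results Result table from [fisher_enrich()].
#' @param gene_sets The gene-set list the results were computed from.
#' @param jaccard_max Similarity threshold (default 0.5); a set at or
#'   above this similarity with a kept set is flagged redundant.
#' @return `results` with a logical `kept_after_redundancy` column.
#' @export
collapse_redundancy <- function(results, gene_sets, jaccard_max = 0.5) {
  ord <- order(results$p, results$set_id)
  kept_ids <- character(0)
  kept <- logical(nrow(results))
  for (i in ord) {
    set <- unique(gene_sets[[results$set_id[i]]])
    redundant <- FALSE
    for (ks in kept_ids) {
      other <- unique(gene_sets[[ks]])
      jac <- length(intersect(set, other)) / length(union(set, other))
      if (jac >= jaccard_max) { redundant <- TRUE; break }
    }
    if (!redundant) {
      kept[i] <- TRUE
      kept_ids <- c(kept_ids, results$set_id[i])
    }
  }
  results$kept_after_redundancy <- kept
  results
}
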