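#' Collapse probes into clusters by genomic distance
#'
#' Single-linkage chaining per chromosome: probes are sorted by position
#' and consecutive probes join the same cluster iff their gap is at most
#' `maxgap` base pairs. The result is deterministic and invariant to the
#' input order of `probe_ids`.
#'
#' @param annotation Probe annotation (`probe_id`, `chrom`, `pos`).
#' @param probe_ids Probes to cluster (default: all annotated probes).
#' @param maxgap Maximum gap in bp joining consecutive probes (default 500).
#' @return List of character vectors of probe ids, each sorted by position.
#' @export
cluster_probes <- function(annotation, probe_ids = annotation$probe_id,
                           maxgap = 500) {
  stopifnot(maxgap > 0)
  miss <- setdiff(probe_ids, annotation$probe_id)
  if (length(miss) > 0L) {
    stop("probes missing from annotation: ", paste(utils::head(miss, 5L), collapse = ", "))
  }
  ann <- annotation[match(unique(probe_ids), annotation$probe_id), ]
  out <- list()
  for (chr in unique(ann$chrom)) {
    a <- ann[ann$chrom == chr, ]
    a <- a[order(a$pos, a$probe_id), ]
    gaps <- diff(a$pos)
    grp <- cumsum(c(1L, as.integer(gaps > maxgap)))
    out <- c(out, split(a$probe_id, grp))
  }
  names(out) <- NULL
  out
}

#' Score a probe cluster as a candidate region
#'
#' Region effect is the unweighted mean probe `logfc`; the region p-value
#' combines the probes' signed z-scores by Stouffer's method
#' (`z_i = sign(logfc_i) * qnorm(p_i / 2, lower = FALSE)`,
#' `Z = sum(z_i) / sqrt(n)`), so probes pulling in opposite directions
#' cancel rather than reinforce. A single-probe cluster keeps its probe's
#' p-value. Clusters containing opposite-sign probes are flagged
#' `heterogeneous`. Fisher's method (unsigned) is available as an
#' alternative.
#'
#' @param cluster Character vector of probe ids.
#' @param diff_table `"diff_table"` covering the probes.
#' @param annotation Probe annotation (for coordinates and gene labels).
#' @param method `"stouffer"` (default) or `"fisher"`.
#' @return One-row data.frame: `gene`, `chrom`, `start`, `width`,
#'   `n_probes`, `mean_logfc`, `p_region`, `heterogeneous`, `probe_ids`
#'   (list column).
#' @export
score_region <- function(cluster, diff_table, annotation,
                         method = c("stouffer", "fisher")) {
  method <- match.arg(method)
  idx <- match(cluster, diff_table$feature_id)
  if (anyNA(idx)) stop("cluster probe(s) absent from diff table: ",
                       paste(cluster[is.na(idx)], collapse = ", "))
  d <- diff_table[idx, ]
  a <- annotation[match(cluster, annotation$probe_id), ]
  ord <- order(a$pos)
  d <- d[ord, ]
  a <- a[ord, ]
  n <- nrow(d)
  p_region <- if (n == 1L) {
    d$p
  } else if (method == "stouffer") {
    z <- sign(d$logfc) * stats::qnorm(d$p / 2, lower.tail = FALSE)
    2 * stats::pnorm(-abs(sum(z) / sqrt(n)))
  } else {
    stats::pchisq(-2 * sum(log(d$p)), df = 2 * n, lower.tail = FALSE)
  }
  genes <- unique(a$gene[nzchar(a$gene)])
  data.frame(
    gene = if (length(genes) > 0L) paste(genes, collapse = "/") else "",
    chrom = a$chrom[1L],
    start = min(a$pos),
    width = max(a$pos) - min(a$pos) + 1L,
    n_probes = n,
    mean_logfc = mean(d$logfc),
    p_region = p_region,
    heterogeneous = length(unique(sign(d$logfc[d$logfc != 0]))) > 1L,
    probe_ids = I(list(a$probe_id)),
    stringsAsFactors = FALSE
  )
}

#' Find differentially methylated regions
#'
#' Clusters the given probes by distance, scores every candidate cluster,
#' applies BH correction across all candidates, and retains regions with
#' `p_bh < alpha` and at least `min_probes` probes, sorted by p.
#'
#' @param diff_table Probe-level `"diff_table"`.
#' @param annotation Probe annotation.
#' @param probe_ids Probes considered for clustering (default: all tested
#'   features in `diff_table`).
#' @param maxgap Distance rule in bp (default 500).
#' @param alpha BH threshold on the region p (default 0.05).
#' @param min_probes Minimum probes per reported region (default 2).
#' @param method Combination method passed to [score_region()].
#' @return List with `regions` (the called regions) and `candidates` (all
#'   scored clusters with `p_bh`).
#' @export
find_dmrs <- function(diff_table, annotation,
                      probe_ids = diff_table$feature_id[diff_table$tested],
                      maxgap = 500, alpha = 0.05, min_probes = 2L,
                      method = "stouffer") {
  clusters <- cluster_probes(annotation, probe_ids, maxgap = maxgap)
  if (length(clusters) == 0L) {
    empty <- data.frame()
    return(list(regions = empty, candidates = empty))
  }
  cand <- do.call(rbind, lapply(clusters, score_region,
                                diff_table = diff_table,
                                annotation = annotation, method = method))
  cand$p_bh <- bh_adjust(cand$p_region)
  keep <- cand$p_bh < alpha & cand$n_probes >= min_probes
  regions <- cand[keep, , drop = FALSE]
  regions <- regions[order(regions$p_region), , drop = FALSE]
  list(regions = regions, candidates = cand)
}
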