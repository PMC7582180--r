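#' Convert methylation beta-values to M-values
#'
#' `M = log2(beta / (1 - beta))`. The M scale is the analysis scale for
#' array methylation: variances are more homoscedastic, and M above +1
#' (beta > 2/3) indicates a methylated site, M below -1 a demethylated one.
#'
#' @param beta Numeric vector/matrix of methylation fractions in (0, 1).
#' @param clip If `TRUE`, values are clipped into `[eps, 1 - eps]` instead
#'   of erroring on the boundary. Off by default.
#' @param eps Clipping bound.
#' @return M-values, same shape as `beta`.
#' @export
beta_to_m <- function(beta, clip = FALSE, eps = 1e-6) {
  if (clip) {
    beta <- pmin(pmax(beta, eps), 1 - eps)
  } else if (any(beta <= 0 | beta >= 1, na.rm = TRUE)) {
    stop("beta values must lie strictly in (0, 1); use clip = TRUE to clip")
  }
  log2(beta / (1 - beta))
}

#' Convert M-values back to beta-values
#'
#' Inverse of [beta_to_m()]: `beta = 2^M / (1 + 2^M)`.
#'
#' @param m Numeric vector/matrix of M-values.
#' @return beta-values in (0, 1).
#' @export
m_to_beta <- function(m) {
  2^m / (1 + 2^m)
}

#' Filter probes by SNP overlap and gene annotation
#'
#' Removes probes flagged as overlapping a known SNP (the flag is an input
#' annotation column, never computed here) and/or probes with no gene
#' association (intergenic probes), mirroring the pre-filtering applied
#' before differential and network analysis.
#'
#' @param x Methylation matrix (probes in rows).
#' @param annotation Probe annotation covering all rows of `x`.
#' @param drop_snp Remove probes with `snp_overlap == TRUE`.
#' @param require_gene Remove probes whose `gene` annotation is empty.
#' @return List with the filtered `matrix` and a `report` data.frame
#'   (input/removed/retained counts; removals are attributed sequentially,
#'   SNP first, so they sum to `n_input - n_retained`).
#' @export
filter_probes <- function(x, annotation, drop_snp = TRUE, require_gene = FALSE) {
  missing_ann <- setdiff(rownames(x), annotation$probe_id)
  if (length(missing_ann) > 0L) {
    stop("probes missing from annotation: ",
         paste(utils::head(missing_ann, 5L), collapse = ", "),
         if (length(missing_ann) > 5L) ", ...")
  }
  ann <- annotation[match(rownames(x), annotation$probe_id), ]
  keep <- rep(TRUE, nrow(x))
  n_snp <- 0L
  if (drop_snp) {
    rm_snp <- keep & isTRUE_vec(ann$snp_overlap)
    n_snp <- sum(rm_snp)
    keep <- keep & !rm_snp
  }
  n_intergenic <- 0L
  if (require_gene) {
    rm_gene <- keep & !nzchar(ann$gene)
    n_intergenic <- sum(rm_gene)
    keep <- keep & !rm_gene
  }
  report <- data.frame(
    n_input = nrow(x),
    n_removed_snp = n_snp,
    n_removed_intergenic = n_intergenic,
    n_retained = sum(keep),
    drop_snp = drop_snp,
    require_gene = require_gene
  )
  list(matrix = x[keep, , drop = FALSE], report = report)
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Drop features with null variance
#'
#' Removes rows whose sample variance (over non-missing values) is exactly
#' zero; near-zero variance is kept. Rank-based association is undefined on
#' constant features, so they are excluded before network construction.
#'
#' @param x Feature-by-sample matrix.
#' @return The matrix without zero-variance rows.
#' @export
drop_null_variance <- function(x) {
  v <- apply(x, 1L, function(r) stats::var(r[!is.na(r)]))
  x[!is.na(v) & v > 0, , drop = FALSE]
}

#' Select top differential features by FDR
#'
#' Returns the ids of features whose BH-adjusted p falls below `fdr_cutoff`.
#' Used to pick the top varying CpG probes (default FDR < 0.1) that enter
#' the integrated network together with the full miRNA set.
#'
#' @param diff_table A differential result table with `feature_id` and
#'   `p_bh` columns.
#' @param fdr_cutoff BH-adjusted p cutoff (default 0.1).
#' @return Character vector of feature ids.
#' @export
select_top_differential <- function(diff_table, fdr_cutoff = 0.1) {
  diff_table$feature_id[!is.na(diff_table$p_bh) & diff_table$p_bh < fdr_cutoff]
}
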