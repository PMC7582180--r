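#' Comparative-Ct delta-Ct values
#'
#' `delta_ct = Ct_reference - Ct_target`, so a larger delta-Ct means a more
#' abundant target (fewer cycles needed); the fold-change view is
#' `2^delta_ct`. Technical replicates must be averaged before calling
#' this; samples with a missing reference Ct are excluded with a warning.
#'
#' @param ct_target Numeric vector of target Ct values (replicate-averaged).
#' @param ct_reference Matching reference-gene Ct values (e.g. SNORD44 for
#'   miRNA, B2M for mRNA).
#' @return Numeric vector of delta-Ct values (`NA` where the reference is
#'   missing).
#' @export
delta_ct <- function(ct_target, ct_reference) {
  stopifnot(length(ct_target) == length(ct_reference))
  bad <- !is.finite(ct_reference)
  if (any(bad)) warning(sum(bad), " sample(s) lack a reference Ct and were excluded")
  out <- ct_reference - ct_target
  out[bad] <- NA_real_
  out
}

#' Two-group comparison of delta-Ct values
#'
#' Unpaired two-sided t-test (equal-variance by default, Welch optional)
#' of delta-Ct between AD and HC, per target. Targets with fewer than 2
#' usable samples in either group are skipped with a warning.
#'
#' @param dct Matrix or data.frame of delta-Ct values, targets in rows,
#'   samples in columns; or a numeric vector for a single target.
#' @param sample_sheet Sample sheet matching the columns.
#' @param welch Use the Welch (unequal-variance) test.
#' @return data.frame: `target`, `mean_AD`, `mean_HC`, `diff` (AD - HC),
#'   `t`, `df`, `p`.
#' @export
compare_groups_delta_ct <- function(dct, sample_sheet, welch = FALSE) {
  if (is.vector(dct)) dct <- matrix(dct, nrow = 1L,
                                    dimnames = list("target", names(dct)))
  dct <- as.matrix(dct)
  ss <- validate_sample_sheet(sample_sheet)
  stopifnot(identical(colnames(dct), ss$sample_id))
  is_ad <- ss$group == "AD"
  out <- list()
  for (i in seq_len(nrow(dct))) {
    a <- dct[i, is_ad]
    h <- dct[i, !is_ad]
    a <- a[is.finite(a)]; h <- h[is.finite(h)]
    if (length(a) < 2L || length(h) < 2L) {
      warning("target '", rownames(dct)[i], "' skipped: fewer than 2 samples in a group")
      next
    }
    tt <- stats::t.test(a, h, var.equal = !welch)
    out[[length(out) + 1L]] <- data.frame(
      target = rownames(dct)[i], mean_AD = mean(a), mean_HC = mean(h),
      diff = mean(a) - mean(h), t = unname(tt$statistic),
      df = unname(tt$parameter), p = tt$p.value, stringsAsFactors = FALSE
    )
  }
  if (length(out) == 0L) return(data.frame())
  do.call(rbind, out)
}

#' Methylation-expression coupling for one CpG/gene pair
#'
#' The promoter-methylation vs transcript-abundance analysis: pooled
#' Spearman correlation between a CpG's M-values and a gene's expression
#' (delta-Ct units), per-group Spearman correlations with BH adjustment
#' over the group family, and a per-group ordinary least-squares
#' regression `expression ~ M` reporting slope (delta-Ct per M-unit), R^2
#' and the F-test p. A negative slope means lower methylation goes with
#' higher expression.
#'
#' @param m M-values for the probe, named by sample id.
#' @param expr Expression values (delta-Ct) named by sample id; samples
#'   missing either value are dropped pairwise.
#' @param sample_sheet Sample sheet covering the samples.
#' @param probe_id,gene_id Identifiers carried into the result.
#' @return List of class `"coupling_result"`: `pooled` (rho, p, n) and
#'   `by_group` data.frame (group, n, rho, p_rho, fdr_rho, slope,
#'   intercept, r2, p_slope).
#' @export
methylation_expression_coupling <- function(m, expr, sample_sheet,
                                            probe_id = "probe",
                                            gene_id = "gene") {
  ss <- validate_sample_sheet(sample_sheet)
  shared <- intersect(names(m)[is.finite(m)], names(expr)[is.finite(expr)])
  shared <- intersect(shared, ss$sample_id)
  if (length(shared) < 5L) stop("fewer than 5 shared samples for pooled coupling")
  m <- m[shared]; expr <- expr[shared]
  grp <- ss$group[match(shared, ss$sample_id)]
  ct_pool <- stats::cor.test(m, expr, method = "spearman", exact = FALSE)
  by_group <- list()
  for (g in levels(grp)) {
    idx <- grp == g
    n <- sum(idx)
    if (n < 4L) {
      by_group[[g]] <- data.frame(group = g, n = n, rho = NA_real_,
                                  p_rho = NA_real_, slope = NA_real_,
                                  intercept = NA_real_, r2 = NA_real_,
                                  p_slope = NA_real_)
      next
    }
    ct <- stats::cor.test(m[idx], expr[idx], method = "spearman", exact = FALSE)
    fit <- stats::lm(expr[idx] ~ m[idx])
    sm <- summary(fit)
    p_slope <- if (is.null(sm$fstatistic)) NA_real_ else
      stats::pf(sm$fstatistic[1L], sm$fstatistic[2L], sm$fstatistic[3L],
                lower.tail = FALSE)
    by_group[[g]] <- data.frame(
      group = g, n = n, rho = unname(ct$estimate), p_rho = ct$p.value,
      slope = unname(stats::coef(fit)[2L]),
      intercept = unname(stats::coef(fit)[1L]),
      r2 = sm$r.squared, p_slope = unname(p_slope)
    )
  }
  bg <- do.call(rbind, by_group)
  rownames(bg) <- NULL
  bg$fdr_rho <- bh_adjust(bg$p_rho)
  structure(
    list(probe_id = probe_id, gene_id = gene_id,
         pooled = data.frame(rho = unname(ct_pool$estimate),
                             p = ct_pool$p.value, n = length(shared)),
         by_group = bg),
    class = "coupling_result"
  )
}

#' @export
print.coupling_result <- function(x, ...) {
  cat("Coupling ", x$probe_id, " ~ ", x$gene_id, ": pooled Spearman rho = ",
      format(signif(x$pooled$rho, 3)), " (p = ",
      format(signif(x$pooled$p, 3)), ", n = ", x$pooled$n, ")\n", sep = "")
  print.data.frame(x$by_group, digits = 3)
  invisible(x)
}
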