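#' Bundled reference table of differentially methylated probes
#'
#' Loads the packaged table of 49 CpG probes with significant (BH p < 0.05)
#' DNA methylation differences between circulating CD4+CLA+ T cells of adult
#' atopic dermatitis patients and healthy controls: probe id, hg19
#' coordinate and strand, gene annotation (possibly empty or
#' slash-separated for probes between two genes), CpG-island relation,
#' regulatory flags, the AD-minus-HC M-value difference (`logfc`), and raw
#' and BH-adjusted p-values. 37 probes are hypomethylated and 12
#' hypermethylated in patients.
#'
#' @return data.frame with 49 rows.
#' @export
load_cla_dmps <- function() {
  path <- system.file("extdata", "cla_dmps.tsv", package = "methmir",
                      mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = character(0))
  tab$direction <- sign(tab$logfc)
  stopifnot(nrow(tab) == 49L, !anyDuplicated(tab$probe_id))
  tab
}

#' Bundled reference table of differentially methylated regions
#'
#' Loads the packaged table of 7 hypomethylated regions over 5 genes
#' (GPR55, MAN1A1, ESR1, CDHR3, NCOR2) obtained by collapsing nearby
#' probes by genomic distance in the same CD4+CLA+ T-cell comparison.
#' Coordinates are 1-based; `width` is in base pairs (max - min + 1).
#'
#' @param split_probes If `TRUE` (default) the `probe_ids` column is a list
#'   column of probe-id vectors; if `FALSE` the raw semicolon-joined string
#'   is kept.
#' @return data.frame with 7 rows.
#' @export
load_cla_dmrs <- function(split_probes = TRUE) {
  path <- system.file("extdata", "cla_dmrs.tsv", package = "methmir",
                      mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(nrow(tab) == 7L)
  probes <- strsplit(tab$probe_ids, ";", fixed = TRUE)
  stopifnot(all(lengths(probes) == tab$n_probes))
  if (split_probes) tab$probe_ids <- probes
  tab
}

#' Count distinct differentially methylated genes
#'
#' Counts the distinct gene annotations among DMP records and, optionally,
#' their union with DMR genes. Two counting conventions exist for probes
#' annotated to two genes with a slash (for example "MCART6/ZCCHC18"):
#' as a single annotation string (`split_slash = FALSE`) or as two gene
#' symbols (`split_slash = TRUE`).
#'
#' @param dmps DMP table with a `gene` column (default: the bundled table).
#' @param dmrs Optional DMR table with a `gene` column whose genes are
#'   added to the union.
#' @param split_slash Split slash-separated annotations into symbols.
#' @return Integer count of distinct nonempty gene annotations.
#' @export
count_diff_genes <- function(dmps = load_cla_dmps(), dmrs = NULL,
                             split_slash = FALSE) {
  genes <- dmps$gene[nzchar(dmps$gene)]
  if (split_slash) genes <- unlist(strsplit(genes, "/", fixed = TRUE))
  if (!is.null(dmrs)) genes <- c(genes, dmrs$gene[nzchar(dmrs$gene)])
  length(unique(genes))
}
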