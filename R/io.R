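#' Read a feature-by-sample matrix from tab-separated text
#'
#' Parses a TSV whose first column holds feature identifiers (CpG probe ids,
#' miRNA names, or gene symbols) and whose header row holds sample ids.
#' Non-numeric cells become `NA` and are counted in the `n_missing`
#' attribute; nothing is imputed.
#'
#' @param path Path to a tab-separated text file.
#' @param scale Declared scale/layer of the values: `"M"` or `"beta"` for
#'   methylation, or an expression layer tag such as `"mirna"`,
#'   `"mrna_qpcr"`. Stored as the `"scale"` attribute. Values declared
#'   `"beta"` are checked to lie in (0, 1).
#' @return A numeric matrix with feature rownames and sample colnames, with
#'   attributes `scale` and `n_missing`.
#' @export
read_feature_matrix <- function(path, scale = "M") {
  lines <- readLines(path)
  if (length(lines) == 0L) stop("empty matrix file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  ncol_expected <- length(header)
  body <- fields[-1L]
  bad <- which(lengths(body) != ncol_expected)
  if (length(bad) > 0L) {
    stop("ragged row at line ", bad[1L] + 1L, " of ", path,
         " (expected ", ncol_expected, " fields, found ",
         length(body[[bad[1L]]]), ")")
  }
  ids <- vapply(body, `[[`, character(1L), 1L)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    stop("duplicated feature id(s) in ", path, ": ",
         paste(dup, collapse = ", "))
  }
  vals <- suppressWarnings(
    vapply(body, function(f) as.numeric(f[-1L]), numeric(ncol_expected - 1L))
  )
  x <- if (is.null(dim(vals))) matrix(vals, nrow = length(body), byrow = TRUE) else t(vals)
  dimnames(x) <- list(ids, header[-1L])
  if (identical(scale, "beta")) {
    v <- x[is.finite(x)]
    if (any(v <= 0 | v >= 1)) {
      stop("values declared scale='beta' must lie strictly in (0, 1)")
    }
  }
  attr(x, "scale") <- scale
  attr(x, "n_missing") <- sum(is.na(x))
  x
}

#' Write a feature-by-sample matrix as tab-separated text
#'
#' Inverse of [read_feature_matrix()]: first column `feature_id`, header row
#' of sample ids. Values are written with full double precision so that a
#' write/read round trip is lossless to at least 12 decimal digits.
#'
#' @param x Numeric matrix with rownames and colnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(x, path) {
  stopifnot(is.matrix(x), !is.null(rownames(x)), !is.null(colnames(x)))
  header <- paste(c("feature_id", colnames(x)), collapse = "\t")
  rows <- vapply(seq_len(nrow(x)), function(i) {
    paste(c(rownames(x)[i], formatC(x[i, ], format = "g", digits = 17)),
          collapse = "\t")
  }, character(1L))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read a sample sheet
#'
#' Expects columns `sample_id`, `group`, `age`, and optionally `subject_id`.
#' Group labels must be `AD` (cases) or `HC` (controls).
#'
#' @param path TSV path.
#' @return A data.frame with `group` as a factor with levels `HC`, `AD`
#'   (so the AD-vs-HC contrast is the second level's coefficient).
#' @export
read_sample_sheet <- function(path) {
  ss <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_sample_sheet(ss)
}

#' @keywords internal
validate_sample_sheet <- function(ss) {
  need <- c("sample_id", "group", "age")
  miss <- setdiff(need, names(ss))
  if (length(miss) > 0L) stop("sample sheet lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(ss$sample_id)) stop("duplicated sample_id in sample sheet")
  if (!all(ss$group %in% c("AD", "HC"))) stop("group labels must be 'AD' or 'HC'")
  if (any(!is.finite(ss$age)) || any(ss$age < 0)) stop("age must be nonnegative and finite")
  ss$group <- factor(ss$group, levels = c("HC", "AD"))
  ss
}

#' Read a probe annotation table
#'
#' Columns: `probe_id`, `chrom`, `pos` (1-based), `strand`, `gene` (possibly
#' empty or slash-separated), `island_relation`, and logical `enhancer`,
#' `dhs`, `snp_overlap` flags (missing flag columns default to `FALSE`).
#'
#' @param path TSV path.
#' @return data.frame of probe annotation.
#' @export
read_probe_annotation <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = character(0))
  need <- c("probe_id", "chrom", "pos")
  miss <- setdiff(need, names(ann))
  if (length(miss) > 0L) stop("annotation lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(ann$probe_id)) stop("duplicated probe_id in annotation")
  if (any(ann$pos <= 0)) stop("probe positions must be positive 1-based coordinates")
  if (any(!nzchar(ann$chrom))) stop("chrom must be nonempty")
  for (fl in c("enhancer", "dhs", "snp_overlap")) {
    if (is.null(ann[[fl]])) ann[[fl]] <- FALSE else ann[[fl]] <- as.logical(ann[[fl]])
  }
  if (is.null(ann$gene)) ann$gene <- ""
  ann
}

#' Read gene sets in GMT format
#'
#' One set per line: set id, description, then tab-separated member symbols.
#' Duplicate members within a line are dropped.
#'
#' @param path GMT path.
#' @return Named list of character vectors; each element carries a
#'   `description` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(structure(list(), names = character(0)))
  out <- vector("list", length(lines))
  ids <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) stop("GMT line ", i, " has fewer than 3 columns")
    members <- unique(f[-(1:2)])
    members <- members[nzchar(members)]
    if (length(members) == 0L) stop("GMT line ", i, " defines an empty set")
    ids[i] <- f[1L]
    out[[i]] <- structure(members, description = f[2L])
  }
  if (anyDuplicated(ids)) stop("duplicated set ids in GMT")
  names(out) <- ids
  out
}

#' Read a miRNA-to-target-gene map
#'
#' Two-column TSV (`mirna`, `gene`), one target per row; collapsed to a
#' named list of unique target sets. Empty target sets are never stored.
#'
#' @param path TSV path.
#' @return Named list: miRNA id -> character vector of target gene symbols.
#' @export
read_target_map <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("mirna", "gene") %in% names(tab))) {
    stop("target map needs columns 'mirna' and 'gene'")
  }
  tab <- tab[nzchar(tab$gene), , drop = FALSE]
  lapply(split(tab$gene, tab$mirna), unique)
}

#' Write differentially methylated regions as BED
#'
#' Internal coordinates are 1-based inclusive (as in array annotation
#' tables); BED uses 0-based half-open intervals, so a region starting at
#' `start` with width `w` becomes `[start - 1, start - 1 + w)`. The score
#' column carries the BH-adjusted region p scaled to 0-1000
#' (`round(-10 * log10(p_bh))`, capped).
#'
#' @param regions data.frame with `chrom`, `start`, `width`, `gene`, and
#'   optionally `p_bh`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  if (nrow(regions) == 0L) {
    writeLines("# chrom\tstart\tend\tname\tscore", path)
    return(invisible(path))
  }
  if (any(regions$width <= 0)) stop("region width must be positive")
  score <- if (is.null(regions$p_bh)) 0L else
    pmin(1000L, as.integer(round(-10 * log10(pmax(regions$p_bh, 1e-100)))))
  bed <- data.frame(
    chrom = regions$chrom,
    start = regions$start - 1L,
    end = regions$start - 1L + regions$width,
    name = if (is.null(regions$gene)) "." else regions$gene,
    score = score
  )
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a network edge table as TSV
#'
#' @param edges Edge data.frame (as produced by [spearman_all_pairs()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(edges, path) {
  utils::write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a community graph as GraphML
#'
#' @param graph An igraph object (e.g. from [build_network_graph()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(graph, path) {
  igraph::write_graph(graph, path, format = "graphml")
  invisible(path)
}
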