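# Expression-side computations: normalisation, fold changes,
# methylation-expression correlation and gene-set enrichment.

#' Quantile normalisation of an expression matrix
#'
#' Forces every column (sample) to the same distribution: each column's
#' sorted values are replaced by the across-column means of the sorted
#' values at each rank; tied values receive the mean of the reference
#' values over their rank range.  Standard normalisation for RPKM tables
#' before cross-sample comparisons.
#'
#' @param x numeric matrix (genes x samples), no negative values; at
#'   least two columns.
#' @return Matrix of the same shape and dimnames.
#' @export
quantile_normalize <- function(x) {
  x <- as.matrix(x)
  stopifnot(ncol(x) >= 2L, !anyNA(x))
  if (any(x < 0)) stop("expression values must be non-negative")
  ref <- rowMeans(apply(x, 2L, sort))
  out <- apply(x, 2L, function(col) {
    o <- order(col)
    res <- numeric(length(col))
    sorted <- col[o]
    runs <- rle(sorted)
    stops <- cumsum(runs$lengths)
    starts <- stops - runs$lengths + 1L
    vals <- vapply(seq_along(runs$values), function(i) {
      mean(ref[starts[i]:stops[i]])
    }, numeric(1))
    res[o] <- rep(vals, runs$lengths)
    res
  })
  dimnames(out) <- dimnames(x)
  out
}

#' Per-gene log2 fold change between group means
#'
#' `log2(mean(case) / mean(control))` per gene, with means taken over the
#' replicate columns of each group.  Genes whose group mean is zero are
#' flagged rather than reported as infinite, unless a pseudocount is
#' supplied.
#'
#' @param x numeric matrix (genes x samples) with column names.
#' @param case,control column names (or indices) of the two groups.
#' @param pseudocount value added to both means before the ratio
#'   (default 0: zero means are flagged as `NA`).
#' @return data.frame with `gene`, `mean_case`, `mean_control`, `log2fc`,
#'   `flagged`.
#' @export
log2_group_fold_change <- function(x, case, control, pseudocount = 0) {
  x <- as.matrix(x)
  stopifnot(length(case) >= 1L, length(control) >= 1L)
  mc <- rowMeans(x[, case, drop = FALSE])
  mn <- rowMeans(x[, control, drop = FALSE])
  num <- mc + pseudocount
  den <- mn + pseudocount
  ok <- num > 0 & den > 0
  data.frame(
    gene = if (is.null(rownames(x))) as.character(seq_len(nrow(x)))
    else rownames(x),
    mean_case = mc, mean_control = mn,
    log2fc = ifelse(ok, log2(num / den), NA_real_),
    flagged = !ok,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Correlation between methylation change and expression change
#'
#' Pearson product-moment correlation between per-gene methylation
#' differences (percentage points, case minus control) and expression
#' log2 fold changes.  Promoter hypermethylation that represses
#' transcription appears as a negative correlation.
#'
#' @param delta_meth numeric vector of methylation differences.
#' @param log2fc numeric vector of expression log2 fold changes, same
#'   genes and order.
#' @return list with `r`, `n`, and the two-sided `p` of the correlation
#'   test.
#' @export
meth_expr_correlation <- function(delta_meth, log2fc) {
  stopifnot(length(delta_meth) == length(log2fc))
  keep <- !is.na(delta_meth) & !is.na(log2fc)
  delta_meth <- delta_meth[keep]
  log2fc <- log2fc[keep]
  if (length(delta_meth) < 3L) {
    stop("insufficient data: need >= 3 paired genes")
  }
  if (stats::sd(delta_meth) == 0 || stats::sd(log2fc) == 0) {
    stop("correlation undefined: constant vector")
  }
  ct <- stats::cor.test(delta_meth, log2fc, method = "pearson")
  list(r = unname(ct$estimate), n = length(delta_meth),
       p = ct$p.value)
}

#' Hypergeometric gene-set enrichment
#'
#' Upper-tail hypergeometric test of a query gene list against each gene
#' set, within a stated universe, with Benjamini-Hochberg adjustment
#' across sets.  A generic replacement for database-backed GO or
#' regulatory-feature enrichment: supply any named list of gene sets
#' (e.g. read from a GMT file with [read_gmt()]).
#'
#' @param query character vector of genes; must be a subset of
#'   `universe`.
#' @param gene_sets named list of character vectors; each set is
#'   intersected with the universe before testing.
#' @param universe character vector of all considered genes (e.g. all
#'   genes with a scored promoter).
#' @return data.frame sorted by p-value with `term`, `k` (hits), `K`
#'   (set size in universe), `n` (query size), `N` (universe size), `p`,
#'   `fdr`, and the hit genes.
#' @export
hypergeom_enrichment <- function(query, gene_sets, universe) {
  query <- unique(query)
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe")
  if (length(query) == 0L) stop("empty query")
  if (!all(query %in% universe)) {
    stop("query genes outside the universe: ",
         paste(head(base::setdiff(query, universe), 5), collapse = ", "))
  }
  if (length(gene_sets) == 0L) stop("no gene sets supplied")
  n <- length(query)
  N <- length(universe)
  rows <- lapply(names(gene_sets), function(term) {
    set <- intersect(unique(gene_sets[[term]]), universe)
    K <- length(set)
    hit <- intersect(query, set)
    k <- length(hit)
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = term, k = k, K = K, n = n, N = N, p = p,
               genes = paste(sort(hit), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- p.adjust(out$p, method = "BH")
  out <- out[order(out$p, out$term), c("term", "k", "K", "n", "N", "p",
                                       "fdr", "genes")]
  rownames(out) <- NULL
  out
}

#' Read gene sets from a GMT file
#'
#' GMT: one set per line, tab-separated: set name, description, genes.
#'
#' @param path path to the GMT file.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t", fixed = TRUE), function(f) {
    if (length(f) < 3L) stop("malformed GMT line: ", f[1])
    unique(f[-(1:2)])
  })
  names(sets) <- vapply(strsplit(lines, "\t", fixed = TRUE), `[`,
                        character(1), 1L)
  sets
}

#' Read an RPKM expression table
#'
#' Tab-separated, header row of sample names, first column gene symbols.
#'
#' @param path path to the table.
#' @return Numeric matrix, genes x samples.
#' @export
read_expression_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  genes <- tab[[1]]
  if (anyDuplicated(genes)) stop("duplicate gene ids in expression table")
  m <- as.matrix(tab[-1])
  if (!is.numeric(m)) stop("non-numeric expression values")
  if (any(m < 0)) stop("negative expression values")
  rownames(m) <- genes
  m
}
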