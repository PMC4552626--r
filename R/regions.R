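# Annotation model and region-level methylation scoring.
#
# All intervals are 0-based half-open [start, end).  CpG positions from
# methylomes are 1-based and converted on the fly when intersecting with
# intervals.

.interval_df <- function(chrom = character(), start = integer(),
                         end = integer(), name = character(),
                         strand = NULL) {
  df <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                   end = as.numeric(end),
                   name = as.character(name), stringsAsFactors = FALSE)
  if (!is.null(strand)) df$strand <- as.character(strand)
  if (nrow(df) > 0L && any(df$start >= df$end)) {
    stop("invalid interval: start must be < end")
  }
  df
}

.as_granges <- function(df) {
  if (nrow(df) == 0L) return(GRanges())
  GRanges(df$chrom, IRanges(df$start + 1L, df$end))
}

.from_granges <- function(gr, name = "region") {
  if (length(gr) == 0L) return(.interval_df())
  .interval_df(as.character(seqnames(gr)), start(gr) - 1L, end(gr),
               if (length(name) == length(gr)) name
               else sprintf("%s_%d", name, seq_along(gr)))
}

#' Read a BED file
#'
#' Reads BED3-BED6 (0-based half-open, no header) into an interval table.
#'
#' @param path path to a BED file.
#' @return data.frame with columns `chrom`, `start`, `end`, `name`
#'   (and `score`, `strand` when present).
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  names(raw) <- cols[seq_len(min(ncol(raw), 6L))]
  if (is.null(raw$name)) raw$name <- sprintf("%s:%d-%d", raw$chrom,
                                             raw$start, raw$end)
  raw
}

#' Write an interval table as BED
#'
#' @param df interval data.frame (`chrom`, `start`, `end`, optionally
#'   `name`, `score`, `strand`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path) {
  out <- data.frame(chrom = df$chrom, start = df$start, end = df$end,
                    name = if (is.null(df$name)) "." else df$name,
                    score = if (is.null(df$score)) 0 else df$score,
                    strand = if (is.null(df$strand)) "." else df$strand)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a gene table
#'
#' Reads a refFlat-like tab-separated gene table with a header and at least
#' the columns `gene`, `chrom`, `strand`, `txStart`, `txEnd` (transcript
#' bounds, 0-based half-open).
#'
#' @param path path to the gene table.
#' @return data.frame of genes.
#' @export
read_gene_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  genes <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  required <- c("gene", "chrom", "strand", "txStart", "txEnd")
  missing_cols <- base::setdiff(required, names(genes))
  if (length(missing_cols) > 0L) {
    stop("gene table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  genes
}

#' Build the annotation model
#'
#' Derives the region sets used throughout the package from a gene table
#' and optional BED-style interval tables:
#'
#' * promoters: `(offsets[1], offsets[2])` around each gene's TSS, default
#'   `(-2000, +1000)`, i.e. 3000 bp windows.  For minus-strand genes the
#'   TSS is `txEnd` and the offsets are mirrored.  Promoters sharing
#'   identical coordinates (bidirectional gene pairs) are collapsed to one
#'   interval whose `genes` field lists all gene symbols.
#' * CpG shores: 2000 bp flanks on each side of every CpG island, with any
#'   island overlap subtracted.
#' * introns: gene span minus exons, when an exon set is given.
#' * iLADs: complement of the LADs within chromosome bounds.
#'
#' Chromosome bounds come from `chrom_sizes` when supplied, otherwise from
#' the largest coordinate seen on each chromosome.
#'
#' @param genes gene table (see [read_gene_table()]).
#' @param islands,lads,exons optional interval data.frames
#'   (`chrom`, `start`, `end`, optionally `name`).
#' @param chrom_sizes optional named vector of chromosome lengths (bp).
#' @param promoter_offsets integer pair `(upstream, downstream)` relative
#'   to the TSS, upstream negative; must satisfy `upstream < downstream`.
#' @return An object of class `annotation_model`: a list of interval
#'   data.frames (`promoters`, `cpg_islands`, `cpg_shores`, `exons`,
#'   `introns`, `lads`, `ilads`), the `genes` table and `chrom_sizes`.
#' @examples
#' genes <- data.frame(gene = "G1", chrom = "chr1", strand = "+",
#'                     txStart = 10000, txEnd = 20000)
#' ann <- build_annotation(genes)
#' ann$promoters  # [8000, 11000)
#' @export
build_annotation <- function(genes, islands = NULL, lads = NULL,
                             exons = NULL, chrom_sizes = NULL,
                             promoter_offsets = c(-2000L, 1000L)) {
  stopifnot(length(promoter_offsets) == 2L,
            promoter_offsets[1] < promoter_offsets[2])
  required <- c("gene", "chrom", "strand", "txStart", "txEnd")
  missing_cols <- base::setdiff(required, names(genes))
  if (length(missing_cols) > 0L) {
    stop("gene table lacks columns: ", paste(missing_cols, collapse = ", "))
  }

  known_chroms <- unique(c(genes$chrom, islands$chrom, lads$chrom,
                           exons$chrom, names(chrom_sizes)))
  for (nm in c("islands", "lads", "exons")) {
    df <- get(nm)
    if (!is.null(df) && nrow(df) > 0L) {
      off <- base::setdiff(unique(df$chrom), c(genes$chrom,
                                               names(chrom_sizes)))
      if (length(off) > 0L && !is.null(chrom_sizes)) {
        stop("chromosomes in ", nm, " absent from gene table/sizes: ",
             paste(off, collapse = ", "))
      }
    }
  }
  if (is.null(chrom_sizes)) {
    chrom_sizes <- vapply(known_chroms, function(ch) {
      max(0, genes$txEnd[genes$chrom == ch] + abs(promoter_offsets[1]),
          islands$end[islands$chrom == ch] + 2000,
          lads$end[lads$chrom == ch], exons$end[exons$chrom == ch])
    }, numeric(1))
  }

  ## strand-aware promoters
  if (nrow(genes) > 0L) {
    tss <- ifelse(genes$strand == "-", genes$txEnd, genes$txStart)
    p_start <- ifelse(genes$strand == "-", tss - promoter_offsets[2],
                      tss + promoter_offsets[1])
    p_end <- ifelse(genes$strand == "-", tss - promoter_offsets[1],
                    tss + promoter_offsets[2])
    p_start <- pmax(p_start, 0)
    p_end <- pmin(p_end, chrom_sizes[genes$chrom])
    key <- paste(genes$chrom, p_start, p_end)
    first <- !duplicated(key)
    promoters <- .interval_df(genes$chrom[first], p_start[first],
                              p_end[first],
                              vapply(key[first], function(k) {
                                paste(genes$gene[key == k], collapse = ",")
                              }, character(1)))
    names(promoters)[names(promoters) == "name"] <- "genes"
    promoters$name <- sprintf("%s:%d-%d", promoters$chrom,
                              as.integer(promoters$start),
                              as.integer(promoters$end))
  } else {
    promoters <- .interval_df()
    promoters$genes <- character()
  }

  ## CpG shores: 2 kb flanks minus any island overlap
  if (!is.null(islands) && nrow(islands) > 0L) {
    isl <- .interval_df(islands$chrom, islands$start, islands$end,
                        if (is.null(islands$name))
                          sprintf("island_%d", seq_len(nrow(islands)))
                        else islands$name)
    left <- .interval_df(isl$chrom, pmax(isl$start - 2000, 0), isl$start,
                         paste0(isl$name, "_shoreL"))
    right <- .interval_df(isl$chrom, isl$end,
                          pmin(isl$end + 2000, chrom_sizes[isl$chrom]),
                          paste0(isl$name, "_shoreR"))
    shore_gr <- GenomicRanges::setdiff(.as_granges(rbind(left, right)),
                                       .as_granges(isl))
    shores <- .from_granges(shore_gr, "shore")
  } else {
    isl <- .interval_df()
    shores <- .interval_df()
  }

  ## introns: gene span minus exons
  if (!is.null(exons) && nrow(exons) > 0L) {
    ex <- .interval_df(exons$chrom, exons$start, exons$end,
                       if (is.null(exons$name))
                         sprintf("exon_%d", seq_len(nrow(exons)))
                       else exons$name)
    span <- .interval_df(genes$chrom, genes$txStart, genes$txEnd,
                         genes$gene)
    intron_gr <- GenomicRanges::setdiff(.as_granges(span), .as_granges(ex))
    introns <- .from_granges(intron_gr, "intron")
  } else {
    ex <- .interval_df()
    introns <- .interval_df()
  }

  ## iLADs: complement of LADs within chromosome bounds
  if (!is.null(lads) && nrow(lads) > 0L) {
    lad <- .interval_df(lads$chrom, lads$start, lads$end,
                        if (is.null(lads$name))
                          sprintf("LAD_%d", seq_len(nrow(lads)))
                        else lads$name)
  } else {
    lad <- .interval_df()
  }
  bounds <- .interval_df(names(chrom_sizes), 0, chrom_sizes,
                         names(chrom_sizes))
  bounds <- bounds[bounds$end > 0, , drop = FALSE]
  ilad_gr <- GenomicRanges::setdiff(.as_granges(bounds), .as_granges(lad))
  ilads <- .from_granges(ilad_gr, "iLAD")

  structure(
    list(promoters = promoters, cpg_islands = isl, cpg_shores = shores,
         exons = ex, introns = introns, lads = lad, ilads = ilads,
         genes = genes, chrom_sizes = chrom_sizes),
    class = "annotation_model"
  )
}

#' @export
print.annotation_model <- function(x, ...) {
  cat("annotation_model over", length(x$chrom_sizes), "chromosome(s):\n")
  for (cls in c("promoters", "cpg_islands", "cpg_shores", "exons",
                "introns", "lads", "ilads")) {
    cat(sprintf("  %-12s %d intervals\n", cls, nrow(x[[cls]])))
  }
  invisible(x)
}

.score_intervals <- function(m, intervals, min_cpgs = 3L,
                             min_coverage = 20L) {
  calls <- m$calls[m$calls$coverage >= min_coverage, , drop = FALSE]
  n_reg <- nrow(intervals)
  out <- data.frame(chrom = intervals$chrom,
                    start = intervals$start, end = intervals$end,
                    name = if (is.null(intervals$name))
                      sprintf("%s:%d-%d", intervals$chrom,
                              as.integer(intervals$start),
                              as.integer(intervals$end))
                    else intervals$name,
                    n_cpgs = 0L, meth_c = 0, total_c = 0,
                    percent = NA_real_, stringsAsFactors = FALSE)
  if (n_reg > 0L && nrow(calls) > 0L) {
    cpg_gr <- GRanges(calls$chrom, IRanges(calls$pos, width = 1L))
    hits <- findOverlaps(cpg_gr, .as_granges(intervals))
    if (length(hits) > 0L) {
      reg <- subjectHits(hits)
      cpg <- queryHits(hits)
      out$n_cpgs <- tabulate(reg, n_reg)
      out$meth_c <- as.vector(rowsum(calls$count_m[cpg], reg,
                                     reorder = TRUE))[
        match(seq_len(n_reg), sort(unique(reg)))]
      out$total_c <- as.vector(rowsum(calls$coverage[cpg], reg,
                                      reorder = TRUE))[
        match(seq_len(n_reg), sort(unique(reg)))]
      out$meth_c[is.na(out$meth_c)] <- 0
      out$total_c[is.na(out$total_c)] <- 0
      out$percent <- ifelse(out$total_c > 0,
                            100 * out$meth_c / out$total_c, NA_real_)
    }
  }
  keep <- out$n_cpgs >= min_cpgs
  res <- out[keep, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "n_skipped") <- sum(!keep)
  res
}

#' Score methylation over a single region
#'
#' Pools methylated and total cytosine counts over the CpGs inside
#' `[start, end)` that pass the coverage filter.  The region percent is
#' `100 * meth_c / total_c` — the percentage of methylated cytosines over
#' all covered cytosines in the region, i.e. the coverage-weighted mean of
#' the per-CpG percents, not their unweighted mean.  A region with fewer
#' than `min_cpgs` passing CpGs is not scored (returns `NULL`), rather
#' than scored as zero.
#'
#' @param m a [methylome()].
#' @param interval one-row data.frame (or list) with `chrom`, `start`,
#'   `end` (0-based half-open) and optionally `name`.
#' @param min_cpgs minimum passing CpGs required to score the region
#'   (default 3).
#' @param min_coverage minimum per-CpG coverage (default 20).
#' @return One-row data.frame with `chrom`, `start`, `end`, `name`,
#'   `n_cpgs`, `meth_c`, `total_c`, `percent`, or `NULL` if the region
#'   cannot be scored.
#' @export
score_region <- function(m, interval, min_cpgs = 3L, min_coverage = 20L) {
  stopifnot(is(m, "methylome"))
  iv <- .interval_df(interval$chrom, interval$start, interval$end,
                     if (is.null(interval$name))
                       sprintf("%s:%d-%d", interval$chrom,
                               as.integer(interval$start),
                               as.integer(interval$end))
                     else interval$name)
  res <- .score_intervals(m, iv, min_cpgs = min_cpgs,
                          min_coverage = min_coverage)
  if (nrow(res) == 0L) NULL else res
}

#' Score methylation over every region of a feature class
#'
#' @param m a [methylome()].
#' @param annotation an [build_annotation()] model.
#' @param class_name one of `"promoters"`, `"cpg_islands"`,
#'   `"cpg_shores"`, `"exons"`, `"introns"`, `"lads"`, `"ilads"`.
#' @inheritParams score_region
#' @return data.frame of scored regions (one row per region with at least
#'   `min_cpgs` passing CpGs).  The number of regions skipped for lack of
#'   data is attached as attribute `"n_skipped"`.
#' @export
score_feature_class <- function(m, annotation, class_name,
                                min_cpgs = 3L, min_coverage = 20L) {
  stopifnot(is(m, "methylome"), is(annotation, "annotation_model"))
  valid <- c("promoters", "cpg_islands", "cpg_shores", "exons",
             "introns", "lads", "ilads")
  if (!class_name %in% valid) {
    stop("unknown feature class '", class_name, "'; valid classes: ",
         paste(valid, collapse = ", "))
  }
  .score_intervals(m, annotation[[class_name]], min_cpgs = min_cpgs,
                   min_coverage = min_coverage)
}

#' Write a region-methylation table
#'
#' @param scores data.frame from [score_feature_class()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_region_scores <- function(scores, path) {
  write.table(scores, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
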