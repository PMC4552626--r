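# Per-CpG methylation calling from cytosine count reports.
#
# Coordinates: cytosine reports are 1-based (as written by bisulfite
# aligners); all interval sets elsewhere in the package are 0-based
# half-open (BED convention).  Base-quality filtering (Phred >= 20) is
# assumed to have been applied upstream, during read processing, so the
# counts in a report are taken at face value.

.CPG_CONTEXTS <- c("CpG", "CG")
.NONCPG_CONTEXTS <- c("CHG", "CHH")

#' Construct a sample methylome from per-CpG calls
#'
#' A `methylome` holds one sample's filtered per-CpG methylation calls
#' together with the filter settings that produced them.  Percent
#' methylation is always `100 * count_m / (count_m + count_u)`.
#'
#' @param calls data.frame with columns `chrom`, `pos` (1-based), `strand`
#'   (`"+"`/`"-"`), `count_m`, `count_u`.
#' @param sample_id sample identifier.
#' @param group group label (e.g. `"T21"` or `"Normal"`).
#' @param min_coverage minimum read coverage recorded as having been
#'   applied to `calls`.
#' @param destranded logical; whether CpG dyads have been merged.
#' @return An object of class `methylome`: a list with elements `calls`
#'   (data.frame with added `coverage` and `percent` columns), `sample_id`,
#'   `group`, `min_coverage` and `destranded`.
#' @seealso [read_cytosine_report()], [as_methylome()]
#' @export
methylome <- function(calls, sample_id = NA_character_,
                      group = NA_character_, min_coverage = 1L,
                      destranded = FALSE) {
  required <- c("chrom", "pos", "strand", "count_m", "count_u")
  missing_cols <- base::setdiff(required, names(calls))
  if (length(missing_cols) > 0L) {
    stop("'calls' lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  calls <- as.data.frame(calls)[required]
  if (nrow(calls) > 0L) {
    if (any(calls$count_m < 0 | calls$count_u < 0)) {
      stop("negative counts in methylation calls")
    }
    if (!all(calls$strand %in% c("+", "-"))) {
      stop("strand must be '+' or '-'")
    }
    dup <- duplicated(calls[c("chrom", "pos", "strand")])
    if (any(dup)) {
      stop("duplicate (chrom, pos, strand) records; first at row ",
           which(dup)[1L])
    }
  }
  calls$coverage <- calls$count_m + calls$count_u
  calls$percent <- ifelse(calls$coverage > 0,
                          100 * calls$count_m / calls$coverage, NA_real_)
  calls <- calls[order(calls$chrom, calls$pos, calls$strand), ,
                 drop = FALSE]
  rownames(calls) <- NULL
  structure(
    list(calls = calls, sample_id = sample_id, group = group,
         min_coverage = as.integer(min_coverage),
         destranded = isTRUE(destranded)),
    class = "methylome"
  )
}

#' @export
print.methylome <- function(x, ...) {
  cat("methylome: ", x$sample_id,
      if (!is.na(x$group)) paste0(" (", x$group, ")"), "\n",
      "  ", nrow(x$calls), " CpG calls at coverage >= ", x$min_coverage,
      if (x$destranded) ", destranded", "\n", sep = "")
  invisible(x)
}

.validate_report <- function(report) {
  required <- c("chrom", "pos", "strand", "count_m", "count_u", "context")
  missing_cols <- base::setdiff(required, names(report))
  if (length(missing_cols) > 0L) {
    stop("cytosine report lacks columns: ",
         paste(missing_cols, collapse = ", "))
  }
  report
}

#' Convert a raw cytosine report table into a methylome
#'
#' Retains CpG-context rows with coverage at or above `min_coverage` and
#' computes percent methylation for each retained cytosine.
#'
#' @param report data.frame with columns `chrom`, `pos`, `strand`,
#'   `count_m`, `count_u`, `context` (context `"CpG"`/`"CG"` rows are the
#'   CpG calls; `"CHG"`/`"CHH"` rows are used only by [conversion_rate()]).
#' @param min_coverage minimum read coverage for a CpG to be called
#'   (default 20).
#' @inheritParams methylome
#' @return A [methylome()] of the retained CpG calls.  If no CpG passes the
#'   filters a valid empty methylome is returned with a warning.
#' @export
as_methylome <- function(report, min_coverage = 20L,
                         sample_id = NA_character_,
                         group = NA_character_) {
  report <- .validate_report(report)
  cpg <- report[report$context %in% .CPG_CONTEXTS, , drop = FALSE]
  cpg <- cpg[(cpg$count_m + cpg$count_u) >= min_coverage, , drop = FALSE]
  if (nrow(cpg) == 0L) {
    warning("no CpG passed the coverage filter; returning an empty methylome")
  }
  methylome(cpg[c("chrom", "pos", "strand", "count_m", "count_u")],
            sample_id = sample_id, group = group,
            min_coverage = min_coverage)
}

#' Read a cytosine report file
#'
#' Parses a Bismark-style per-cytosine count report (tab-separated, no
#' header: chromosome, 1-based position, strand, methylated count,
#' unmethylated count, context, optionally the trinucleotide) and applies
#' the CpG-context and coverage filters.
#'
#' @param path path to the report.
#' @inheritParams as_methylome
#' @return A [methylome()].
#' @examples
#' tmp <- tempfile(fileext = ".tsv")
#' writeLines(c("chr1\t100\t+\t15\t5\tCpG", "chr1\t200\t+\t10\t5\tCpG"), tmp)
#' m <- read_cytosine_report(tmp, min_coverage = 20)
#' m$calls$percent  # only the first row passes 20X
#' @export
read_cytosine_report <- function(path, min_coverage = 20L,
                                 sample_id = NA_character_,
                                 group = NA_character_) {
  report <- .read_report_file(path)
  as_methylome(report, min_coverage = min_coverage,
               sample_id = if (is.na(sample_id)) basename(path) else sample_id,
               group = group)
}

.read_report_file <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- read.delim(path, header = FALSE, colClasses = "character",
                    stringsAsFactors = FALSE)
  if (ncol(raw) < 6L) {
    stop("cytosine report must have >= 6 tab-separated columns, found ",
         ncol(raw))
  }
  names(raw)[1:6] <- c("chrom", "pos", "strand", "count_m", "count_u",
                       "context")
  pos <- suppressWarnings(as.integer(raw$pos))
  cm <- suppressWarnings(as.numeric(raw$count_m))
  cu <- suppressWarnings(as.numeric(raw$count_u))
  bad <- which(is.na(pos) | pos <= 0L | is.na(cm) | cm < 0 |
                 is.na(cu) | cu < 0 | !(raw$strand %in% c("+", "-")) |
                 !(raw$context %in% c(.CPG_CONTEXTS, .NONCPG_CONTEXTS)))
  if (length(bad) > 0L) {
    stop("malformed cytosine report row at line ", bad[1L], " of ", path)
  }
  data.frame(chrom = raw$chrom, pos = pos, strand = raw$strand,
             count_m = cm, count_u = cu, context = raw$context,
             stringsAsFactors = FALSE)
}

#' Write a cytosine report file
#'
#' @param report data.frame as accepted by [as_methylome()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cytosine_report <- function(report, path) {
  report <- .validate_report(report)
  write.table(report[c("chrom", "pos", "strand", "count_m", "count_u",
                       "context")],
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Merge CpG dyad strands
#'
#' When enabled, merges each minus-strand record at position `p` with the
#' plus-strand record at `p - 1` (the two cytosines of one CpG dyad) by
#' summing counts; the merged call is reported at the plus-strand position.
#' Unpaired minus-strand records are kept, reported at `p - 1`.  Total
#' counts are conserved.
#'
#' @param m a [methylome()].
#' @param enabled logical; if `FALSE` the methylome is returned unchanged.
#' @return A [methylome()] with `destranded = TRUE` when enabled.
#' @export
destrand <- function(m, enabled = TRUE) {
  stopifnot(is(m, "methylome"))
  if (!enabled) return(m)
  calls <- m$calls
  dyad_pos <- ifelse(calls$strand == "-", calls$pos - 1L, calls$pos)
  key <- paste(calls$chrom, dyad_pos)
  cm <- rowsum(calls$count_m, key)
  cu <- rowsum(calls$count_u, key)
  first <- !duplicated(key)
  ord <- match(sort(unique(key)), key[first])
  merged <- data.frame(
    chrom = calls$chrom[first][ord],
    pos = dyad_pos[first][ord],
    strand = "+",
    count_m = as.vector(cm),
    count_u = as.vector(cu),
    stringsAsFactors = FALSE
  )
  methylome(merged, sample_id = m$sample_id, group = m$group,
            min_coverage = m$min_coverage, destranded = TRUE)
}

#' Bisulfite conversion rate from non-CpG cytosines
#'
#' Cytosines outside CpG context are presumed unmethylated, so the fraction
#' of their reads reported unmethylated estimates the bisulfite conversion
#' rate: `100 * sum(count_u) / sum(count_m + count_u)` over CHG/CHH rows.
#' No coverage filter is applied; every non-CpG read contributes.
#'
#' @param x path to a cytosine report, or a report data.frame.
#' @return Conversion rate in percent.
#' @export
conversion_rate <- function(x) {
  report <- if (is.character(x)) .read_report_file(x) else .validate_report(x)
  noncpg <- report[report$context %in% .NONCPG_CONTEXTS, , drop = FALSE]
  total <- sum(noncpg$count_m) + sum(noncpg$count_u)
  if (nrow(noncpg) == 0L || total == 0) {
    stop("conversion rate undefined: no covered non-CpG cytosines")
  }
  100 * sum(noncpg$count_u) / total
}

#' Correlation between technical replicates
#'
#' Pearson correlation of percent methylation over the CpGs called in both
#' replicates, the standard concordance summary for RRBS libraries
#' prepared independently from the same culture.
#'
#' @param a,b two [methylome()] objects.
#' @return A list with `r` (Pearson correlation) and `n` (number of shared
#'   CpG sites).
#' @export
replicate_correlation <- function(a, b) {
  stopifnot(is(a, "methylome"), is(b, "methylome"))
  key_a <- paste(a$calls$chrom, a$calls$pos, a$calls$strand)
  key_b <- paste(b$calls$chrom, b$calls$pos, b$calls$strand)
  idx <- match(key_a, key_b)
  shared <- !is.na(idx)
  n <- sum(shared)
  if (n < 3L) {
    stop("insufficient data: ", n, " shared CpG sites (need >= 3)")
  }
  pa <- a$calls$percent[shared]
  pb <- b$calls$percent[idx[shared]]
  if (stats::sd(pa) == 0 || stats::sd(pb) == 0) {
    stop("correlation undefined: zero variance in a replicate")
  }
  list(r = cor(pa, pb), n = n)
}

#' Pool methylomes by summing counts per CpG
#'
#' Sums methylated and unmethylated counts across samples at each
#' (chrom, pos, strand) site, the pooling used before group-level region
#' scoring and Fisher testing.
#'
#' @param ms list of [methylome()] objects.
#' @param sample_id,group labels for the pooled methylome.
#' @param min_coverage coverage filter applied to the pooled counts.
#' @return A [methylome()] of pooled counts.
#' @export
pool_methylomes <- function(ms, sample_id = "pooled",
                            group = NA_character_, min_coverage = 1L) {
  stopifnot(length(ms) >= 1L, all(vapply(ms, is, logical(1), "methylome")))
  calls <- do.call(rbind, lapply(ms, function(m) {
    m$calls[c("chrom", "pos", "strand", "count_m", "count_u")]
  }))
  key <- paste(calls$chrom, calls$pos, calls$strand)
  cm <- rowsum(calls$count_m, key)
  cu <- rowsum(calls$count_u, key)
  first <- !duplicated(key)
  ord <- match(rownames(cm), key[first])
  pooled <- data.frame(
    chrom = calls$chrom[first][ord],
    pos = calls$pos[first][ord],
    strand = calls$strand[first][ord],
    count_m = as.vector(cm),
    count_u = as.vector(cu),
    stringsAsFactors = FALSE
  )
  pooled <- pooled[(pooled$count_m + pooled$count_u) >= min_coverage, ,
                   drop = FALSE]
  methylome(pooled, sample_id = sample_id, group = group,
            min_coverage = min_coverage)
}
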