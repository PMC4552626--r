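# Promoter differential-methylation testing and the multi-comparison
# filtering cascade.

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p-value for the table `[[a, b], [c, d]]`, computed by
#' summing the hypergeometric probabilities of all tables with the same
#' margins whose probability does not exceed that of the observed table.
#' A relative slack of 1e-7 is applied when comparing probabilities, so
#' tables tied with the observed one up to floating-point error are
#' included (two-sided Fisher conventions differ exactly here).
#'
#' @param a,b,c,d non-negative cell counts; rows are groups (e.g. case and
#'   control) and columns methylated/unmethylated cytosines.
#' @return The two-sided p-value.  If a margin is zero the table carries no
#'   information and `p = 1` is returned with attribute
#'   `degenerate = TRUE`.
#' @examples
#' fisher_exact_2x2(3, 1, 1, 3)  # 34/70
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  m <- a + b
  n <- c + d
  k <- a + c
  if (m == 0 || n == 0 || k == 0 || (b + d) == 0) {
    return(structure(1, degenerate = TRUE))
  }
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- probs[match(a, support)]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' SLIM q-values from p-values
#'
#' Converts p-values to q-values with a sliding-linear-model (SLIM)
#' estimate of the null proportion `pi0`.  The empirical CDF of the
#' p-values is evaluated on a lambda grid (default 0.01 to 0.96 in steps
#' of 0.05) and straight lines are fitted to sliding windows of grid
#' points; in the uniform (null-dominated) upper range of the CDF the
#' fitted slope estimates `pi0`.  The q-value is then
#' `pi0 * p * n / rank`, monotonised from the largest p-value downwards
#' (i.e. `pi0` times the Benjamini-Hochberg adjusted value) and capped at
#' 1.  With fewer p-values than a window holds, `pi0 = 1` is used and the
#' result reduces to BH.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @param lambda grid of CDF evaluation points.
#' @param window number of consecutive grid points per linear fit.
#' @return Numeric vector of q-values, same order as `p`, with the
#'   estimated `pi0` attached as attribute `"pi0"`.
#' @export
slim_qvalues <- function(p, lambda = seq(0.01, 0.96, by = 0.05),
                         window = 5L) {
  if (length(p) == 0L) stop("no p-values supplied")
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  n <- length(p)
  pi0 <- 1
  if (n >= window * 2L) {
    cdf <- vapply(lambda, function(l) mean(p <= l), numeric(1))
    n_win <- length(lambda) - window + 1L
    slopes <- vapply(seq_len(n_win), function(i) {
      idx <- i:(i + window - 1L)
      stats::cov(lambda[idx], cdf[idx]) / stats::var(lambda[idx])
    }, numeric(1))
    ## windows in the upper half of the grid sit on the null-dominated
    ## part of the CDF; signal inflates slopes near zero, so clamp at 1
    ## and take the median of the upper-range slopes
    upper <- lambda[seq_len(n_win)] >= 0.25
    pi0 <- median(pmin(slopes[upper], 1))
    pi0 <- min(1, max(0.05, pi0))
  }
  q <- pmin(1, pi0 * p.adjust(p, method = "BH"))
  attr(q, "pi0") <- pi0
  q
}

#' Promoter differential-methylation test
#'
#' For every region scored in both groups, tests the pooled 2x2 table of
#' methylated/unmethylated cytosine counts (case vs control) with
#' [fisher_exact_2x2()], adjusts for multiple testing, and calls a region
#' differentially methylated when `q <= q_threshold` and the absolute
#' methylation difference is at least `diff_threshold` percentage points.
#' Replicates must already be pooled within each group (see
#' [pool_methylomes()]); the methylation difference is signed case minus
#' control, so positive means hypermethylated in the case group.
#'
#' @param case_scores,control_scores region-methylation tables from
#'   [score_feature_class()] (columns `name`, `meth_c`, `total_c`,
#'   `percent`), one per group.  Regions missing from either table are
#'   skipped.
#' @param q_threshold significance threshold on the q-value (default
#'   0.001).
#' @param diff_threshold minimum absolute methylation difference in
#'   percentage points (default 25).
#' @param q_method `"slim"` (default) or `"bh"`.
#' @return data.frame with one row per shared region: coordinates, `genes`
#'   (when present in the inputs), `meth_case`, `meth_control`,
#'   `meth_diff`, `p`, `q`, `is_dmr`.
#' @export
test_promoters <- function(case_scores, control_scores,
                           q_threshold = 0.001, diff_threshold = 25,
                           q_method = c("slim", "bh")) {
  q_method <- match.arg(q_method)
  idx <- match(case_scores$name, control_scores$name)
  shared <- !is.na(idx)
  if (!any(shared)) stop("no regions scored in both groups")
  ca <- case_scores[shared, , drop = FALSE]
  co <- control_scores[idx[shared], , drop = FALSE]
  p <- vapply(seq_len(nrow(ca)), function(i) {
    as.numeric(fisher_exact_2x2(ca$meth_c[i], ca$total_c[i] - ca$meth_c[i],
                                co$meth_c[i], co$total_c[i] - co$meth_c[i]))
  }, numeric(1))
  q <- if (q_method == "slim") as.numeric(slim_qvalues(p)) else
    p.adjust(p, method = "BH")
  out <- data.frame(
    chrom = ca$chrom, start = ca$start, end = ca$end, name = ca$name,
    stringsAsFactors = FALSE
  )
  if (!is.null(ca$genes)) out$genes <- ca$genes
  out$n_cpgs_case <- ca$n_cpgs
  out$n_cpgs_control <- co$n_cpgs
  out$meth_case <- ca$percent
  out$meth_control <- co$percent
  out$meth_diff <- ca$percent - co$percent
  out$p <- p
  out$q <- q
  out$is_dmr <- out$q <= q_threshold & abs(out$meth_diff) >= diff_threshold
  rownames(out) <- NULL
  out
}

#' Label a pairwise comparison and its DMR calls
#'
#' A comparison set binds one case/control sample pairing (e.g. the twin
#' pair discordant for trisomy 21, or an unrelated case/control pair) to
#' its promoter DMR test results; it is the unit the filtering cascade
#' manipulates.
#'
#' @param comparison_id short label, e.g. `"discordantT21"`.
#' @param case_ids,control_ids sample identifiers; must be disjoint and
#'   non-empty.
#' @param dmrs DMR table from [test_promoters()].
#' @return An object of class `comparison_set`.
#' @export
comparison_set <- function(comparison_id, case_ids, control_ids, dmrs) {
  stopifnot(length(case_ids) >= 1L, length(control_ids) >= 1L)
  if (length(intersect(case_ids, control_ids)) > 0L) {
    stop("case and control sample ids must be disjoint")
  }
  structure(
    list(comparison_id = comparison_id, case_ids = case_ids,
         control_ids = control_ids, dmrs = dmrs),
    class = "comparison_set"
  )
}

#' @export
print.comparison_set <- function(x, ...) {
  cat("comparison_set '", x$comparison_id, "': ",
      paste(x$case_ids, collapse = "+"), " vs ",
      paste(x$control_ids, collapse = "+"), "; ",
      sum(x$dmrs$is_dmr), "/", nrow(x$dmrs), " DMRs\n", sep = "")
  invisible(x)
}

.dmr_keys <- function(x) {
  if (is.character(x)) return(x)
  if (is(x, "comparison_set")) x <- x$dmrs
  if (is.data.frame(x)) return(x$name[x$is_dmr])
  stop("cannot extract DMR keys from object of class ", class(x)[1])
}

.universe_keys <- function(x) {
  if (is.character(x)) return(NULL)
  if (is(x, "comparison_set")) x <- x$dmrs
  if (is.data.frame(x)) return(x$name)
  NULL
}

#' Call promoter DMRs for one simulated comparison
#'
#' Convenience wrapper running the standard promoter DMR pipeline on an
#' [simulate_methylomes()] result: pool the replicates of each group, sum
#' counts, score every promoter under the coverage and minimum-CpG rules,
#' and test with [test_promoters()].
#'
#' @param sim an `rrbs_simulation`.
#' @param comparison_id label for the resulting [comparison_set()].
#' @param min_cpgs,min_coverage region-scoring filters.
#' @inheritParams test_promoters
#' @return A [comparison_set()].
#' @export
dmr_comparison <- function(sim, comparison_id = "comparison",
                           min_cpgs = 3L, min_coverage = 20L,
                           q_threshold = 0.001, diff_threshold = 25,
                           q_method = c("slim", "bh")) {
  stopifnot(is(sim, "rrbs_simulation"))
  pool_role <- function(role) {
    ids <- sim$samples$sample_id[sim$samples$role == role]
    pool_methylomes(lapply(ids, function(id) {
      as_methylome(sim$reports[[id]], min_coverage = 1L, sample_id = id)
    }), sample_id = paste0(role, "_pooled"))
  }
  case_scores <- score_feature_class(pool_role("case"), sim$annotation,
                                     "promoters", min_cpgs = min_cpgs,
                                     min_coverage = min_coverage)
  control_scores <- score_feature_class(pool_role("control"),
                                        sim$annotation, "promoters",
                                        min_cpgs = min_cpgs,
                                        min_coverage = min_coverage)
  dmrs <- test_promoters(case_scores, control_scores,
                         q_threshold = q_threshold,
                         diff_threshold = diff_threshold,
                         q_method = q_method)
  comparison_set(comparison_id,
                 sim$samples$sample_id[sim$samples$role == "case"],
                 sim$samples$sample_id[sim$samples$role == "control"],
                 dmrs)
}

#' DMR filtering cascade across comparison sets
#'
#' Isolates DMR candidates attributable to the condition by set algebra
#' over comparisons sharing one promoter universe:
#'
#' 1. start with the DMRs of the discordant-pair comparison;
#' 2. exclude any DMR also called in a control comparison (normal twin
#'    pairs, condition-concordant twin pairs), which removes twin-pair
#'    epigenetic variation unrelated to the condition;
#' 3. keep only DMRs also called in the unrelated case/control comparison,
#'    which requires the signal to replicate outside the twin pair.
#'
#' Hyper/hypomethylated tallies use the sign of the methylation difference
#' in the discordant comparison.
#'
#' @param discordant a [comparison_set()] (or DMR table, or character
#'   vector of region keys) for the discordant pair.
#' @param controls list of comparison sets whose DMRs are excluded.
#' @param unrelated comparison set whose DMRs the final list must
#'   intersect.
#' @return An object of class `cascade_result` with `initial`,
#'   `after_exclusion` and `final` key vectors, per-stage `counts`, and
#'   per-stage hyper/hypo tallies when signs are available.
#' @export
run_cascade <- function(discordant, controls = list(), unrelated) {
  if (is(controls, "comparison_set") || is.data.frame(controls) ||
      is.character(controls)) {
    controls <- list(controls)
  }
  ## comparisons must test the same promoter universe; individual regions
  ## may drop out for lack of coverage, so the check is for disjoint key
  ## spaces (a different annotation), not for exact equality
  disc_universe <- .universe_keys(discordant)
  for (i in seq_along(controls)) {
    u <- .universe_keys(controls[[i]])
    if (!is.null(u) && !is.null(disc_universe) &&
        length(intersect(u, disc_universe)) == 0L) {
      stop("promoter key space of control comparison ", i,
           " does not match the discordant comparison")
    }
  }
  u <- .universe_keys(unrelated)
  if (!is.null(u) && !is.null(disc_universe) &&
      length(intersect(u, disc_universe)) == 0L) {
    stop("promoter key space of the unrelated comparison does not match ",
         "the discordant comparison")
  }

  initial <- unique(.dmr_keys(discordant))
  excluded <- unique(unlist(lapply(controls, .dmr_keys)))
  after_exclusion <- base::setdiff(initial, excluded)
  final <- intersect(after_exclusion, unique(.dmr_keys(unrelated)))

  signs <- NULL
  if (!is.character(discordant)) {
    tab <- if (is(discordant, "comparison_set")) discordant$dmrs else
      discordant
    signs <- setNames(sign(tab$meth_diff), tab$name)
  }
  tally <- function(keys) {
    if (is.null(signs)) return(c(hyper = NA_integer_, hypo = NA_integer_))
    s <- signs[keys]
    c(hyper = sum(s > 0), hypo = sum(s <= 0))
  }
  structure(
    list(initial = initial, after_exclusion = after_exclusion,
         final = final,
         counts = c(initial = length(initial),
                    after_exclusion = length(after_exclusion),
                    final = length(final)),
         tallies = rbind(initial = tally(initial),
                         after_exclusion = tally(after_exclusion),
                         final = tally(final))),
    class = "cascade_result"
  )
}

#' @export
print.cascade_result <- function(x, ...) {
  cat("DMR filtering cascade:\n")
  for (stage in names(x$counts)) {
    cat(sprintf("  %-16s %4d", stage, x$counts[[stage]]))
    t <- x$tallies[stage, ]
    if (!any(is.na(t))) {
      cat(sprintf("  (%d hyper / %d hypo)", t[["hyper"]], t[["hypo"]]))
    }
    cat("\n")
  }
  invisible(x)
}

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "twinmeth")
  if (!nzchar(path)) stop("packaged fixture not found: ", file)
  path
}

.check_fixture <- function(path, expected_md5) {
  got <- unname(md5sum(path))
  if (!identical(got, expected_md5)) {
    stop("fixture integrity check failed for ", basename(path),
         ": md5 ", got, " != ", expected_md5)
  }
}

#' Reference promoter DMR tables
#'
#' Returns one of the reference DMR tables packaged with twinmeth,
#' transcribed from a published RRBS study of monozygotic twins:
#'
#' * `"t21"` — final promoter DMR candidates from twins discordant for
#'   trisomy 21 (37 gene rows over 35 distinct 3000 bp promoter windows;
#'   `meth_diff` is signed T21 minus normal, so positive means the T21
#'   twin is hypermethylated).
#' * `"chd"` — promoter DMRs shared between two T21 twin pairs discordant
#'   for a congenital heart defect (13 genes; signed methylation
#'   differences in the AVSD- and VSD-discordant pairs plus an expression
#'   log2 fold change where available).
#'
#' Fixture files are verified against a stored checksum on load.
#'
#' @param which `"t21"` or `"chd"`.
#' @return A typed data.frame.
#' @export
dmr_reference_table <- function(which = c("t21", "chd")) {
  which <- match.arg(which)
  if (which == "t21") {
    path <- .extdata("t21_twin_promoter_dmrs.tsv")
    .check_fixture(path, .FIXTURE_MD5[["t21_twin_promoter_dmrs.tsv"]])
    tab <- read.delim(path, stringsAsFactors = FALSE)
    stopifnot(identical(names(tab), c("chrom", "start", "end",
                                      "meth_diff", "gene", "description")))
    tab$start <- as.integer(tab$start)
    tab$end <- as.integer(tab$end)
    tab$meth_diff <- as.numeric(tab$meth_diff)
  } else {
    path <- .extdata("chd_twin_common_dmrs.tsv")
    .check_fixture(path, .FIXTURE_MD5[["chd_twin_common_dmrs.tsv"]])
    tab <- read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
    stopifnot(identical(names(tab), c("gene", "description",
                                      "meth_diff_avsd", "meth_diff_vsd",
                                      "log2fc")))
    tab$meth_diff_avsd <- as.numeric(tab$meth_diff_avsd)
    tab$meth_diff_vsd <- as.numeric(tab$meth_diff_vsd)
    tab$log2fc <- as.numeric(tab$log2fc)
  }
  tab
}

#' Genes with discordant methylation direction between two comparisons
#'
#' Given the `"chd"` reference table (or any table with two signed
#' methylation-difference columns), returns the genes whose differences
#' have opposite signs in the two comparisons, sorted alphabetically.
#'
#' @param tab data.frame with columns `gene`, `meth_diff_avsd`,
#'   `meth_diff_vsd`.
#' @return Character vector of gene symbols.
#' @export
direction_discordance <- function(tab = dmr_reference_table("chd")) {
  stopifnot(all(c("gene", "meth_diff_avsd", "meth_diff_vsd") %in%
                  names(tab)))
  opp <- sign(tab$meth_diff_avsd) * sign(tab$meth_diff_vsd) < 0
  sort(tab$gene[opp])
}
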