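# Global methylome comparisons and the metagene ("gene model") profile.

#' Two-sided Mann-Whitney U test
#'
#' U statistic and two-sided p-value for the shift between two samples.
#' Without ties and with both sample sizes at most 50 the p-value is
#' exact (from the null distribution of U); otherwise a normal
#' approximation with tie correction and continuity correction is used.
#' When every value is tied the statistic carries no information and
#' `p = 1` is returned.
#'
#' @param x,y numeric vectors.
#' @param exact force (`TRUE`) or forbid (`FALSE`) the exact p-value;
#'   default `NULL` chooses automatically.
#' @return list with `U` (number of `(x, y)` pairs with `x > y`, ties
#'   counted 1/2), `p`, and `method` (`"exact"` or `"normal"`).
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))$p  # exact: 0.1
#' @export
mann_whitney_u <- function(x, y, exact = NULL) {
  stopifnot(length(x) >= 1L, length(y) >= 1L,
            !anyNA(x), !anyNA(y))
  n <- length(x)
  m <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  ties <- table(r)
  has_ties <- any(ties > 1L)
  if (is.null(exact)) exact <- !has_ties && n <= 50L && m <= 50L
  if (exact && has_ties) {
    stop("exact Mann-Whitney p-value is unavailable with ties")
  }
  if (exact) {
    p <- if (U > n * m / 2) {
      pwilcox(U - 1, n, m, lower.tail = FALSE)
    } else {
      pwilcox(U, n, m)
    }
    return(list(U = U, p = min(1, 2 * p), method = "exact"))
  }
  N <- n + m
  mu <- n * m / 2
  sigma2 <- (n * m / 12) * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (sigma2 <= 0) return(list(U = U, p = 1, method = "normal"))
  z <- U - mu
  z <- (z - sign(z) * 0.5) / sqrt(sigma2)  # continuity correction
  list(U = U, p = min(1, 2 * pnorm(-abs(z))), method = "normal")
}

#' Feature-level methylation comparison between two methylomes
#'
#' Scores one feature class in both methylomes, pairs the regions scored
#' in both, and compares the two percent-methylation vectors with a
#' two-sided Mann-Whitney U test (used, as is conventional for global
#' methylome comparisons, as a distribution-shift test).  Also builds the
#' per-CpG difference histogram over CpG sites called in both samples, in
#' both orientations (case minus control and its mirror), which summarises
#' the direction of any global shift.
#'
#' @param case,control [methylome()] objects.
#' @param annotation an [build_annotation()] model.
#' @param class_name feature class (see [score_feature_class()]).
#' @param min_cpgs,min_coverage region-scoring filters.
#' @param bin_width width in percentage points of the difference-histogram
#'   bins; differences are assigned to the nearest bin center (centers at
#'   multiples of `bin_width` from -100 to 100), a rule symmetric under
#'   negation so the two orientations are exact mirror images.
#' @return An object of class `feature_comparison`: feature class, paired
#'   percent vectors, `U`, `p`, medians, and the difference histograms.
#' @export
compare_feature <- function(case, control, annotation, class_name,
                            min_cpgs = 3L, min_coverage = 20L,
                            bin_width = 5) {
  ca <- score_feature_class(case, annotation, class_name,
                            min_cpgs = min_cpgs,
                            min_coverage = min_coverage)
  co <- score_feature_class(control, annotation, class_name,
                            min_cpgs = min_cpgs,
                            min_coverage = min_coverage)
  idx <- match(ca$name, co$name)
  shared <- !is.na(idx)
  if (sum(shared) < 3L) {
    stop("insufficient data: ", sum(shared),
         " regions scored in both samples (need >= 3)")
  }
  pc <- ca$percent[shared]
  pn <- co$percent[idx[shared]]
  mw <- mann_whitney_u(pc, pn)

  ## per-CpG differences at shared sites
  key_ca <- paste(case$calls$chrom, case$calls$pos, case$calls$strand)
  key_co <- paste(control$calls$chrom, control$calls$pos,
                  control$calls$strand)
  keep_ca <- case$calls$coverage >= min_coverage
  keep_co <- control$calls$coverage >= min_coverage
  i <- match(key_ca, key_co)
  site <- keep_ca & !is.na(i) & keep_co[replace(i, is.na(i), 1L)]
  d <- case$calls$percent[site] - control$calls$percent[i[site]]
  half <- floor(100 / bin_width)
  centers <- bin_width * (-half:half)
  count_bins <- function(v) tabulate(round(v / bin_width) + half + 1L,
                                     nbins = 2L * half + 1L)
  h_fwd <- count_bins(d)
  h_rev <- count_bins(-d)

  structure(
    list(class = class_name, n_regions = sum(shared),
         percent_case = pc, percent_control = pn,
         U = mw$U, p = mw$p, method = mw$method,
         median_case = median(pc), median_control = median(pn),
         n_cpg_sites = length(d), median_cpg_diff = median(d),
         diff_centers = centers,
         diff_hist_case_minus_control = h_fwd,
         diff_hist_control_minus_case = h_rev),
    class = "feature_comparison"
  )
}

#' @export
print.feature_comparison <- function(x, ...) {
  cat("feature_comparison (", x$class, "): ", x$n_regions,
      " paired regions\n", sep = "")
  cat(sprintf("  Mann-Whitney U = %.1f, two-sided p = %.3g (%s)\n",
              x$U, x$p, x$method))
  cat(sprintf("  median %% methylation: case %.2f, control %.2f\n",
              x$median_case, x$median_control))
  cat(sprintf("  per-CpG median difference (case - control): %.2f\n",
              x$median_cpg_diff))
  invisible(x)
}

## Assign CpGs of one methylome to metagene bins and pool counts.
.metagene_counts <- function(m, genes, flank, inner, flank_bins,
                             body_bins, min_coverage) {
  calls <- m$calls[m$calls$coverage >= min_coverage, , drop = FALSE]
  bin_w <- (flank + inner) / flank_bins
  spans <- .interval_df(genes$chrom, pmax(genes$txStart - flank, 0),
                        genes$txEnd + flank, genes$gene)
  grid <- rbind(
    data.frame(segment = "promoter_flank", bin = seq_len(flank_bins)),
    data.frame(segment = "body", bin = seq_len(body_bins)),
    data.frame(segment = "tts_flank", bin = seq_len(flank_bins)),
    data.frame(segment = "intergenic", bin = 1L)
  )
  grid$meth <- 0
  grid$total <- 0
  if (nrow(calls) == 0L) return(grid)

  cpg_gr <- GRanges(calls$chrom, IRanges(calls$pos, width = 1L))
  hits <- findOverlaps(cpg_gr, .as_granges(spans))
  ci <- queryHits(hits)
  gi <- subjectHits(hits)

  x <- (calls$pos[ci] - 1) + 0.5            # 0-based CpG center
  minus <- genes$strand[gi] == "-"
  d_tss <- ifelse(minus, genes$txEnd[gi] - x, x - genes$txStart[gi])
  L <- genes$txEnd[gi] - genes$txStart[gi]

  seg <- ifelse(d_tss < inner, "promoter_flank",
                ifelse(d_tss < L - inner, "body", "tts_flank"))
  bin <- integer(length(seg))
  p <- seg == "promoter_flank"
  bin[p] <- pmin(flank_bins, pmax(1L, floor((d_tss[p] + flank) / bin_w) + 1L))
  b <- seg == "body"
  bin[b] <- pmin(body_bins,
                 floor((d_tss[b] - inner) / (L[b] - 2 * inner) *
                         body_bins) + 1L)
  t <- seg == "tts_flank"
  bin[t] <- pmin(flank_bins,
                 pmax(1L, floor((d_tss[t] - (L[t] - inner)) / bin_w) + 1L))

  in_gene <- rep(FALSE, nrow(calls))
  in_gene[unique(ci)] <- TRUE
  seg_all <- c(seg, rep("intergenic", sum(!in_gene)))
  bin_all <- c(bin, rep(1L, sum(!in_gene)))
  meth_all <- c(calls$count_m[ci], calls$count_m[!in_gene])
  tot_all <- c(calls$coverage[ci], calls$coverage[!in_gene])

  key <- paste(seg_all, bin_all)
  meth <- rowsum(meth_all, key)
  tot <- rowsum(tot_all, key)
  idx <- match(paste(grid$segment, grid$bin), rownames(meth))
  grid$meth <- ifelse(is.na(idx), 0, meth[idx])
  grid$total <- ifelse(is.na(idx), 0, tot[idx])
  grid
}

#' Metagene methylation profile over a gene model
#'
#' Aligns all genes at their TSS and TTS, bins the surrounding sequence
#' (strand-aware, so bin 1 is always biological upstream), pools cytosine
#' counts across genes per bin in each condition, and reports the per-bin
#' methylation density (percent methylated cytosines over all covered
#' cytosines) and the case/control fold change.  Segments:
#'
#' * `promoter_flank`: `-flank` to `+inner` of the TSS, `flank_bins`
#'   fixed-width bins (defaults: -10 kb..+1 kb in 44 x 250 bp bins);
#' * `body`: `TSS + inner` to `TTS - inner`, `body_bins` bins scaled
#'   proportionally to gene length;
#' * `tts_flank`: `-inner` to `+flank` of the TTS;
#' * `intergenic`: everything outside all gene models, pooled as one bin.
#'
#' Genes whose body would be empty (length `<= 2 * inner`) are excluded
#' with a warning.  Fold change is only defined where both densities are
#' positive; other bins are flagged.
#'
#' @param case,control [methylome()] objects (pool replicates first).
#' @param genes gene table (`gene`, `chrom`, `strand`, `txStart`,
#'   `txEnd`).
#' @param flank flank width in bp (default 10000).
#' @param inner inner offset in bp defining the body margin (default
#'   1000).
#' @param flank_bins,body_bins bin counts per segment.
#' @param min_coverage per-CpG coverage filter.
#' @return An object of class `gene_model_profile`: data.frame with
#'   `segment`, `bin`, per-condition pooled counts and densities,
#'   `fold_change`, and `flagged` (density missing in either condition);
#'   the number of excluded genes is attached as attribute
#'   `"n_excluded_genes"`.
#' @export
gene_model_profile <- function(case, control, genes, flank = 10000,
                               inner = 1000, flank_bins = 44L,
                               body_bins = 60L, min_coverage = 20L) {
  stopifnot(is(case, "methylome"), is(control, "methylome"))
  usable <- (genes$txEnd - genes$txStart) > 2 * inner
  if (sum(!usable) > 0L) {
    warning(sum(!usable), " gene(s) shorter than ", 2 * inner,
            " bp excluded from the gene model")
  }
  genes <- genes[usable, , drop = FALSE]
  if (nrow(genes) == 0L) stop("no usable genes (all bodies empty)")

  a <- .metagene_counts(case, genes, flank, inner, flank_bins, body_bins,
                        min_coverage)
  b <- .metagene_counts(control, genes, flank, inner, flank_bins,
                        body_bins, min_coverage)
  out <- data.frame(segment = a$segment, bin = a$bin,
                    meth_case = a$meth, total_case = a$total,
                    meth_control = b$meth, total_control = b$total,
                    stringsAsFactors = FALSE)
  out$density_case <- ifelse(out$total_case > 0,
                             100 * out$meth_case / out$total_case,
                             NA_real_)
  out$density_control <- ifelse(out$total_control > 0,
                                100 * out$meth_control / out$total_control,
                                NA_real_)
  ok <- !is.na(out$density_case) & !is.na(out$density_control) &
    out$density_case > 0 & out$density_control > 0
  out$fold_change <- ifelse(ok, out$density_case / out$density_control,
                            NA_real_)
  out$flagged <- !ok
  structure(out, class = c("gene_model_profile", "data.frame"),
            n_excluded_genes = sum(!usable))
}

#' Write a metagene profile table
#'
#' @param profile a [gene_model_profile()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_model_profile <- function(profile, path) {
  write.table(as.data.frame(profile), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
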