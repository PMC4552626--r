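# RRBS-like simulator: beta-binomial CpG counts over a synthetic genome
# annotation, with planted promoter DMRs, a configurable global
# methylation shift in the case group, technical replicates, non-CpG
# cytosines for conversion-rate estimation, and a coupled expression
# table.  Everything is deterministic under a fixed seed; each sample
# draws its counts from its own RNG stream derived from the master seed,
# so adding samples does not perturb earlier ones.

.derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 7919 + stream * 104729) %% 2147483647)
}

.clamp01 <- function(p) pmin(0.99, pmax(0.01, p))

#' Configuration for the RRBS simulator
#'
#' Collects every knob of the synthetic-data generator with defaults that
#' emulate a twin-pair RRBS experiment: overdispersed ~30X coverage,
#' bimodal baseline methylation (low at CpG islands and promoters, high
#' in the background genome), two technical replicates per twin with
#' jitter chosen to give replicate correlations around 0.9, and
#' near-complete bisulfite conversion (0.2% residual non-CpG
#' methylation).
#'
#' @param seed master RNG seed (all outputs are byte-identical under the
#'   same seed).
#' @param n_chromosomes,chromosome_length synthetic genome shape (bp).
#' @param n_promoters total number of genes/promoters across the genome.
#' @param cpgs_per_promoter_range integer `(min, max)` CpGs simulated per
#'   promoter.
#' @param background_cpg_density background CpGs per kb outside
#'   promoters.
#' @param coverage_mean mean read coverage per cytosine.
#' @param coverage_dispersion negative-binomial dispersion `phi`
#'   (`variance = mu + phi * mu^2`); `0` gives Poisson coverage.
#' @param baseline_methylation_beta named list of beta shape pairs
#'   (`island`, `promoter`, `background`) for the latent per-CpG
#'   methylation level of each region class.
#' @param global_shift percentage points added to the case group's
#'   promoter and island CpG methylation (the genome-wide
#'   hypermethylation knob).
#' @param planted_dmrs data.frame with columns `region_class` (currently
#'   `"promoter"`) and `delta_percent` (signed percentage points added to
#'   the case group over the whole region); one row per planted DMR.
#'   Planted DMRs are assigned to evenly spaced promoters, so the same
#'   annotation always receives them at the same intervals.
#' @param replicate_noise_sd percentage-point jitter applied
#'   independently per CpG and replicate (technical noise).
#' @param noncpg_methylation true methylation of non-CpG cytosines in
#'   percent (residual bisulfite non-conversion; default 0.2).
#' @param expression_coupling list with `slope` (expression log2
#'   fold change per unit of planted methylation difference, applied as
#'   `-slope * delta/100`) and `noise_sd` (log2-scale Gaussian noise).
#' @param n_replicates technical replicates per group.
#' @param gene_length,island_width geometry of each synthetic gene (bp).
#' @param groups labels for the two groups, `c(case=, control=)`.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_chromosomes = 2L,
                              chromosome_length = 1e7,
                              n_promoters = 200L,
                              cpgs_per_promoter_range = c(10L, 30L),
                              background_cpg_density = 1,
                              coverage_mean = 30,
                              coverage_dispersion = 0.1,
                              baseline_methylation_beta = list(
                                island = c(1, 9),
                                promoter = c(3, 7),
                                background = c(7, 3)),
                              global_shift = 0,
                              planted_dmrs = NULL,
                              replicate_noise_sd = 4,
                              noncpg_methylation = 0.2,
                              expression_coupling = list(slope = 3,
                                                         noise_sd = 0.5),
                              n_replicates = 2L,
                              gene_length = 10000,
                              island_width = 1000,
                              groups = c(case = "T21",
                                         control = "Normal")) {
  stopifnot(seed == as.integer(seed),
            n_chromosomes >= 1L, chromosome_length > 0,
            n_promoters >= 0L,
            length(cpgs_per_promoter_range) == 2L,
            cpgs_per_promoter_range[1] >= 1L,
            cpgs_per_promoter_range[1] <= cpgs_per_promoter_range[2],
            background_cpg_density >= 0,
            coverage_mean > 0, coverage_dispersion >= 0,
            all(c("island", "promoter", "background") %in%
                  names(baseline_methylation_beta)),
            replicate_noise_sd >= 0,
            noncpg_methylation >= 0, noncpg_methylation <= 100,
            n_replicates >= 1L, gene_length > 2000, island_width > 0,
            length(groups) == 2L)
  if (!is.null(planted_dmrs)) {
    stopifnot(is.data.frame(planted_dmrs),
              all(c("region_class", "delta_percent") %in%
                    names(planted_dmrs)),
              all(planted_dmrs$region_class == "promoter"),
              all(abs(planted_dmrs$delta_percent) <= 90),
              all(planted_dmrs$delta_percent != 0))
    if (nrow(planted_dmrs) > n_promoters) {
      stop("more planted DMRs than promoters")
    }
  }
  structure(
    list(seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
         chromosome_length = chromosome_length,
         n_promoters = as.integer(n_promoters),
         cpgs_per_promoter_range = as.integer(cpgs_per_promoter_range),
         background_cpg_density = background_cpg_density,
         coverage_mean = coverage_mean,
         coverage_dispersion = coverage_dispersion,
         baseline_methylation_beta = baseline_methylation_beta,
         global_shift = global_shift, planted_dmrs = planted_dmrs,
         replicate_noise_sd = replicate_noise_sd,
         noncpg_methylation = noncpg_methylation,
         expression_coupling = expression_coupling,
         n_replicates = as.integer(n_replicates),
         gene_length = gene_length, island_width = island_width,
         groups = groups),
    class = "simulation_config"
  )
}

## bp reserved on each side of a gene for flanks + margin
.SLOT_MARGIN <- 13000

#' Generate the synthetic genome annotation
#'
#' Lays genes out on evenly spaced slots along each chromosome
#' (alternating strands), places a CpG island centred on each TSS, three
#' exons per gene, and alternating LAD blocks covering half of each
#' chromosome, then derives promoters (3000 bp strand-aware windows),
#' shores, introns and iLADs via [build_annotation()].
#'
#' @param config a [simulation_config()].
#' @return An [build_annotation()] model.
#' @export
generate_annotation <- function(config) {
  stopifnot(is(config, "simulation_config"))
  n_chr <- config$n_chromosomes
  chroms <- paste0("chr", seq_len(n_chr))
  chrom_sizes <- setNames(rep(config$chromosome_length, n_chr), chroms)

  n_genes <- config$n_promoters
  genes <- data.frame(gene = character(), chrom = character(),
                      strand = character(), txStart = numeric(),
                      txEnd = numeric(), stringsAsFactors = FALSE)
  if (n_genes > 0L) {
    per_chr <- diff(floor(seq(0, n_genes, length.out = n_chr + 1L)))
    slot <- floor(config$chromosome_length / pmax(per_chr, 1L))
    if (any(per_chr > 0 & slot < config$gene_length + 2 * .SLOT_MARGIN)) {
      stop("infeasible config: ", n_genes, " promoters of ",
           config$gene_length + 2 * .SLOT_MARGIN,
           " bp footprint do not fit ", n_chr, " chromosome(s) of ",
           config$chromosome_length, " bp")
    }
    gene_list <- lapply(seq_len(n_chr), function(ci) {
      k <- per_chr[ci]
      if (k == 0L) return(NULL)
      s0 <- (seq_len(k) - 1L) * slot[ci] + .SLOT_MARGIN
      strand <- rep(c("+", "-"), length.out = k)
      data.frame(
        gene = sprintf("gene_%s_%03d", chroms[ci], seq_len(k)),
        chrom = chroms[ci], strand = strand,
        txStart = s0, txEnd = s0 + config$gene_length,
        stringsAsFactors = FALSE
      )
    })
    genes <- do.call(rbind, gene_list)
  }

  islands <- NULL
  if (n_genes > 0L) {
    tss <- ifelse(genes$strand == "-", genes$txEnd, genes$txStart)
    islands <- data.frame(
      chrom = genes$chrom,
      start = tss - floor(config$island_width / 2),
      end = tss + ceiling(config$island_width / 2),
      name = paste0(genes$gene, "_island"),
      stringsAsFactors = FALSE
    )
    third <- floor(config$gene_length / 3)
    exons <- rbind(
      data.frame(chrom = genes$chrom, start = genes$txStart,
                 end = genes$txStart + 500,
                 name = paste0(genes$gene, "_ex1")),
      data.frame(chrom = genes$chrom, start = genes$txStart + third,
                 end = genes$txStart + third + 500,
                 name = paste0(genes$gene, "_ex2")),
      data.frame(chrom = genes$chrom, start = genes$txEnd - 500,
                 end = genes$txEnd, name = paste0(genes$gene, "_ex3"))
    )
  } else {
    exons <- NULL
  }

  ## alternating LAD blocks: every other eighth of each chromosome
  block <- config$chromosome_length / 8
  lads <- do.call(rbind, lapply(chroms, function(ch) {
    starts <- block * c(1, 3, 5, 7)
    data.frame(chrom = ch, start = starts, end = starts + block,
               name = sprintf("%s_LAD%d", ch, seq_along(starts)),
               stringsAsFactors = FALSE)
  }))

  build_annotation(genes, islands = islands, lads = lads, exons = exons,
                   chrom_sizes = chrom_sizes)
}

## deterministic planted-DMR placement: evenly spaced promoter indices,
## independent of the RNG, so two simulations over the same annotation
## plant their DMRs at identical intervals
.planted_promoter_index <- function(n_planted, n_promoters) {
  if (n_planted == 0L) return(integer())
  unique(round(seq(1, n_promoters, length.out = n_planted)))
}

.sim_latent <- function(config, annotation) {
  set.seed(.derive_seed(config$seed, 0L))
  prom <- annotation$promoters
  n_prom <- nrow(prom)

  ## CpG positions: clustered in promoters plus genome-wide background
  cpg <- list()
  if (n_prom > 0L) {
    rng <- config$cpgs_per_promoter_range
    ## guard the scalar case: sample(20, ...) would draw from 1:20
    n_per <- if (rng[1] == rng[2]) rep(rng[1], n_prom) else
      sample(rng[1]:rng[2], n_prom, replace = TRUE)
    cpg$prom <- do.call(rbind, lapply(seq_len(n_prom), function(i) {
      pos <- sort(sample((prom$start[i] + 1L):prom$end[i], n_per[i]))
      data.frame(chrom = prom$chrom[i], pos = pos, promoter = i,
                 stringsAsFactors = FALSE)
    }))
  }
  n_bg_per_chr <- round(config$background_cpg_density *
                          config$chromosome_length / 1000)
  if (n_bg_per_chr > 0L) {
    cpg$bg <- do.call(rbind, lapply(names(annotation$chrom_sizes),
                                    function(ch) {
      data.frame(chrom = ch,
                 pos = sort(sample.int(config$chromosome_length,
                                       n_bg_per_chr)),
                 promoter = NA_integer_, stringsAsFactors = FALSE)
    }))
  }
  cpgs <- do.call(rbind, cpg)
  cpgs <- cpgs[!duplicated(cpgs[c("chrom", "pos")]), , drop = FALSE]
  cpgs <- cpgs[order(cpgs$chrom, cpgs$pos), , drop = FALSE]
  rownames(cpgs) <- NULL

  ## region class per CpG (island takes precedence over promoter)
  cpg_gr <- GRanges(cpgs$chrom, IRanges(cpgs$pos, width = 1L))
  in_island <- queryHits(findOverlaps(cpg_gr,
                                      .as_granges(annotation$cpg_islands)))
  in_prom <- queryHits(findOverlaps(cpg_gr, .as_granges(prom)))
  cpgs$class <- "background"
  cpgs$class[in_prom] <- "promoter"
  cpgs$class[in_island] <- "island"
  ## recover promoter index for background CpGs that landed in promoters
  hit <- findOverlaps(cpg_gr, .as_granges(prom))
  cpgs$promoter[queryHits(hit)] <- subjectHits(hit)

  ## latent baseline methylation per CpG
  p0 <- numeric(nrow(cpgs))
  for (cls in c("island", "promoter", "background")) {
    idx <- cpgs$class == cls
    ab <- config$baseline_methylation_beta[[cls]]
    p0[idx] <- rbeta(sum(idx), ab[1], ab[2])
  }

  ## plant DMRs: re-draw the affected promoters' baselines uniformly in
  ## the range that keeps baseline + delta inside [0.05, 0.95], so the
  ## realised group difference equals the planted delta
  planted <- config$planted_dmrs
  truth <- data.frame(chrom = prom$chrom, start = prom$start,
                      end = prom$end, name = prom$name,
                      genes = prom$genes, region_class = "promoter",
                      planted_delta_percent = 0, stringsAsFactors = FALSE)
  if (!is.null(planted) && nrow(planted) > 0L) {
    idx <- .planted_promoter_index(nrow(planted), n_prom)
    for (j in seq_along(idx)) {
      delta <- planted$delta_percent[j] / 100
      lo <- max(0.05, 0.05 - delta)
      hi <- min(0.95, 0.95 - delta)
      members <- which(cpgs$promoter == idx[j])
      p0[members] <- runif(length(members), lo, hi)
      truth$planted_delta_percent[idx[j]] <- planted$delta_percent[j]
    }
  }
  truth$is_null <- truth$planted_delta_percent == 0

  ## case-group methylation: global shift on promoter/island CpGs plus
  ## planted deltas, applied on the percent scale then clamped
  shift <- ifelse(cpgs$class %in% c("island", "promoter"),
                  config$global_shift / 100, 0)
  delta <- numeric(nrow(cpgs))
  nonzero <- which(truth$planted_delta_percent != 0)
  for (i in nonzero) {
    delta[which(cpgs$promoter == i)] <- truth$planted_delta_percent[i] / 100
  }
  p_control <- .clamp01(p0)
  p_case <- .clamp01(p0 + shift + delta)

  ## non-CpG cytosines (for conversion-rate estimation): fixed positions
  ## offset into the gaps between CpGs
  n_noncpg <- nrow(cpgs)
  noncpg <- data.frame(
    chrom = cpgs$chrom,
    pos = cpgs$pos + 7L,
    context = rep(c("CHH", "CHG"), length.out = n_noncpg),
    stringsAsFactors = FALSE
  )
  noncpg <- noncpg[!paste(noncpg$chrom, noncpg$pos) %in%
                     paste(cpgs$chrom, cpgs$pos), , drop = FALSE]

  list(cpgs = cpgs, p_case = p_case, p_control = p_control,
       truth = truth, noncpg = noncpg)
}

.rcoverage <- function(n, mu, phi) {
  if (phi <= 0) rpois(n, mu) else rnbinom(n, mu = mu, size = 1 / phi)
}

#' Simulate RRBS methylomes for a case/control twin comparison
#'
#' Draws per-sample cytosine count reports over the annotation's CpGs:
#' coverage is negative-binomial, methylated counts are binomial with a
#' latent per-CpG methylation level drawn from the beta distribution of
#' the CpG's region class.  The two groups share each CpG's latent
#' baseline (as genetically identical twins share their epigenetic
#' baseline); the case group additionally receives the configured global
#' shift (promoter/island CpGs) and the planted DMR deltas.  Technical
#' replicates share the group-level methylation and re-draw counts with
#' independent percentage-point jitter.  Non-CpG cytosines are emitted at
#' the configured residual methylation so conversion-rate estimation can
#' be exercised.
#'
#' @param config a [simulation_config()].
#' @param annotation matching [generate_annotation()] model (regenerated
#'   from `config` when omitted).
#' @return A list of class `rrbs_simulation`:
#' * `reports`: named list of cytosine report data.frames, one per
#'   sample (`<group>_rep<k>`), writable with [write_cytosine_report()];
#' * `samples`: data.frame of `sample_id`, `group`, `role`
#'   (case/control), `replicate`;
#' * `truth`: the truth ledger — one row per promoter with its interval,
#'   `planted_delta_percent` and `is_null`;
#' * `annotation`: the annotation model used.
#' @export
simulate_methylomes <- function(config, annotation = NULL) {
  stopifnot(is(config, "simulation_config"))
  if (is.null(annotation)) annotation <- generate_annotation(config)
  latent <- .sim_latent(config, annotation)
  n_cpg <- nrow(latent$cpgs)
  n_non <- nrow(latent$noncpg)
  p_non <- config$noncpg_methylation / 100

  samples <- expand.grid(replicate = seq_len(config$n_replicates),
                         role = c("case", "control"),
                         stringsAsFactors = FALSE)
  samples$group <- unname(config$groups[samples$role])
  samples$sample_id <- sprintf("%s_rep%d", samples$group,
                               samples$replicate)
  samples <- samples[c("sample_id", "group", "role", "replicate")]

  reports <- vector("list", nrow(samples))
  names(reports) <- samples$sample_id
  for (i in seq_len(nrow(samples))) {
    set.seed(.derive_seed(config$seed, i))
    p_group <- if (samples$role[i] == "case") latent$p_case else
      latent$p_control
    p_rep <- .clamp01(p_group + rnorm(n_cpg, 0,
                                      config$replicate_noise_sd / 100))
    cov <- .rcoverage(n_cpg, config$coverage_mean,
                      config$coverage_dispersion)
    meth <- rbinom(n_cpg, cov, p_rep)
    cpg_rows <- data.frame(
      chrom = latent$cpgs$chrom, pos = latent$cpgs$pos, strand = "+",
      count_m = meth, count_u = cov - meth, context = "CpG",
      stringsAsFactors = FALSE
    )
    cov_n <- .rcoverage(n_non, config$coverage_mean,
                        config$coverage_dispersion)
    meth_n <- rbinom(n_non, cov_n, p_non)
    non_rows <- data.frame(
      chrom = latent$noncpg$chrom, pos = latent$noncpg$pos, strand = "+",
      count_m = meth_n, count_u = cov_n - meth_n,
      context = latent$noncpg$context, stringsAsFactors = FALSE
    )
    rep_tab <- rbind(cpg_rows, non_rows)
    rep_tab <- rep_tab[order(rep_tab$chrom, rep_tab$pos), , drop = FALSE]
    rownames(rep_tab) <- NULL
    reports[[i]] <- rep_tab
  }

  structure(
    list(reports = reports, samples = samples, truth = latent$truth,
         annotation = annotation),
    class = "rrbs_simulation"
  )
}

#' @export
print.rrbs_simulation <- function(x, ...) {
  cat("rrbs_simulation: ", length(x$reports), " samples, ",
      nrow(x$truth), " promoters (",
      sum(!x$truth$is_null), " planted DMRs)\n", sep = "")
  invisible(x)
}

#' Write all outputs of a simulation to a directory
#'
#' Writes one cytosine report per sample, BED files for each annotation
#' class, the gene table, and the truth ledger.
#'
#' @param sim an [simulate_methylomes()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(is(sim, "rrbs_simulation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (id in names(sim$reports)) {
    write_cytosine_report(sim$reports[[id]],
                          file.path(dir, paste0(id, ".cytosine.tsv")))
  }
  ann <- sim$annotation
  for (cls in c("promoters", "cpg_islands", "cpg_shores", "exons",
                "introns", "lads", "ilads")) {
    df <- ann[[cls]]
    if (nrow(df) > 0L) write_bed(df, file.path(dir, paste0(cls, ".bed")))
  }
  write.table(ann$genes, file.path(dir, "genes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(sim$truth, file.path(dir, "truth_ledger.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Simulate an expression table coupled to planted methylation changes
#'
#' Generates a gene x sample RPKM matrix in which each gene's expression
#' log2 fold change (case over control) is
#' `-slope * planted_delta / 100` plus Gaussian noise: promoter
#' hypermethylation represses expression.  Baseline abundances are
#' log-normal; replicate values add small log-normal measurement noise.
#'
#' @param config a [simulation_config()] (uses `expression_coupling` and
#'   the master seed).
#' @param truth truth ledger from [simulate_methylomes()].
#' @param n_case,n_control replicate columns per group (defaults 3 and
#'   4).
#' @return list with `rpkm` (matrix, genes x samples), `groups` (named
#'   group vector per column), and `truth_log2fc` (the noiseless coupled
#'   fold change per gene).
#' @export
simulate_expression <- function(config, truth, n_case = 3L,
                                n_control = 4L) {
  stopifnot(is(config, "simulation_config"), is.data.frame(truth),
            all(c("genes", "planted_delta_percent") %in% names(truth)))
  set.seed(.derive_seed(config$seed, 900000L))
  genes <- vapply(strsplit(truth$genes, ",", fixed = TRUE), `[`,
                  character(1), 1L)
  n <- length(genes)
  slope <- config$expression_coupling$slope
  noise <- config$expression_coupling$noise_sd
  base <- rlnorm(n, meanlog = log(50), sdlog = 1)
  lfc <- -slope * truth$planted_delta_percent / 100 +
    rnorm(n, 0, noise)
  rep_noise <- 0.1  # log2-scale within-group measurement noise
  case_cols <- vapply(seq_len(n_case), function(j) {
    base * 2^(lfc + rnorm(n, 0, rep_noise))
  }, numeric(n))
  control_cols <- vapply(seq_len(n_control), function(j) {
    base * 2^rnorm(n, 0, rep_noise)
  }, numeric(n))
  rpkm <- cbind(case_cols, control_cols)
  colnames(rpkm) <- c(sprintf("%s_expr%d", config$groups[["case"]],
                              seq_len(n_case)),
                      sprintf("%s_expr%d", config$groups[["control"]],
                              seq_len(n_control)))
  rownames(rpkm) <- genes
  groups <- setNames(rep(unname(config$groups), c(n_case, n_control)),
                     colnames(rpkm))
  list(rpkm = rpkm, groups = groups, truth_log2fc = setNames(lfc, genes))
}
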