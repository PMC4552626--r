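test_that("generated annotation has the promised geometry", {
  cfg <- simulation_config(seed = 2, n_promoters = 40,
                           chromosome_length = 2e6, n_chromosomes = 2)
  ann <- generate_annotation(cfg)
  expect_s3_class(ann, "annotation_model")
  expect_true(all(ann$promoters$end - ann$promoters$start == 3000))
  expect_equal(nrow(ann$promoters), 40L)
  # shores never overlap islands
  ov <- GenomicRanges::findOverlaps(
    GenomicRanges::GRanges(ann$cpg_shores$chrom,
                           IRanges::IRanges(ann$cpg_shores$start + 1,
                                            ann$cpg_shores$end)),
    GenomicRanges::GRanges(ann$cpg_islands$chrom,
                           IRanges::IRanges(ann$cpg_islands$start + 1,
                                            ann$cpg_islands$end)))
  expect_equal(length(ov), 0L)
  # LADs and iLADs tile each chromosome exactly
  lad_bp <- sum(ann$lads$end - ann$lads$start)
  ilad_bp <- sum(ann$ilads$end - ann$ilads$start)
  expect_equal(lad_bp + ilad_bp, sum(ann$chrom_sizes))

  # no promoters: empty set, iLADs still defined
  cfg0 <- simulation_config(seed = 2, n_promoters = 0,
                            chromosome_length = 2e6, n_chromosomes = 1)
  ann0 <- generate_annotation(cfg0)
  expect_equal(nrow(ann0$promoters), 0L)
  expect_gt(nrow(ann0$ilads), 0L)
})

test_that("infeasible gene packing raises a sizing error", {
  cfg <- simulation_config(seed = 1, n_promoters = 500,
                           chromosome_length = 1e6, n_chromosomes = 1)
  expect_error(generate_annotation(cfg), "infeasible")
})

test_that("the simulator is byte-identical under a fixed seed", {
  cfg <- simulation_config(seed = 101, n_promoters = 15,
                           chromosome_length = 1e6, n_chromosomes = 1,
                           planted_dmrs = data.frame(
                             region_class = "promoter",
                             delta_percent = c(40, -30)))
  s1 <- simulate_methylomes(cfg)
  s2 <- simulate_methylomes(cfg)
  expect_identical(s1$reports, s2$reports)
  expect_identical(s1$truth, s2$truth)
  d1 <- tempfile(); d2 <- tempfile()
  write_simulation(s1, d1)
  write_simulation(s2, d2)
  f1 <- list.files(d1, full.names = TRUE)
  f2 <- list.files(d2, full.names = TRUE)
  expect_equal(basename(f1), basename(f2))
  expect_equal(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("count draws are per-sample streams anchored to the seed", {
  cfg2 <- simulation_config(seed = 101, n_promoters = 15,
                            chromosome_length = 1e6, n_chromosomes = 1,
                            n_replicates = 1L)
  cfg3 <- simulation_config(seed = 101, n_promoters = 15,
                            chromosome_length = 1e6, n_chromosomes = 1,
                            n_replicates = 2L)
  s2 <- simulate_methylomes(cfg2)
  s3 <- simulate_methylomes(cfg3)
  # the first replicate of each group is unchanged by adding a second
  expect_identical(s2$reports[["T21_rep1"]], s3$reports[["T21_rep1"]])
})

test_that("null groups differ by less than a percentage point on average", {
  cfg <- simulation_config(seed = 7, n_promoters = 200,
                           chromosome_length = 5e6, n_chromosomes = 2,
                           background_cpg_density = 2,
                           global_shift = 0)
  sim <- simulate_methylomes(cfg)
  case <- as_methylome(sim$reports$T21_rep1, 20)
  ctrl <- as_methylome(sim$reports$Normal_rep1, 20)
  key_c <- paste(case$calls$chrom, case$calls$pos)
  key_n <- paste(ctrl$calls$chrom, ctrl$calls$pos)
  shared <- intersect(key_c, key_n)
  expect_gt(length(shared), 10000)
  d <- case$calls$percent[match(shared, key_c)] -
    ctrl$calls$percent[match(shared, key_n)]
  expect_lt(abs(mean(d)), 1)
})

test_that("planted promoter deltas are recovered within sampling error", {
  # degenerate noise settings (Poisson coverage, no replicate jitter)
  # isolate binomial sampling, the regime the +/-5 point bound describes
  cfg <- simulation_config(seed = 13, n_promoters = 50,
                           chromosome_length = 3e6, n_chromosomes = 1,
                           cpgs_per_promoter_range = c(20L, 20L),
                           coverage_dispersion = 0,
                           replicate_noise_sd = 0,
                           planted_dmrs = data.frame(
                             region_class = "promoter",
                             delta_percent = rep(40, 5)))
  sim <- simulate_methylomes(cfg)
  planted <- sim$truth[!sim$truth$is_null, ]
  expect_equal(nrow(planted), 5L)
  expect_equal(planted$planted_delta_percent, rep(40, 5))
  case <- pool_methylomes(list(as_methylome(sim$reports$T21_rep1, 1),
                               as_methylome(sim$reports$T21_rep2, 1)))
  ctrl <- pool_methylomes(list(as_methylome(sim$reports$Normal_rep1, 1),
                               as_methylome(sim$reports$Normal_rep2, 1)))
  for (i in seq_len(nrow(planted))) {
    iv <- planted[i, c("chrom", "start", "end")]
    d <- score_region(case, iv, min_coverage = 20)$percent -
      score_region(ctrl, iv, min_coverage = 20)$percent
    expect_lt(abs(d - 40), 5)
  }
})

test_that("latent methylation follows the configured beta baselines", {
  cfg <- simulation_config(seed = 21, n_promoters = 100,
                           chromosome_length = 4e6, n_chromosomes = 1,
                           background_cpg_density = 2,
                           coverage_mean = 60)
  sim <- simulate_methylomes(cfg)
  m <- as_methylome(sim$reports$Normal_rep1, 20)
  ann <- sim$annotation
  cpg_gr <- GenomicRanges::GRanges(m$calls$chrom,
                                   IRanges::IRanges(m$calls$pos, width = 1))
  in_prom <- GenomicRanges::countOverlaps(
    cpg_gr, GenomicRanges::GRanges(ann$promoters$chrom,
                                   IRanges::IRanges(ann$promoters$start + 1,
                                                    ann$promoters$end))) > 0
  in_isl <- GenomicRanges::countOverlaps(
    cpg_gr, GenomicRanges::GRanges(ann$cpg_islands$chrom,
                                   IRanges::IRanges(ann$cpg_islands$start + 1,
                                                    ann$cpg_islands$end))) > 0
  expect_lt(abs(mean(m$calls$percent[in_isl]) - 10), 3)    # beta(1,9)
  expect_lt(abs(mean(m$calls$percent[!in_prom]) - 70), 3)  # beta(7,3)
})

test_that("technical replicates correlate near 0.9", {
  cfg <- simulation_config(seed = 33, n_promoters = 150,
                           chromosome_length = 4e6, n_chromosomes = 2)
  sim <- simulate_methylomes(cfg)
  r <- replicate_correlation(as_methylome(sim$reports$Normal_rep1, 20),
                             as_methylome(sim$reports$Normal_rep2, 20))$r
  expect_gt(r, 0.85)
  expect_lt(r, 0.95)
})

test_that("simulated conversion rate reflects residual non-CpG methylation", {
  cfg <- simulation_config(seed = 3, n_promoters = 50,
                           chromosome_length = 2e6, n_chromosomes = 1)
  sim <- simulate_methylomes(cfg)
  cr <- conversion_rate(sim$reports$T21_rep1)
  expect_gt(cr, 99.5)
  expect_lt(cr, 100)
})

test_that("expression fold changes follow the planted coupling", {
  truth50 <- data.frame(genes = sprintf("g%02d", 1:50),
                        planted_delta_percent = c(rep(0, 40),
                                                  rep(c(40, -40), 5)))
  # under zero coupling the delta / log2FC correlation is null noise
  # (sd ~ 1/sqrt(n-1) = 0.14 at n = 50); check the typical draw, not a
  # single one, since ~4% of null draws legitimately exceed 0.3
  r0 <- vapply(55:59, function(s) {
    cfg0 <- simulation_config(seed = s, expression_coupling =
                                list(slope = 0, noise_sd = 0.5))
    abs(cor(truth50$planted_delta_percent,
            simulate_expression(cfg0, truth50)$truth_log2fc))
  }, numeric(1))
  expect_lt(median(r0), 0.3)

  cfg1 <- simulation_config(seed = 55, expression_coupling =
                              list(slope = 3, noise_sd = 1e-9))
  e1 <- simulate_expression(cfg1, truth50)
  fc <- log2_group_fold_change(e1$rpkm, names(e1$groups)[e1$groups == "T21"],
                               names(e1$groups)[e1$groups == "Normal"])
  expect_lt(cor(truth50$planted_delta_percent, fc$log2fc), -0.95)

  # seven-gene ledger: correlation reproducible by the plain formula
  truth7 <- data.frame(genes = sprintf("hx%d", 1:7),
                       planted_delta_percent = c(35, 62, 45, 45, 31, 41,
                                                 61))
  e7 <- simulate_expression(simulation_config(seed = 56), truth7)
  fc7 <- log2_group_fold_change(e7$rpkm,
                                names(e7$groups)[e7$groups == "T21"],
                                names(e7$groups)[e7$groups == "Normal"])
  got <- meth_expr_correlation(truth7$planted_delta_percent, fc7$log2fc)
  n <- 7
  x <- truth7$planted_delta_percent
  y <- fc7$log2fc
  brute <- (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
  expect_equal(got$r, brute, tolerance = 1e-12)
  expect_lt(got$r, 0)
})
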