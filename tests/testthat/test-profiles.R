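test_that("Mann-Whitney exact p matches enumeration at small n", {
  expect_equal(mann_whitney_u(c(1, 2, 3), c(4, 5, 6))$p, 0.1)
  expect_equal(mann_whitney_u(c(4, 5, 6), c(1, 2, 3))$p, 0.1)
  # identical samples (all tied): no information
  expect_equal(mann_whitney_u(rep(1, 5), rep(1, 7))$p, 1)

  set.seed(99)
  for (i in 1:10) {
    n <- sample(2:6, 1)
    m <- sample(2:6, 1)
    x <- sample(100, n)  # distinct values, tie-free
    y <- sample(100 + seq(101, 200), m)
    got <- mann_whitney_u(x, y)
    expect_equal(got$method, "exact")
    expect_equal(got$p, mw_oracle(x, y), tolerance = 1e-12)
  }
})

test_that("Mann-Whitney agrees with wilcox.test in both regimes", {
  set.seed(5)
  x <- rnorm(12)
  y <- rnorm(15, 0.5)
  expect_equal(mann_whitney_u(x, y)$p,
               stats::wilcox.test(x, y, exact = TRUE)$p.value)
  xl <- rnorm(80)
  yl <- rnorm(90, 0.3)
  expect_equal(mann_whitney_u(xl, yl)$p,
               stats::wilcox.test(xl, yl, exact = FALSE,
                                  correct = TRUE)$p.value,
               tolerance = 1e-10)
  # tie correction path
  xt <- round(rnorm(40), 0)
  yt <- round(rnorm(40, 0.4), 0)
  expect_equal(mann_whitney_u(xt, yt)$p,
               suppressWarnings(stats::wilcox.test(xt, yt,
                                                   correct = TRUE)$p.value),
               tolerance = 1e-10)
})

.small_sim_pair <- function(seed = 77, shift = 0, n_promoters = 60) {
  cfg <- simulation_config(seed = seed, n_promoters = n_promoters,
                           chromosome_length = 3e6, n_chromosomes = 1,
                           global_shift = shift,
                           background_cpg_density = 0.5)
  sim <- simulate_methylomes(cfg)
  list(
    case = pool_methylomes(lapply(sim$samples$sample_id[sim$samples$role ==
                                                          "case"],
                                  function(id) as_methylome(sim$reports[[id]], 1)),
                           group = "T21"),
    control = pool_methylomes(lapply(sim$samples$sample_id[sim$samples$role ==
                                                             "control"],
                                     function(id) as_methylome(sim$reports[[id]], 1)),
                              group = "Normal"),
    sim = sim
  )
}

test_that("identical methylomes compare as identical", {
  pr <- .small_sim_pair()
  fc <- compare_feature(pr$case, pr$case, pr$sim$annotation, "promoters")
  expect_equal(fc$p, 1)
  expect_equal(fc$median_case, fc$median_control)
  # symmetric difference histogram in the two orientations
  expect_equal(fc$diff_hist_case_minus_control,
               rev(fc$diff_hist_control_minus_case))
})

test_that("difference histograms mirror between orientations", {
  pr <- .small_sim_pair(seed = 78, shift = 8)
  fc <- compare_feature(pr$case, pr$control, pr$sim$annotation,
                        "promoters")
  expect_equal(fc$diff_hist_case_minus_control,
               rev(fc$diff_hist_control_minus_case))
  expect_gt(fc$median_cpg_diff, 0)
})

test_that("too few co-scored regions is an explicit error", {
  a <- toy_methylome(c(100, 200, 300), c(20, 0, 10), c(0, 20, 10))
  genes <- data.frame(gene = "G", chrom = "chr1", strand = "+",
                      txStart = 30000, txEnd = 60000)
  ann <- build_annotation(genes, chrom_sizes = c(chr1 = 1e5))
  expect_error(compare_feature(a, a, ann, "promoters"), "insufficient")
})

test_that("a methylome compared to itself has unit fold change", {
  pr <- .small_sim_pair(seed = 80)
  genes <- pr$sim$annotation$genes
  prof <- gene_model_profile(pr$case, pr$case, genes)
  covered <- !prof$flagged
  expect_true(any(covered))
  expect_true(all(prof$fold_change[covered] == 1))
})

test_that("metagene bins partition gene-model CpGs", {
  pr <- .small_sim_pair(seed = 81)
  genes <- pr$sim$annotation$genes
  prof <- gene_model_profile(pr$case, pr$control, genes,
                             min_coverage = 20)
  # synthetic genes (and their 10 kb flanks) never overlap, so pooled
  # bin totals must equal the total filtered coverage
  calls <- pr$case$calls[pr$case$calls$coverage >= 20, ]
  expect_equal(sum(prof$total_case), sum(calls$coverage))
  expect_equal(nrow(prof), 44 + 60 + 44 + 1)
  expect_true(all(table(prof$segment[prof$segment != "intergenic"]) ==
                    c(body = 60, promoter_flank = 44, tts_flank = 44)))
})

test_that("short genes are excluded from the gene model with a warning", {
  pr <- .small_sim_pair(seed = 82)
  genes <- rbind(pr$sim$annotation$genes,
                 data.frame(gene = "stub", chrom = "chr1", strand = "+",
                            txStart = 2.9e6, txEnd = 2.9e6 + 1500))
  expect_warning(prof <- gene_model_profile(pr$case, pr$control, genes),
                 "excluded")
  expect_equal(attr(prof, "n_excluded_genes"), 1L)
  only_short <- genes[genes$gene == "stub", ]
  expect_error(suppressWarnings(
    gene_model_profile(pr$case, pr$control, only_short)), "no usable")
})

test_that("promoter-restricted hypermethylation peaks at the TSS flank", {
  pr <- .small_sim_pair(seed = 83, shift = 15, n_promoters = 80)
  prof <- gene_model_profile(pr$case, pr$control,
                             pr$sim$annotation$genes)
  tss_bins <- prof$segment == "promoter_flank" & prof$bin >= 33
  body_bins <- prof$segment == "body"
  expect_gt(max(prof$fold_change[tss_bins], na.rm = TRUE),
            max(prof$fold_change[body_bins], na.rm = TRUE))
  expect_true(all(prof$fold_change[tss_bins] > 1, na.rm = TRUE))
})

test_that("minus-strand genes are mirrored before binning", {
  # one gene per strand, same span; a CpG cluster just downstream of the
  # plus TSS must land in the same bins as its mirror near the minus TSS
  genes_p <- data.frame(gene = "P", chrom = "chr1", strand = "+",
                        txStart = 50000, txEnd = 60000)
  genes_m <- data.frame(gene = "M", chrom = "chr1", strand = "-",
                        txStart = 50000, txEnd = 60000)
  m_plus <- toy_methylome(c(50101, 50201), c(30, 30), c(0, 0))
  m_minus <- toy_methylome(c(59800, 59900), c(30, 30), c(0, 0))
  prof_p <- gene_model_profile(m_plus, m_plus, genes_p)
  prof_m <- gene_model_profile(m_minus, m_minus, genes_m)
  expect_equal(prof_p$total_case, prof_m$total_case)
})
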