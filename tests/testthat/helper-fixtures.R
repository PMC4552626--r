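# Small in-code fixtures shared across test files.

## methylome from a compact spec: one row per CpG
toy_methylome <- function(pos, count_m, count_u, chrom = "chr1",
                          strand = "+", sample_id = "toy",
                          group = NA_character_, min_coverage = 1L) {
  methylome(data.frame(chrom = chrom, pos = pos, strand = strand,
                       count_m = count_m, count_u = count_u,
                       stringsAsFactors = FALSE),
            sample_id = sample_id, group = group,
            min_coverage = min_coverage)
}

## write a cytosine report and return the path
toy_report_file <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

## random methylome for property-style tests
random_methylome <- function(n = 200, seed = 1, chrom = "chr1") {
  set.seed(seed)
  pos <- sort(sample.int(1e6, n))
  cov <- rpois(n, 30)
  cm <- rbinom(n, cov, runif(n))
  toy_methylome(pos, cm, cov - cm, chrom = chrom, min_coverage = 1L)
}

## independent full-enumeration oracle for the two-sided Fisher test:
## hypergeometric probabilities from binomial coefficients only
fisher_oracle <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  support <- max(0, k - n):min(k, m)
  probs <- choose(m, support) * choose(n, k - support) / choose(m + n, k)
  p_obs <- probs[match(a, support)]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

## independent exact Mann-Whitney oracle: enumerate every assignment of
## the pooled values into the two groups and count U statistics at least
## as extreme (two-sided via doubling the smaller tail)
mw_oracle <- function(x, y) {
  n <- length(x); m <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_of <- function(idx) sum(r[idx]) - n * (n + 1) / 2
  u_obs <- u_of(seq_len(n))
  all_u <- combn(n + m, n, u_of)
  lo <- mean(all_u <= u_obs)
  hi <- mean(all_u >= u_obs)
  min(1, 2 * min(lo, hi))
}
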