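# Checksums of the packaged reference fixtures; verified on load so a
# corrupted or edited transcription fails loudly.
.FIXTURE_MD5 <- c(
  "t21_twin_promoter_dmrs.tsv"       = "f44ceff0c6dc88aa9cae14eafff0944d",
  "chd_twin_common_dmrs.tsv"         = "13d748be8be99f22925f7cfd5690dc3f",
  "morphogenesis_meth_expression.tsv" = "d350b6c51737f1613d3af0d754898854"
)

#' Reference methylation-expression table
#'
#' Methylation differences (percentage points, case minus control) and
#' expression log2 fold changes for the embryonic-organ-morphogenesis
#' genes of the trisomy-21 twin comparison, in fibroblasts and in iPS
#' cells derived from the same twins.  Used to exercise
#' [meth_expr_correlation()] on published values.
#'
#' @return data.frame with columns `gene`, `fib_meth_diff`, `fib_log2fc`,
#'   `ips_meth_diff`, `ips_log2fc`.
#' @export
meth_expr_reference <- function() {
  path <- .extdata("morphogenesis_meth_expression.tsv")
  .check_fixture(path, .FIXTURE_MD5[["morphogenesis_meth_expression.tsv"]])
  tab <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(identical(names(tab), c("gene", "fib_meth_diff", "fib_log2fc",
                                    "ips_meth_diff", "ips_log2fc")))
  tab
}
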