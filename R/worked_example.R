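#' Reported pleiotropic loci for BMI and type 2 diabetes
#'
#' The 23 loci called at conjunction FDR < 0.05 in a published joint cFDR
#' analysis of BMI (GIANT meta-analysis) and type 2 diabetes (trans-ethnic
#' meta-analysis) GWAS summary statistics, shipped as a worked example and
#' as a regression fixture for the conjunction rule: the printed
#' `conj_fdr` column equals the maximum of the two directional cFDR
#' columns in every row, and each directional cFDR is at least the
#' corresponding nominal p-value.
#'
#' @return `data.table` with columns `snp_id`, `role`, `gene`, `chrom`,
#'   `p_bmi`, `p_t2d`, `cfdr_bmi_t2d` (cFDR for BMI given T2D),
#'   `cfdr_t2d_bmi`, `conj_fdr`.
#' @export
bmi_t2d_loci <- function() {
  path <- system.file("extdata", "bmi_t2d_pleiotropic_loci.tsv",
                      package = "pleiocfdr", mustWork = TRUE)
  data.table::fread(path, colClasses = list(character = "chrom"))
}

#' Recompute the conjunction FDR column of [bmi_t2d_loci()]
#'
#' Feeds the table's two directional cFDR columns through
#' [conjunction_fdr()] and returns the resulting table, so the printed
#' `conj_fdr` values can be reproduced by the package's own conjunction
#' arithmetic.
#'
#' @param loci Table in the [bmi_t2d_loci()] layout.
#' @return The [conjunction_fdr()] output for these loci.
#' @export
reconjoin_loci <- function(loci = bmi_t2d_loci()) {
  tab_ab <- data.table::data.table(snp_id = loci$snp_id, chrom = loci$chrom,
                                   p1 = loci$p_bmi, cfdr = loci$cfdr_bmi_t2d)
  tab_ba <- data.table::data.table(snp_id = loci$snp_id, chrom = loci$chrom,
                                   p1 = loci$p_t2d, cfdr = loci$cfdr_t2d_bmi)
  conjunction_fdr(tab_ab, tab_ba)
}
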