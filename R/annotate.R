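# SNP-to-gene assignment by interval logic: a SNP inside a gene interval is
# labelled within_gene (smallest enclosing interval wins); otherwise it is
# intergenic and reports up to two flanking genes within a distance limit,
# nearer first. Interval queries go through GenomicRanges.

#' Annotate SNPs against a gene-interval table
#'
#' @param snps Table with `snp_id`, `chrom`, `pos` (e.g. a merged, cFDR, or
#'   conjunction table).
#' @param genes Gene intervals from [read_gene_intervals()] (1-based
#'   inclusive).
#' @param flank_limit Maximum distance (bp) at which a flanking gene is
#'   reported for intergenic SNPs (default 1 Mb).
#' @return `data.table`: `snp_id`, `role` (`"within_gene"`/`"intergenic"`),
#'   `genes` (comma-joined, nearer flank first; empty when no gene is within
#'   reach), in input row order.
#' @export
annotate_snps <- function(snps, genes, flank_limit = 1e6) {
  stopifnot(flank_limit > 0)
  snps <- data.table::as.data.table(snps)
  genes <- data.table::as.data.table(genes)
  seqlv <- union(unique(snps$chrom), unique(genes$chrom))
  missing_chr <- setdiff(unique(snps$chrom), unique(genes$chrom))
  if (length(missing_chr) > 0) {
    message("annotate_snps: no genes on chromosome(s) ",
            paste(missing_chr, collapse = ", "))
  }
  snp_gr <- GenomicRanges::GRanges(
    seqnames = factor(snps$chrom, levels = seqlv),
    ranges = IRanges::IRanges(start = snps$pos, width = 1))
  gene_gr <- GenomicRanges::GRanges(
    seqnames = factor(genes$chrom, levels = seqlv),
    ranges = IRanges::IRanges(start = genes$start, end = genes$end))

  role <- rep("intergenic", nrow(snps))
  gene_str <- rep("", nrow(snps))

  ov <- GenomicRanges::findOverlaps(snp_gr, gene_gr)
  if (length(ov) > 0) {
    hits <- data.table::data.table(
      snp = S4Vectors::queryHits(ov),
      gene = S4Vectors::subjectHits(ov),
      width = genes$end[S4Vectors::subjectHits(ov)] -
        genes$start[S4Vectors::subjectHits(ov)],
      name = genes$gene_name[S4Vectors::subjectHits(ov)])
    data.table::setorderv(hits, c("snp", "width", "name"))
    best <- hits[!duplicated(hits$snp)]
    role[best$snp] <- "within_gene"
    gene_str[best$snp] <- best$name
  }

  inter <- which(role == "intergenic")
  if (length(inter) > 0) {
    # nearest gene strictly upstream / downstream of each intergenic SNP
    up <- GenomicRanges::follow(snp_gr[inter], gene_gr)
    dn <- GenomicRanges::precede(snp_gr[inter], gene_gr)
    for (k in seq_along(inter)) {
      i <- inter[k]
      cand <- data.table::data.table(gene = integer(0), dist = numeric(0))
      for (g in c(up[k], dn[k])) {
        if (is.na(g)) next
        d <- if (snps$pos[i] < genes$start[g]) genes$start[g] - snps$pos[i]
             else snps$pos[i] - genes$end[g]
        if (d <= flank_limit) {
          cand <- rbind(cand, data.table::data.table(gene = g, dist = d))
        }
      }
      if (nrow(cand) > 0) {
        cand[, "name" := genes$gene_name[gene]]
        data.table::setorderv(cand, c("dist", "name"))
        gene_str[i] <- paste(cand$name, collapse = ",")
      }
    }
  }
  data.table::data.table(snp_id = snps$snp_id, role = role,
                         genes = gene_str)
}
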