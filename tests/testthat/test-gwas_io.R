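test_that("summary statistics are parsed, validated, and sorted", {
  path <- write_stats_tsv(tiny_stats_df())
  ss <- read_summary_stats(path)
  expect_equal(nrow(ss), 3)
  expect_equal(ss$snp_id, c("rs1", "rs2", "rs3"))     # (chrom, pos) order
  expect_equal(ss$pvalue, c(0.5, 1e-8, 0.99))
  expect_true(all(ss$pvalue > 0 & ss$pvalue <= 1))
})

test_that("p-value domain rules: zero clamped, out-of-range dropped", {
  df <- tiny_stats_df()
  df$P <- c(0, 1.5, 0.2)
  path <- write_stats_tsv(df)
  expect_warning(ss <- suppressMessages(read_summary_stats(path)),
                 "clamped")
  expect_equal(nrow(ss), 2)                            # p = 1.5 dropped
  expect_equal(ss$pvalue[ss$snp_id == "rs1"], 1e-300)  # clamp floor
})

test_that("chromosome labels normalized and duplicates keep first", {
  df <- data.frame(SNP = c("rs1", "rs1", "rs2"),
                   CHR = c("chr2", "chr2", "chr10"),
                   BP = c(10L, 20L, 30L), P = c(0.1, 0.2, 0.3))
  path <- write_stats_tsv(df)
  expect_message(ss <- read_summary_stats(path), "duplicate")
  expect_equal(nrow(ss), 2)
  expect_setequal(ss$chrom, c("2", "10"))
  expect_equal(ss$pvalue[ss$snp_id == "rs1"], 0.1)     # first occurrence
  expect_equal(ss$chrom, c("2", "10"))                 # numeric chrom order
})

test_that("missing mapped column and empty file are configuration errors", {
  df <- tiny_stats_df()
  names(df)[4] <- "PVAL"
  expect_error(read_summary_stats(write_stats_tsv(df)), "absent from header")
  expect_error(read_summary_stats(write_stats_tsv(df),
                                  column_map = c(pvalue = "PVAL")), NA)
  df2 <- tiny_stats_df()
  df2$P <- c(2, 3, -1)
  expect_error(suppressMessages(read_summary_stats(write_stats_tsv(df2))),
               "no valid rows")
})

test_that("merge keeps exactly the shared SNP ids, symmetric in the id set", {
  a <- validate_summary_stats(data.table::data.table(
    snp_id = c("rs1", "rs2", "rs3"), chrom = "1", pos = c(10L, 20L, 30L),
    pvalue = c(0.1, 0.2, 0.3)))
  b <- validate_summary_stats(data.table::data.table(
    snp_id = c("rs2", "rs3", "rs4"), chrom = "1", pos = c(20L, 30L, 40L),
    pvalue = c(0.4, 0.5, 0.6)))
  m <- merge_common_snps(a, b)
  expect_setequal(m$snp_id, c("rs2", "rs3"))
  expect_equal(m$p1[m$snp_id == "rs2"], 0.2)
  expect_equal(m$p2[m$snp_id == "rs2"], 0.4)
  expect_setequal(merge_common_snps(b, a)$snp_id, m$snp_id)
  expect_setequal(merge_common_snps(a, a)$snp_id, a$snp_id)
  c_tab <- validate_summary_stats(data.table::data.table(
    snp_id = "rs9", chrom = "1", pos = 5L, pvalue = 0.5))
  expect_error(merge_common_snps(a, c_tab), "empty intersection|no SNPs shared")
})

test_that("results tables round-trip bit-identically and empty tables error", {
  tab <- data.table::data.table(snp_id = "rs1", chrom = "1", pos = 10L,
                                p1 = 1 / 3, p2 = exp(-30), ccdf = pi / 10,
                                cfdr = 2 / 7)
  path <- tempfile(fileext = ".tsv")
  write_results_table(tab, path)
  expect_equal(length(readLines(path)), 2)       # header + one row
  back <- data.table::fread(path, colClasses = list(character = "chrom"))
  expect_identical(back$p1, tab$p1)
  expect_identical(back$p2, tab$p2)
  expect_identical(back$cfdr, tab$cfdr)
  path2 <- tempfile(fileext = ".tsv")
  expect_error(write_results_table(tab[0], path2), "empty")
  expect_false(file.exists(path2))
})

test_that("reference panel reader rejects bad dosages and derives MAF", {
  dos <- rbind(c(0, 1, 2, 0), c(2, 2, 1, 2))
  panel <- panel_from_dosages(dos)
  expect_equal(panel$info$maf, c(min(3 / 8, 5 / 8), min(7 / 8, 1 / 8)))
  df <- data.frame(snp_id = "rs1", chrom = "1", pos = 1L,
                   s1 = 3, s2 = 1)
  path <- tempfile(fileext = ".tsv")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_reference_panel(path), "outside \\{0, 1, 2\\}")
})

test_that("gene intervals convert BED coordinates to 1-based inclusive", {
  path <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t99\t200\tGENEA", "1\t899\t1000\tGENEB"), path)
  genes <- read_gene_intervals(path)
  expect_equal(genes$start, c(100L, 900L))
  expect_equal(genes$end, c(200L, 1000L))
  expect_equal(genes$chrom, c("1", "1"))
})
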