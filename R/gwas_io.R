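# Reading, validation, and harmonization of GWAS summary-statistic tables,
# genotype reference panels, and gene-interval files. All tabular I/O is
# header-bearing TSV via data.table.

#' Read a GWAS summary-statistics table
#'
#' Reads a whitespace/tab-delimited per-SNP association table, validates it,
#' and returns a harmonized table sorted by genomic position. The p-value
#' domain required downstream is (0, 1]: exact zeros (which occur in
#' downloaded meta-analysis files when the true value underflows) are clamped
#' to `1e-300`; negative, greater-than-one, or non-numeric p-values are
#' dropped with a reported count. Chromosome labels are normalized by
#' stripping a leading `"chr"`. Duplicate SNP identifiers keep their first
#' occurrence in file order.
#'
#' @param path Path to a delimited text file with a header line.
#' @param column_map Named character vector mapping the logical columns
#'   `snp_id`, `chrom`, `pos`, `pvalue` (and optionally `maf`) to the
#'   physical column names in the file header. Defaults to the conventional
#'   `SNP`/`CHR`/`BP`/`P`/`MAF` names.
#' @return A `data.table` with columns `snp_id`, `chrom`, `pos`, `pvalue`
#'   (and `maf` when mapped), sorted by (chromosome, position).
#' @export
read_summary_stats <- function(path,
                               column_map = c(snp_id = "SNP", chrom = "CHR",
                                              pos = "BP", pvalue = "P",
                                              maf = "MAF")) {
  if (!file.exists(path)) {
    stop("summary-statistics file not found: ", path)
  }
  defaults <- c(snp_id = "SNP", chrom = "CHR", pos = "BP", pvalue = "P",
                maf = "MAF")
  cm <- defaults
  cm[names(column_map)] <- column_map
  raw <- data.table::fread(path, header = TRUE)
  required <- cm[c("snp_id", "chrom", "pos", "pvalue")]
  missing_cols <- required[!required %in% names(raw)]
  if (length(missing_cols) > 0) {
    stop("mapped column(s) absent from header of ", path, ": ",
         paste(missing_cols, collapse = ", "))
  }
  has_maf <- cm["maf"] %in% names(raw)
  dt <- data.table::data.table(
    snp_id = as.character(raw[[cm["snp_id"]]]),
    chrom  = normalize_chrom(raw[[cm["chrom"]]]),
    pos    = suppressWarnings(as.integer(raw[[cm["pos"]]])),
    pvalue = suppressWarnings(as.numeric(raw[[cm["pvalue"]]]))
  )
  if (has_maf) {
    dt[, "maf" := suppressWarnings(as.numeric(raw[[cm["maf"]]]))]
  }
  dt <- validate_summary_stats(dt, label = basename(path))
  dt
}

#' Validate and sort an in-memory summary-statistics table
#'
#' Applies the same clamping/dropping rules as [read_summary_stats()] to a
#' table already in memory (e.g. simulator output).
#'
#' @param dt `data.table` with columns `snp_id`, `chrom`, `pos`, `pvalue`.
#' @param label Name used in messages.
#' @return Validated table sorted by (chromosome, position).
#' @export
validate_summary_stats <- function(dt, label = "summary stats") {
  dt <- data.table::as.data.table(dt)
  n0 <- nrow(dt)
  n_zero <- sum(!is.na(dt$pvalue) & dt$pvalue == 0)
  if (n_zero > 0) {
    warning(label, ": ", n_zero, " p-value(s) of exactly 0 clamped to 1e-300")
    dt[pvalue == 0, "pvalue" := 1e-300]
  }
  keep <- !is.na(dt$pvalue) & dt$pvalue > 0 & dt$pvalue <= 1 &
    !is.na(dt$pos) & dt$pos >= 1 & !is.na(dt$snp_id)
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message(label, ": dropped ", n_dropped,
            " row(s) with out-of-range or non-numeric fields")
    dt <- dt[keep]
  }
  dup <- duplicated(dt$snp_id)
  if (any(dup)) {
    message(label, ": ", sum(dup),
            " duplicate SNP id(s); first occurrence kept")
    dt <- dt[!dup]
  }
  if (nrow(dt) == 0) {
    stop(label, ": no valid rows after validation")
  }
  sort_by_position(dt)
  dt[]
}

#' Merge the SNPs common to two traits' summary statistics
#'
#' Inner join on SNP identifier; this intersection is the unit on which all
#' cFDR computation operates. Genomic coordinates are taken from the first
#' (principal) table.
#'
#' @param a,b Validated summary-statistics tables ([read_summary_stats()]).
#' @return `data.table` with columns `snp_id`, `chrom`, `pos`, `p1` (p-value
#'   from `a`), `p2` (p-value from `b`), sorted by position.
#' @export
merge_common_snps <- function(a, b) {
  left <- data.table::as.data.table(a)[, list(snp_id, chrom, pos, p1 = pvalue)]
  right <- data.table::as.data.table(b)[, list(snp_id, p2 = pvalue)]
  merged <- merge(left, right, by = "snp_id")
  if (nrow(merged) == 0) {
    stop("no SNPs shared between the two summary-statistics tables ",
         "(empty intersection)")
  }
  sort_by_position(merged)
  merged[]
}

#' Read a genotype reference panel
#'
#' The panel format is a TSV whose first three columns are `snp_id`, `chrom`,
#' `pos` followed by one dosage column per sample with entries in {0, 1, 2}.
#' Minor allele frequency is derived from the dosages as `min(f, 1 - f)` with
#' `f = mean(dosage) / 2`.
#'
#' @param path Path to the panel TSV.
#' @return A `ref_panel`: list with `info` (`data.table`: `snp_id`, `chrom`,
#'   `pos`, `maf`) and `dosages` (numeric matrix, one row per SNP, rownames =
#'   SNP ids).
#' @export
read_reference_panel <- function(path) {
  if (!file.exists(path)) stop("reference-panel file not found: ", path)
  raw <- data.table::fread(path, header = TRUE)
  if (ncol(raw) < 4) {
    stop("reference panel must have snp_id, chrom, pos plus >=1 dosage column")
  }
  dos <- as.matrix(raw[, -(1:3)])
  storage.mode(dos) <- "double"
  bad <- !(dos %in% c(0, 1, 2))
  if (any(bad)) {
    stop("reference panel contains ", sum(bad),
         " dosage value(s) outside {0, 1, 2}")
  }
  rownames(dos) <- as.character(raw[[1]])
  new_ref_panel(snp_id = as.character(raw[[1]]),
                chrom = normalize_chrom(raw[[2]]),
                pos = as.integer(raw[[3]]),
                dosages = dos)
}

# internal constructor shared by the reader and the simulator
new_ref_panel <- function(snp_id, chrom, pos, dosages) {
  f <- rowMeans(dosages) / 2
  info <- data.table::data.table(snp_id = snp_id, chrom = chrom, pos = pos,
                                 maf = pmin(f, 1 - f))
  structure(list(info = info, dosages = dosages), class = "ref_panel")
}

#' Write a reference panel to the TSV format [read_reference_panel()] expects
#' @param panel A `ref_panel`.
#' @param path Output path.
#' @export
write_reference_panel <- function(panel, path) {
  dt <- data.table::data.table(panel$info[, list(snp_id, chrom, pos)])
  dos <- data.table::as.data.table(panel$dosages)
  data.table::setnames(dos, paste0("s", seq_len(ncol(dos))))
  data.table::fwrite(cbind(dt, dos), path, sep = "\t")
  invisible(path)
}

#' Read a BED-like gene-interval table
#'
#' Four columns without header: chrom, start, end, gene_name. BED half-open
#' 0-based coordinates are converted to 1-based inclusive.
#'
#' @param path Path to the BED-like file.
#' @return `data.table` with `gene_name`, `chrom`, `start`, `end`, sorted by
#'   (chromosome, start).
#' @export
read_gene_intervals <- function(path) {
  if (!file.exists(path)) stop("gene-interval file not found: ", path)
  raw <- data.table::fread(path, header = FALSE,
                           col.names = c("chrom", "start", "end", "gene_name"))
  genes <- data.table::data.table(
    gene_name = as.character(raw$gene_name),
    chrom = normalize_chrom(raw$chrom),
    start = as.integer(raw$start) + 1L,
    end = as.integer(raw$end)
  )
  if (any(genes$start > genes$end)) stop("gene interval with start > end")
  data.table::setorderv(genes, c("chrom", "start"))
  genes[]
}

#' Write a results table as TSV
#'
#' Full float precision (values round-trip through [data.table::fread()]
#' bit-identically); one header line.
#'
#' @param table Non-empty `data.table`/`data.frame`.
#' @param path Output path.
#' @export
write_results_table <- function(table, path) {
  if (is.null(table) || nrow(table) == 0) {
    stop("refusing to write an empty results table to ", path)
  }
  out <- data.table::copy(data.table::as.data.table(table))
  for (col in names(out)) {
    # 17 significant digits so doubles survive a read round trip exactly
    if (is.double(out[[col]])) {
      data.table::set(out, j = col, value = sprintf("%.17g", out[[col]]))
    }
  }
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

# --- helpers -----------------------------------------------------------------

normalize_chrom <- function(x) {
  sub("^chr", "", as.character(x), ignore.case = TRUE)
}

# numeric chromosomes in numeric order first, then others alphabetically;
# modifies by reference and also returns the table
sort_by_position <- function(dt) {
  num <- suppressWarnings(as.numeric(dt$chrom))
  dt[, "..chrom_rank" := data.table::frank(
    list(ifelse(is.na(num), Inf, num), dt$chrom), ties.method = "dense")]
  data.table::setorderv(dt, c("..chrom_rank", "pos"))
  dt[, "..chrom_rank" := NULL]
  dt
}
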