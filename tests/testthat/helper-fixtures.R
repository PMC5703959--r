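# Fixtures are built in code; independent oracles live here so the tests
# they back stay decoupled from the implementation.

write_stats_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

tiny_stats_df <- function() {
  data.frame(SNP = c("rs1", "rs2", "rs3"),
             CHR = c("1", "1", "2"),
             BP = c(100L, 200L, 50L),
             P = c(0.5, 1e-8, 0.99))
}

make_merged <- function(p1, p2, chrom = "1") {
  n <- length(p1)
  data.table::data.table(snp_id = paste0("rs", seq_len(n)), chrom = chrom,
                         pos = seq_len(n) * 100L, p1 = p1, p2 = p2)
}

merged_from_sim <- function(sim_out) {
  merge_common_snps(validate_summary_stats(sim_out$stats_a, "A"),
                    validate_summary_stats(sim_out$stats_b, "B"))
}

# panel built directly from a dosage matrix (rows = SNPs)
panel_from_dosages <- function(dos, chrom = "1",
                               ids = paste0("rs", seq_len(nrow(dos)))) {
  path <- tempfile(fileext = ".tsv")
  df <- data.frame(snp_id = ids, chrom = chrom,
                   pos = seq_len(nrow(dos)) * 100L)
  df <- cbind(df, as.data.frame(dos))
  names(df)[-(1:3)] <- paste0("s", seq_len(ncol(dos)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  read_reference_panel(path)
}

# --- oracle: per-SNP cFDR by direct double-loop counting ---------------------
oracle_cfdr <- function(p1, p2) {
  n <- length(p1)
  vapply(seq_len(n), function(i) {
    n_cond <- sum(p2 <= p2[i])
    n_joint <- sum(p1 <= p1[i] & p2 <= p2[i])
    min(1, p1[i] * n_cond / n_joint)
  }, numeric(1))
}

oracle_joint_counts <- function(p1, p2) {
  n <- length(p1)
  vapply(seq_len(n), function(i) sum(p1 <= p1[i] & p2 <= p2[i]), numeric(1))
}

# --- oracle: naive sliding-window greedy pruning -----------------------------
# Straightforward re-statement of the procedure with explicit loops over the
# survivor list; intentionally unoptimized and written independently of
# ld_prune().
oracle_prune <- function(snps, panel, params) {
  snps <- data.table::as.data.table(snps)
  prow <- match(snps$snp_id, panel$info$snp_id)
  keep <- rep(TRUE, nrow(snps))
  r2_of <- function(i, j) {
    gi <- panel$dosages[prow[i], ]; gj <- panel$dosages[prow[j], ]
    if (var(gi) == 0 || var(gj) == 0) return(0)
    cor(gi, gj)^2
  }
  for (ch in unique(snps$chrom)) {
    chrom_rows <- which(snps$chrom == ch)
    repeat {
      removed <- FALSE
      start <- 1
      repeat {
        alive <- chrom_rows[keep[chrom_rows]]
        if (start > length(alive) - 1) break
        win <- alive[start:min(start + params$window - 1, length(alive))]
        in_win <- rep(TRUE, length(win))
        for (a in seq_len(length(win) - 1)) {
          if (!in_win[a]) next
          for (b in (a + 1):length(win)) {
            if (!in_win[b]) next
            ia <- win[a]; ib <- win[b]
            if (is.na(prow[ia]) || is.na(prow[ib])) next
            if (r2_of(ia, ib) > params$r2_threshold) {
              ma <- panel$info$maf[prow[ia]]; mb <- panel$info$maf[prow[ib]]
              victim <- if (ma < mb) a
                        else if (mb < ma) b
                        else if (snps$pos[ia] > snps$pos[ib]) a else b
              in_win[victim] <- FALSE
              keep[win[victim]] <- FALSE
              removed <- TRUE
              if (victim == a) break
            }
          }
        }
        start <- start + params$step
      }
      if (!removed) break
    }
  }
  snps[keep]
}

# --- oracle: fold enrichment by direct proportion counting -------------------
oracle_fold <- function(merged, t, x) {
  nl <- -log10(merged$p1)
  s <- merged$p2 <= t
  (sum(nl[s] >= x) / sum(s)) / (sum(nl >= x) / nrow(merged))
}
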