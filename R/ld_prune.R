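# Sliding-window, MAF-aware LD pruning of a merged SNP set against a
# genotype reference panel. r^2 is the squared Pearson correlation of 0/1/2
# dosages (composite LD on unphased genotypes).

#' Pruning parameters
#'
#' @param window Number of SNPs per window (default 50).
#' @param step SNPs the window slides forward (default 5).
#' @param r2_threshold Pairs with r^2 above this are pruned (default 0.2).
#' @return Validated `prune_params` list.
#' @export
prune_params <- function(window = 50L, step = 5L, r2_threshold = 0.2) {
  stopifnot(window >= 2, step >= 1, step <= window,
            r2_threshold > 0, r2_threshold < 1)
  structure(list(window = as.integer(window), step = as.integer(step),
                 r2_threshold = r2_threshold), class = "prune_params")
}

#' Squared Pearson correlation between two dosage vectors
#'
#' @param g1,g2 Equal-length numeric vectors (length >= 2), neither constant.
#' @return r^2 in \[0, 1\].
#' @export
compute_r2 <- function(g1, g2) {
  stopifnot(length(g1) == length(g2), length(g1) >= 2)
  if (stats::var(g1) == 0 || stats::var(g2) == 0) {
    stop("undefined correlation: constant dosage vector")
  }
  stats::cor(g1, g2)^2
}

#' Prune correlated SNPs with a sliding window
#'
#' Per chromosome: a window of `window` surviving SNPs is scanned; for every
#' pair with r^2 above the threshold the smaller-MAF member is removed
#' (equal MAF: the larger-position member), removals taking effect
#' immediately within the window; the window then slides `step` surviving
#' SNPs forward. Whole-chromosome passes repeat until a pass removes
#' nothing. SNPs absent from the panel are retained unconditionally, and
#' pairs involving them are skipped (their r^2 cannot be evaluated).
#'
#' @param snps Merged table ([merge_common_snps()]) sorted by position.
#' @param panel A `ref_panel`.
#' @param params A [prune_params()].
#' @return The subset of `snps` surviving pruning, original order preserved.
#' @export
ld_prune <- function(snps, panel, params = prune_params()) {
  stopifnot(inherits(panel, "ref_panel"), inherits(params, "prune_params"))
  snps <- data.table::as.data.table(snps)
  row_panel <- match(snps$snp_id, panel$info$snp_id)
  maf <- panel$info$maf[row_panel]          # NA when absent from panel
  keep <- rep(TRUE, nrow(snps))
  for (ch in unique(snps$chrom)) {
    chrom_idx <- which(snps$chrom == ch)
    repeat {
      removed_in_pass <- FALSE
      start <- 1L
      repeat {
        alive <- chrom_idx[keep[chrom_idx]]
        if (start > length(alive) - 1L) break
        win <- alive[start:min(start + params$window - 1L, length(alive))]
        res <- prune_window(win, row_panel, maf, panel$dosages,
                            params$r2_threshold, snps$pos)
        if (length(res) > 0) {
          keep[res] <- FALSE
          removed_in_pass <- TRUE
        }
        start <- start + params$step
      }
      if (!removed_in_pass) break
    }
  }
  snps[keep]
}

# greedy within-window removal; returns row indices (into snps) to drop
prune_window <- function(win, row_panel, maf, dosages, r2_threshold, pos) {
  in_panel <- !is.na(row_panel[win])
  # correlation matrix over the window's panel-bearing SNPs
  sub <- win[in_panel]
  if (length(sub) < 2) return(integer(0))
  cm <- suppressWarnings(stats::cor(t(dosages[row_panel[sub], , drop = FALSE])))
  cm[is.na(cm)] <- 0  # constant dosages: treat pairs as unlinked
  alive <- rep(TRUE, length(sub))
  drop <- integer(0)
  for (i in seq_len(length(sub) - 1L)) {
    if (!alive[i]) next
    for (j in (i + 1L):length(sub)) {
      if (!alive[j]) next
      if (cm[i, j]^2 > r2_threshold) {
        mi <- maf[sub[i]]; mj <- maf[sub[j]]
        victim <- if (mi < mj) i
                  else if (mj < mi) j
                  else if (pos[sub[i]] > pos[sub[j]]) i else j
        alive[victim] <- FALSE
        drop <- c(drop, sub[victim])
        if (victim == i) break
      }
    }
  }
  drop
}

#' Check the pruning postcondition
#'
#' `TRUE` iff no pair of SNPs lying within any `window`-length run of
#' consecutive survivors on the same chromosome has r^2 above the threshold
#' (pairs with a member absent from the panel, or with constant dosages, are
#' skipped, matching [ld_prune()]).
#'
#' @inheritParams ld_prune
#' @return Logical scalar.
#' @export
verify_pruned <- function(snps, panel, params = prune_params()) {
  snps <- data.table::as.data.table(snps)
  row_panel <- match(snps$snp_id, panel$info$snp_id)
  for (ch in unique(snps$chrom)) {
    idx <- which(snps$chrom == ch & !is.na(row_panel))
    if (length(idx) < 2) next
    d <- dosages_scaled(panel$dosages[row_panel[idx], , drop = FALSE])
    n <- ncol(panel$dosages)
    for (lag in 1:(min(params$window, length(idx)) - 1L)) {
      if (lag >= length(idx)) break
      i <- seq_len(length(idx) - lag)
      # but pairs must be within `window` consecutive survivors counting
      # SNPs missing from the panel as well: use positions in the full
      # per-chromosome survivor list
      full <- which(snps$chrom == ch)
      posn <- match(idx, full)
      ok <- posn[i + lag] - posn[i] <= params$window - 1L
      if (!any(ok)) next
      r <- rowSums(d[i[ok], , drop = FALSE] * d[i[ok] + lag, , drop = FALSE]) /
        (n - 1)
      if (any(r^2 > params$r2_threshold, na.rm = TRUE)) return(FALSE)
    }
  }
  TRUE
}

# rows standardized to zero mean / unit sd; constant rows become all-zero
# (their correlations then evaluate to 0, i.e. treated as unlinked)
dosages_scaled <- function(d) {
  mu <- rowMeans(d)
  sd <- sqrt(apply(d, 1, stats::var))
  sd[sd == 0] <- Inf
  (d - mu) / sd
}
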