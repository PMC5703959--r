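# Conditional FDR estimation from paired p-values via conditional empirical
# cumulative distribution functions, conjunction FDR, and locus calling.
#
# For SNP i with principal-trait p-value p1[i] and conditioning-trait
# p-value p2[i]:
#   n_cond  = #{j : p2[j] <= p2[i]}                       (self-inclusive)
#   n_joint = #{j : p1[j] <= p1[i] and p2[j] <= p2[i]}    (self-inclusive)
#   ccdf    = n_joint / n_cond
#   cfdr    = min(1, p1[i] / ccdf)
# Self-inclusive counting guarantees n_joint >= 1, so the estimator is
# defined for every SNP, and ccdf <= 1 implies cfdr >= p1.

#' Conditional empirical CDF counts for one SNP
#'
#' Direct O(N) counting; used for spot checks and worked examples. The
#' vectorized table-wide computation lives in [cfdr_estimate()].
#'
#' @param p1,p2 Equal-length p-value vectors in (0, 1].
#' @param i Index of the SNP of interest.
#' @return Named numeric: `n_cond`, `n_joint`, `ccdf`.
#' @export
conditional_cdf <- function(p1, p2, i) {
  stopifnot(length(p1) == length(p2), length(p1) >= 1,
            i >= 1, i <= length(p1))
  n_cond <- sum(p2 <= p2[i])
  n_joint <- sum(p1 <= p1[i] & p2 <= p2[i])
  c(n_cond = n_cond, n_joint = n_joint, ccdf = n_joint / n_cond)
}

#' Per-SNP conditional FDR for one conditioning direction
#'
#' Direction `"A|B"` treats the merged table's `p1` as the principal trait
#' and `p2` as the conditioning trait; `"B|A"` swaps the roles. Counting is
#' inclusive on both sides (ties counted), and every SNP counts itself, so
#' the estimate is defined everywhere.
#'
#' @param merged Merged table from [merge_common_snps()] (typically after
#'   [ld_prune()]).
#' @param direction `"A|B"` or `"B|A"`.
#' @return A `data.table` (one row per SNP, input order): `snp_id`, `chrom`,
#'   `pos`, `p1` (principal), `p2` (conditioning), `n_cond`, `n_joint`,
#'   `ccdf`, `cfdr`. The direction is recorded in the `"direction"`
#'   attribute.
#' @export
cfdr_estimate <- function(merged, direction = c("A|B", "B|A")) {
  direction <- match.arg(direction)
  merged <- data.table::as.data.table(merged)
  if (nrow(merged) == 0) stop("cfdr_estimate: empty merged table")
  stopifnot(all(c("p1", "p2") %in% names(merged)))
  if (direction == "A|B") {
    pp1 <- merged$p1; pp2 <- merged$p2
  } else {
    pp1 <- merged$p2; pp2 <- merged$p1
  }
  n_cond <- rank_leq(pp2)
  n_joint <- joint_leq_counts(pp1, pp2)
  ccdf <- n_joint / n_cond
  out <- data.table::data.table(
    snp_id = merged$snp_id, chrom = merged$chrom, pos = merged$pos,
    p1 = pp1, p2 = pp2, n_cond = n_cond, n_joint = n_joint,
    ccdf = ccdf, cfdr = pmin(1, pp1 * n_cond / n_joint))
  data.table::setattr(out, "direction", direction)
  out
}

# #{j: x[j] <= x[i]} for every i (max rank under ties)
rank_leq <- function(x) {
  as.integer(rank(x, ties.method = "max"))
}

# Self-inclusive two-dimensional dominance counts
#   out[i] = #{j : a[j] <= a[i] and b[j] <= b[i]}
# computed exactly (ties inclusive on both coordinates) with a Fenwick tree
# over dense ranks of `a`, sweeping b-tie groups in ascending order:
# O(N log N), no dependence on input order.
joint_leq_counts <- function(a, b) {
  n <- length(a)
  ra <- data.table::frank(a, ties.method = "dense")
  K <- max(ra)
  tree <- integer(K)
  out <- integer(n)
  ord <- order(b)
  bo <- b[ord]
  pos <- 1L
  while (pos <= n) {
    end <- pos
    while (end < n && bo[end + 1L] == bo[pos]) end <- end + 1L
    for (k in pos:end) {            # insert the whole b-tie group first
      i <- ra[ord[k]]
      while (i <= K) {
        tree[i] <- tree[i] + 1L
        i <- i + bitwAnd(i, -i)
      }
    }
    for (k in pos:end) {            # then query each member
      i <- ra[ord[k]]
      s <- 0L
      while (i > 0L) {
        s <- s + tree[i]
        i <- i - bitwAnd(i, -i)
      }
      out[ord[k]] <- s
    }
    pos <- end + 1L
  }
  out
}

#' Conjunction FDR from the two directional cFDR tables
#'
#' The conjunction FDR of a SNP — a conservative FDR for association with
#' BOTH traits — is the maximum of its two directional cFDR values.
#'
#' @param table_ab cFDR table for direction A|B ([cfdr_estimate()]).
#' @param table_ba cFDR table for direction B|A, over the same SNP ids.
#' @return `data.table` with `snp_id` (and `chrom`, `pos` when present),
#'   `p_a`, `p_b`, `cfdr_ab`, `cfdr_ba`, `conj_fdr`, in `table_ab` row
#'   order.
#' @export
conjunction_fdr <- function(table_ab, table_ba) {
  table_ab <- data.table::as.data.table(table_ab)
  table_ba <- data.table::as.data.table(table_ba)
  bad <- c(setdiff(table_ab$snp_id, table_ba$snp_id),
           setdiff(table_ba$snp_id, table_ab$snp_id))
  if (length(bad) > 0) {
    stop("conjunction_fdr: SNP id sets differ between directions; e.g. ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  at <- match(table_ab$snp_id, table_ba$snp_id)
  out <- data.table::data.table(snp_id = table_ab$snp_id)
  for (col in c("chrom", "pos")) {
    if (col %in% names(table_ab)) out[, (col) := table_ab[[col]]]
  }
  out[, "p_a" := table_ab$p1]
  out[, "p_b" := table_ba$p1[at]]
  out[, "cfdr_ab" := table_ab$cfdr]
  out[, "cfdr_ba" := table_ba$cfdr[at]]
  out[, "conj_fdr" := pmax(table_ab$cfdr, table_ba$cfdr[at])]
  out[]
}

#' Call significant SNPs from a cFDR or conjunction table
#'
#' Retains rows with the chosen field strictly below `alpha` (the boundary
#' value itself is excluded), sorted ascending by that field.
#'
#' @param table A table from [cfdr_estimate()] or [conjunction_fdr()].
#' @param alpha Significance threshold on the FDR scale (default 0.05).
#' @param field Column to threshold: `"cfdr"` or `"conj_fdr"`.
#' @return The significant subset, sorted ascending by `field`.
#' @export
call_significant <- function(table, alpha = 0.05,
                             field = c("cfdr", "conj_fdr")) {
  field <- match.arg(field)
  stopifnot(alpha > 0, alpha <= 1)
  table <- data.table::as.data.table(table)
  if (!field %in% names(table)) {
    stop("call_significant: column '", field, "' not present in table")
  }
  out <- table[table[[field]] < alpha]
  data.table::setorderv(out, field)
  out[]
}
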