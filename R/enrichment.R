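# Conditional Q-Q curves, fold-enrichment curves, and conditional Manhattan
# plot data. Computation is separated from rendering: the *_data functions
# return plain tables that tests can interrogate; render_plots() only draws.

#' Conditioning levels for stratified diagnostics
#'
#' A strictly decreasing vector of conditioning-trait p-value cutoffs whose
#' first element is 1.0 (the all-SNPs stratum). The default decade strata
#' 1, 0.1, 0.01, 0.001 are the conventional choice for conditional Q-Q
#' plots.
#'
#' @param thresholds Descending numeric vector in (0, 1], starting at 1.
#' @export
conditioning_levels <- function(thresholds = c(1, 0.1, 0.01, 0.001)) {
  stopifnot(length(thresholds) >= 1, thresholds[1] == 1,
            all(thresholds > 0), all(thresholds <= 1),
            all(diff(thresholds) < 0))
  thresholds
}

#' Conditional Q-Q curves
#'
#' For each conditioning level t the stratum S_t = {i : p2_i <= t} is formed;
#' within it the principal p-values are sorted ascending and plotted as
#' x_k = k / |S_t| (the empirical cdf position) against
#' y_k = -log10(p1_(k)). Enrichment shows as the small-t curves lying above
#' the all-SNPs curve. Levels yielding empty strata are dropped with a
#' warning.
#'
#' @param merged Merged table with columns `p1` (principal) and `p2`
#'   (conditioning).
#' @param levels A [conditioning_levels()] vector.
#' @return `data.table` of class `qq_curves`: `threshold`, `n_stratum`, `x`,
#'   `y` (one row per point; within a threshold, x ascending and y
#'   non-increasing).
#' @export
conditional_qq <- function(merged, levels = conditioning_levels()) {
  merged <- data.table::as.data.table(merged)
  if (nrow(merged) == 0) stop("conditional_qq: empty input")
  pieces <- list()
  for (t in levels) {
    p1s <- sort(merged$p1[merged$p2 <= t])
    if (length(p1s) == 0) {
      warning("conditional_qq: stratum p2 <= ", t, " is empty; dropped")
      next
    }
    pieces[[length(pieces) + 1]] <- data.table::data.table(
      threshold = t, n_stratum = length(p1s),
      x = seq_along(p1s) / length(p1s),
      y = pmin(-log10(p1s), 300))
  }
  out <- data.table::rbindlist(pieces)
  data.table::setattr(out, "class",
                      c("qq_curves", class(out)))
  out
}

#' Maximum and mean vertical separation between two Q-Q strata
#'
#' Interpolates both curves onto a common grid of empirical-cdf positions
#' (restricted to x values both curves reach) and returns the largest and
#' the average absolute vertical gap in -log10 units. Under independence of
#' the two traits the curves estimate the same quantile function, so the
#' mean gap measures systematic enrichment while the max gap is dominated by
#' order-statistic noise in small strata.
#'
#' @param qq A `qq_curves` table.
#' @param t_ref,t_cmp Thresholds of the two curves to compare.
#' @param x_range Range of empirical-cdf positions examined.
#' @param grid_step Grid spacing.
#' @return Named numeric: `max_gap`, `mean_gap`.
#' @export
qq_separation <- function(qq, t_ref = 1, t_cmp, x_range = c(0.01, 0.5),
                          grid_step = 0.01) {
  a <- qq[qq$threshold == t_ref]
  b <- qq[qq$threshold == t_cmp]
  if (nrow(a) == 0 || nrow(b) == 0) stop("qq_separation: missing stratum")
  lo <- max(x_range[1], min(a$x), min(b$x))
  grid <- seq(lo, x_range[2], by = grid_step)
  ya <- stats::approx(a$x, a$y, xout = grid, rule = 2)$y
  yb <- stats::approx(b$x, b$y, xout = grid, rule = 2)$y
  gap <- abs(yb - ya)
  c(max_gap = max(gap), mean_gap = mean(gap))
}

#' Fold-enrichment curves
#'
#' fold(t, x) = prop(S_t, -log10 p1 >= x) / prop(all SNPs, -log10 p1 >= x),
#' evaluated over a grid of -log10 p thresholds. Entries with a zero
#' denominator proportion are omitted. The counts entering both proportions
#' are returned so callers can gate on estimability.
#'
#' @inheritParams conditional_qq
#' @param grid -log10 p1 thresholds (default 0 to 10 by 0.1; 7.3 is the
#'   conventional genome-wide significance point, -log10(5e-8)).
#' @return `data.table` of class `fold_curves`: `threshold`, `x`, `fold`,
#'   `n_stratum` (stratum size), `n_tail_stratum` (stratum SNPs above x),
#'   `n_tail_all` (all SNPs above x).
#' @export
fold_enrichment <- function(merged, levels = conditioning_levels(),
                            grid = seq(0, 10, by = 0.1)) {
  merged <- data.table::as.data.table(merged)
  if (nrow(merged) == 0) stop("fold_enrichment: empty input")
  nl1 <- -log10(merged$p1)
  n_all <- nrow(merged)
  tail_all <- vapply(grid, function(x) sum(nl1 >= x), integer(1))
  pieces <- list()
  for (t in levels) {
    s <- merged$p2 <= t
    ns <- sum(s)
    if (ns == 0) next
    tail_s <- vapply(grid, function(x) sum(nl1[s] >= x), integer(1))
    ok <- tail_all > 0
    pieces[[length(pieces) + 1]] <- data.table::data.table(
      threshold = t, x = grid[ok],
      fold = (tail_s[ok] / ns) / (tail_all[ok] / n_all),
      n_stratum = ns, n_tail_stratum = tail_s[ok],
      n_tail_all = tail_all[ok])
  }
  out <- data.table::rbindlist(pieces)
  data.table::setattr(out, "class", c("fold_curves", class(out)))
  out
}

#' Manhattan plot data for a cFDR or conjunction table
#'
#' @param table Table with `chrom`, `pos` and the chosen FDR field.
#' @param field `"cfdr"` or `"conj_fdr"`.
#' @param alpha Significance level; the plotted threshold line sits at
#'   -log10(alpha) (1.3 at the default 0.05).
#' @return List of class `manhattan_data`: `snps` (`data.table`: `chrom`,
#'   `pos`, `xpos` cumulative plotting coordinate, `y` = -log10(field)
#'   capped at 300, `significant`), `line` (-log10(alpha)), `field`,
#'   `alpha`.
#' @export
manhattan_data <- function(table, field = c("cfdr", "conj_fdr"),
                           alpha = 0.05) {
  field <- match.arg(field)
  table <- data.table::as.data.table(table)
  if (!field %in% names(table)) {
    stop("manhattan_data: column '", field, "' not present")
  }
  dt <- data.table::data.table(chrom = table$chrom, pos = table$pos,
                               val = table[[field]])
  sort_by_position(dt)
  offsets <- c(0, cumsum(as.numeric(tapply(dt$pos, factor(dt$chrom,
    levels = unique(dt$chrom)), max))))
  dt[, "xpos" := pos + offsets[match(chrom, unique(chrom))]]
  dt[, "y" := pmin(-log10(val), 300)]
  dt[, "significant" := val < alpha]
  dt[, "val" := NULL]
  structure(list(snps = dt[], line = -log10(alpha), field = field,
                 alpha = alpha),
            class = "manhattan_data")
}

#' Render diagnostic plot data to an image file
#'
#' Dispatches on the object class (`qq_curves`, `fold_curves`,
#' `manhattan_data`); rendering is presentation-only.
#'
#' @param obj A plot-data object.
#' @param path Output image path (extension selects the device, e.g.
#'   `.png`).
#' @param ... Passed to [ggplot2::ggsave()] (e.g. `width`, `height`).
#' @export
render_plots <- function(obj, path, ...) {
  UseMethod("render_plots")
}

#' @export
render_plots.qq_curves <- function(obj, path, ...) {
  if (nrow(obj) == 0) stop("render_plots: empty Q-Q curve set")
  p <- ggplot2::ggplot(obj, ggplot2::aes(x = x, y = y,
        colour = factor(threshold))) +
    ggplot2::geom_line() +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "empirical cdf of principal p-values",
                  y = expression(-log[10](p)),
                  colour = "p2 <=") +
    ggplot2::theme_minimal()
  ggplot2::ggsave(path, p, ...)
  invisible(path)
}

#' @export
render_plots.fold_curves <- function(obj, path, ...) {
  if (nrow(obj) == 0) stop("render_plots: empty fold-enrichment curve set")
  p <- ggplot2::ggplot(obj, ggplot2::aes(x = x, y = fold,
        colour = factor(threshold))) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 1, colour = "grey50") +
    ggplot2::labs(x = expression(-log[10](p)), y = "fold enrichment",
                  colour = "p2 <=") +
    ggplot2::theme_minimal()
  ggplot2::ggsave(path, p, ...)
  invisible(path)
}

#' @export
render_plots.manhattan_data <- function(obj, path, ...) {
  if (nrow(obj$snps) == 0) stop("render_plots: empty Manhattan data")
  chrom_levels <- unique(obj$snps$chrom)
  p <- ggplot2::ggplot(obj$snps, ggplot2::aes(x = xpos, y = y,
        colour = factor(match(chrom, chrom_levels) %% 2))) +
    ggplot2::geom_point(size = 0.4, show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = obj$line, colour = "red") +
    ggplot2::labs(x = "chromosome",
                  y = bquote(-log[10] ~ .(obj$field))) +
    ggplot2::theme_minimal()
  ggplot2::ggsave(path, p, ...)
  invisible(path)
}
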