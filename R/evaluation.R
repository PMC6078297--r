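check_labels <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) {
    stop("scores and labels must have equal length", call. = FALSE)
  }
  if (any(is.na(scores)) || any(is.na(labels))) {
    stop("missing scores or labels; handle them before evaluation", call. = FALSE)
  }
  if (!all(labels %in% c(0L, 1L))) stop("labels must be binary", call. = FALSE)
  if (sum(labels) == 0 || sum(labels) == length(labels)) {
    stop("both classes must be present", call. = FALSE)
  }
  labels
}

#' Area under the ROC curve
#'
#' Computed as the normalized Mann-Whitney U statistic with midrank tie
#' handling: the probability that a randomly chosen positive instance is
#' ranked above a randomly chosen negative one (ties count one half).
#'
#' @param scores Numeric scores (`Inf`/`-Inf` allowed, `NA` not).
#' @param labels Binary labels (1 = positive class).
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  labels <- check_labels(scores, labels)
  n_pos <- sum(labels); n_neg <- length(labels) - n_pos
  r <- rank(scores, ties.method = "average")
  u <- sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2
  u / (n_pos * n_neg)
}

#' Area under the precision-recall curve
#'
#' Step-wise area (no interpolation between PR points): predictions are
#' swept in decreasing score order, tied scores entering as one block, and
#' each recall increment contributes the precision attained at the end of
#' its block.
#'
#' @inheritParams auroc
#' @return AUPR in `[0, 1]`.
#' @export
aupr <- function(scores, labels) {
  labels <- check_labels(scores, labels)
  n_pos <- sum(labels)
  o <- order(-scores)
  s <- scores[o]; l <- labels[o]
  block <- cumsum(!duplicated(s))
  tp_b <- tapply(l, block, sum)
  n_b <- tapply(l, block, length)
  tp <- cumsum(tp_b)
  n_cum <- cumsum(n_b)
  precision <- tp / n_cum
  sum((tp_b / n_pos) * precision)
}

#' Histogram bins over \\[-1, 1\\]
#'
#' @keywords internal
cor_bins <- function(bin_width = 0.1) {
  edges <- seq(-1, 1, by = bin_width)
  if (abs(edges[length(edges)] - 1) > 1e-9) edges <- c(edges, 1)
  edges
}

unit_area_density <- function(values, edges) {
  # right-open bins except the last
  idx <- findInterval(values, edges, rightmost.closed = TRUE, left.open = FALSE)
  idx[idx == length(edges)] <- length(edges) - 1L
  counts <- tabulate(idx, length(edges) - 1L)
  widths <- diff(edges)
  counts / (sum(counts) * widths)
}

#' Difference histogram of dependency distributions
#'
#' Bins two samples of dependency values (e.g. Pearson correlations of
#' interacting and of random gene pairs) into unit-area histograms over
#' `[-1, 1]` and takes their bin-wise difference. Positive differences mark
#' enrichment of interacting pairs at that dependency level, negative ones
#' depletion.
#'
#' @param values_interacting,values_random Numeric values in `[-1, 1]`.
#' @param bin_width Bin width (default 0.1); bins are right-open except the
#'   last.
#' @return Tibble of class `difference_histogram` with columns `bin_low`,
#'   `bin_high`, `bin_mid`, `density_interacting`, `density_random`,
#'   `difference`.
#' @export
difference_histogram <- function(values_interacting, values_random,
                                 bin_width = 0.1) {
  if (length(values_interacting) == 0 || length(values_random) == 0) {
    stop("empty input", call. = FALSE)
  }
  vals <- c(values_interacting, values_random)
  if (any(!is.finite(vals)) || any(vals < -1 - 1e-9) || any(vals > 1 + 1e-9)) {
    stop("values must lie in [-1, 1]", call. = FALSE)
  }
  edges <- cor_bins(bin_width)
  d_i <- unit_area_density(values_interacting, edges)
  d_r <- unit_area_density(values_random, edges)
  out <- tibble::tibble(
    bin_low = edges[-length(edges)],
    bin_high = edges[-1],
    bin_mid = (edges[-length(edges)] + edges[-1]) / 2,
    density_interacting = d_i,
    density_random = d_r,
    difference = d_i - d_r
  )
  class(out) <- c("difference_histogram", class(out))
  out
}

#' Enrichment of high-|PC| correlations among true edges
#'
#' Convenience summary of the regime contrast: the fraction of true
#' (non-self-loop) edges whose flat-chip Pearson correlation exceeds
#' `threshold` in absolute value, the same fraction for random non-edge
#' pairs, and their gap.
#'
#' @param dataset An [expr_dataset()].
#' @param network Edge-list tibble.
#' @param n_random Number of random pairs (default 1000).
#' @param threshold Absolute-correlation threshold (default 0.2).
#' @param seed Seed for the random-pair sample.
#' @return List with `frac_true`, `frac_random`, `gap`, `pairs` (the scored
#'   pair tibble).
#' @export
edge_correlation_enrichment <- function(dataset, network, n_random = 1000,
                                        threshold = 0.2, seed = 0L) {
  pairs <- sample_pairs(network, dataset, n_random = n_random, seed = seed)
  pairs$pc <- vapply(seq_len(nrow(pairs)), function(i) {
    pearson(gene_profile(dataset, pairs$gene_a[i]),
            gene_profile(dataset, pairs$gene_b[i]))
  }, numeric(1))
  is_true <- pairs$label != "random"
  frac_true <- mean(abs(pairs$pc[is_true]) > threshold)
  frac_random <- mean(abs(pairs$pc[!is_true]) > threshold)
  list(frac_true = frac_true, frac_random = frac_random,
       gap = frac_true - frac_random, pairs = pairs)
}

#' Correlation distributions split by interaction sign
#'
#' Unit-area histograms of the Pearson correlation of true edges, split by
#' annotated sign (activating vs repressing).
#'
#' @param dataset An [expr_dataset()].
#' @param network Edge-list tibble with a `sign` column; at least one edge
#'   of each sign is required.
#' @param bin_width Histogram bin width (default 0.1).
#' @return Tibble of class `sign_split_distribution` with per-bin densities
#'   for each sign; attributes `mean_activating` and `mean_repressing` hold
#'   the per-sign mean correlations.
#' @export
sign_split_distribution <- function(dataset, network, bin_width = 0.1) {
  if (!"sign" %in% names(network)) stop("network lacks sign annotations", call. = FALSE)
  edges <- network[network$regulator != network$target &
                     network$sign %in% c("activating", "repressing"), ,
                   drop = FALSE]
  if (!all(c("activating", "repressing") %in% edges$sign)) {
    stop("need at least one edge of each sign", call. = FALSE)
  }
  pc <- vapply(seq_len(nrow(edges)), function(i) {
    pearson(gene_profile(dataset, edges$regulator[i]),
            gene_profile(dataset, edges$target[i]))
  }, numeric(1))
  edges$pc <- pc
  act <- pc[edges$sign == "activating"]
  rep_ <- pc[edges$sign == "repressing"]
  bins <- cor_bins(bin_width)
  out <- tibble::tibble(
    bin_low = bins[-length(bins)],
    bin_high = bins[-1],
    bin_mid = (bins[-length(bins)] + bins[-1]) / 2,
    density_activating = unit_area_density(act, bins),
    density_repressing = unit_area_density(rep_, bins)
  )
  class(out) <- c("sign_split_distribution", class(out))
  attr(out, "mean_activating") <- mean(act)
  attr(out, "mean_repressing") <- mean(rep_)
  out
}

#' Levene homogeneity-of-variance diagnostic for a factorial design
#'
#' Classic (mean-centered) Levene test over the design's cells: absolute
#' deviations from each cell's mean are fed to a one-way F test with the
#' same partition into groups that the ANOVA itself uses. Set
#' `center = "median"` for the Brown-Forsythe variant.
#'
#' @param design A [factorial_design()] with at least 2 replicates.
#' @param center `"mean"` (classic, default) or `"median"`.
#' @return List with `statistic`, `p.value`, `df`.
#' @export
variance_homogeneity_diagnostic <- function(design, center = c("mean", "median")) {
  stopifnot(inherits(design, "factorial_design"))
  center <- match.arg(center)
  d <- dim(design$response)
  if (d[1] < 2) stop("need at least 2 replicates per cell", call. = FALSE)
  y <- as.vector(design$response)
  group <- interaction(as.vector(slice.index(design$response, 2)),
                       as.vector(slice.index(design$response, 3)),
                       as.vector(slice.index(design$response, 4)),
                       drop = TRUE)
  centers <- tapply(y, group, if (center == "mean") mean else stats::median)
  dev <- abs(y - centers[group])
  ft <- stats::oneway.test(dev ~ group, var.equal = TRUE)
  list(statistic = unname(ft$statistic), p.value = unname(ft$p.value),
       df = unname(ft$parameter))
}

#' Normality summary of a sample
#'
#' Moment summary (skewness and excess kurtosis) plus an Anderson-Darling
#' omnibus normality p-value. Advisory only: the motif scores are rank
#' based, so deviations from normality never block scoring.
#'
#' @param values Numeric vector, `n >= 20`, non-constant.
#' @return One-row tibble with `n`, `skewness`, `excess_kurtosis`,
#'   `statistic`, `p.value`.
#' @export
normality_diagnostic <- function(values) {
  if (length(values) < 20) stop("need at least 20 values", call. = FALSE)
  if (!all(is.finite(values))) stop("values must be finite", call. = FALSE)
  if (stats::sd(values) == 0) stop("constant input", call. = FALSE)
  ad <- nortest::ad.test(values)
  tibble::tibble(
    n = length(values),
    skewness = e1071::skewness(values, type = 1),
    excess_kurtosis = e1071::kurtosis(values, type = 1),
    statistic = unname(ad$statistic),
    p.value = unname(ad$p.value)
  )
}

#' @importFrom ggplot2 autoplot
#' @export
autoplot.difference_histogram <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$bin_mid, y = .data$difference)) +
    ggplot2::geom_col(width = object$bin_high[1] - object$bin_low[1],
                      fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = "Pearson correlation",
                  y = "density difference (interacting - random)",
                  title = "Enrichment/depletion of interacting-pair correlations")
}

#' @export
autoplot.sign_split_distribution <- function(object, ...) {
  long <- tidyr::pivot_longer(object,
                              c("density_activating", "density_repressing"),
                              names_to = "sign", names_prefix = "density_",
                              values_to = "density")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$bin_mid, y = .data$density,
                                     colour = .data$sign)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "Pearson correlation", y = "density",
                  title = "Correlation of true edges by interaction sign")
}

#' Plot a benchmark report
#'
#' Bar chart of AUROC by task and method (the machine-readable analog of a
#' methods-comparison figure).
#'
#' @param report Tibble with columns `task`, `method`, `auroc`.
#' @return A ggplot object.
#' @export
plot_benchmark <- function(report) {
  ggplot2::ggplot(report, ggplot2::aes(x = .data$task, y = .data$auroc,
                                       fill = .data$method)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2) +
    ggplot2::coord_cartesian(ylim = c(0.4, 1)) +
    ggplot2::labs(y = "AUROC", x = NULL)
}
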