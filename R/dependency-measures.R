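#' Pairwise correlation coefficients
#'
#' Thin validated wrappers around the product-moment and rank correlation.
#' Constant input makes the coefficient undefined and raises an error
#' instead of returning `NA`.
#'
#' @param x,y Numeric vectors of equal length (>= 3).
#' @return Correlation in `[-1, 1]`.
#' @export
pearson <- function(x, y) {
  check_pair(x, y)
  stats::cor(x, y, method = "pearson")
}

#' @rdname pearson
#' @export
spearman <- function(x, y) {
  check_pair(x, y)
  stats::cor(x, y, method = "spearman")
}

check_pair <- function(x, y) {
  if (length(x) != length(y)) stop("vectors must have equal length", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 observations", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("inputs must be finite", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for constant input", call. = FALSE)
  }
  invisible(TRUE)
}

#' Equal-frequency binning scheme
#'
#' @param n_bins Number of bins (>= 2), or `NULL` to use the default rule
#'   `min(10, max(2, floor(sqrt(n) / 2)))` at estimation time.
#' @return Object of class `binning_scheme`.
#' @export
binning_scheme <- function(n_bins = NULL) {
  if (!is.null(n_bins)) {
    n_bins <- as.integer(n_bins)
    if (n_bins < 2) stop("n_bins must be >= 2", call. = FALSE)
  }
  structure(list(strategy = "equal_frequency", n_bins = n_bins),
            class = "binning_scheme")
}

default_n_bins <- function(n) min(10L, max(2L, as.integer(floor(sqrt(n) / 2))))

#' Assign samples to equal-frequency bins
#'
#' Bin occupancies differ by at most one; ties are broken deterministically
#' by sample index.
#'
#' @param x Numeric vector.
#' @param n_bins Number of bins.
#' @return Integer vector of bin indices in `1..n_bins`.
#' @export
equal_frequency_bins <- function(x, n_bins) {
  n <- length(x)
  if (n < n_bins) stop("fewer samples than bins", call. = FALSE)
  r <- rank(x, ties.method = "first")
  as.integer(floor((r - 1) * n_bins / n)) + 1L
}

# Plug-in entropy (nats) of a contingency table given as a count vector.
plugin_entropy <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p))
}

resolve_bins <- function(binning, n) {
  if (is.null(binning)) binning <- binning_scheme()
  nb <- binning$n_bins
  if (is.null(nb)) nb <- default_n_bins(n)
  if (n < nb) stop("fewer samples than bins", call. = FALSE)
  nb
}

#' Mutual information of two samples (plug-in, equal-frequency bins)
#'
#' Estimates `I(X; Y) = H(X) + H(Y) - H(X, Y)` in nats from the empirical
#' joint distribution of the binned samples. Each variable is binned
#' marginally into equal-frequency bins.
#'
#' @param x,y Numeric vectors of equal length.
#' @param binning A [binning_scheme()] (default rule if `NULL`).
#' @return Non-negative mutual information in nats.
#' @export
mutual_information <- function(x, y, binning = NULL) {
  if (length(x) != length(y)) stop("vectors must have equal length", call. = FALSE)
  n <- length(x)
  nb <- resolve_bins(binning, n)
  if (nb^2 > n) {
    warning("n_bins^2 exceeds sample size; MI estimate may be strongly biased",
            call. = FALSE)
  }
  bx <- equal_frequency_bins(x, nb)
  by <- equal_frequency_bins(y, nb)
  h_x <- plugin_entropy(tabulate(bx, nb))
  h_y <- plugin_entropy(tabulate(by, nb))
  h_xy <- plugin_entropy(tabulate(bx + nb * (by - 1L), nb * nb))
  mi <- h_x + h_y - h_xy
  clamp_nonneg(mi)
}

clamp_nonneg <- function(v, tol = 1e-12) {
  if (v < -tol) stop("internal error: negative information estimate", call. = FALSE)
  max(v, 0)
}

#' First-order conditional (partial) correlation
#'
#' The residual correlation of `x` and `y` after removing the linear (or
#' rank-linear) contribution of `z`:
#' `(r_xy - r_zy * r_zx) / sqrt((1 - r_zy^2) (1 - r_zx^2))`.
#'
#' @param x,y,z Numeric vectors of equal length.
#' @param rank_based If `TRUE`, all three pairwise correlations are Spearman
#'   (first-order conditional Spearman correlation).
#' @return Partial correlation in `[-1, 1]`.
#' @export
conditional_correlation <- function(x, y, z, rank_based = FALSE) {
  check_pair(x, y); check_pair(x, z); check_pair(y, z)
  cc <- if (rank_based) spearman else pearson
  r_xy <- cc(x, y); r_zx <- cc(z, x); r_zy <- cc(z, y)
  if (abs(r_zx) >= 1 - 1e-12 || abs(r_zy) >= 1 - 1e-12) {
    stop("collinearity: conditioning variable is perfectly correlated with x or y",
         call. = FALSE)
  }
  (r_xy - r_zy * r_zx) / sqrt((1 - r_zy^2) * (1 - r_zx^2))
}

#' Conditional mutual information (plug-in, equal-frequency bins)
#'
#' Estimates `I(X; Y | Z) = H(X,Z) + H(Y,Z) - H(Z) - H(X,Y,Z)` in nats on
#' the binned empirical distribution, with the same marginal
#' equal-frequency binning per variable as [mutual_information()].
#'
#' @inheritParams mutual_information
#' @param z Conditioning sample.
#' @return Non-negative conditional mutual information in nats.
#' @export
conditional_mutual_information <- function(x, y, z, binning = NULL) {
  if (length(x) != length(y) || length(x) != length(z)) {
    stop("vectors must have equal length", call. = FALSE)
  }
  n <- length(x)
  nb <- resolve_bins(binning, n)
  bx <- equal_frequency_bins(x, nb)
  by <- equal_frequency_bins(y, nb)
  bz <- equal_frequency_bins(z, nb)
  h_z <- plugin_entropy(tabulate(bz, nb))
  h_xz <- plugin_entropy(tabulate(bx + nb * (bz - 1L), nb^2))
  h_yz <- plugin_entropy(tabulate(by + nb * (bz - 1L), nb^2))
  h_xyz <- plugin_entropy(tabulate(bx + nb * (by - 1L) + nb^2 * (bz - 1L), nb^3))
  clamp_nonneg(h_xz + h_yz - h_z - h_xyz)
}

#' Two-way ANOVA dependency score for a gene pair
#'
#' Builds the balanced gene x condition two-way design for a putative
#' TF:target pair and returns the condition eta-squared (`SS_C / SS_T`),
#' a non-parametric, non-linear dependency score in `[0, 1]`.
#'
#' @param dataset An [expr_dataset()].
#' @param tf,tg Distinct gene ids.
#' @param weights Optional per-condition weights (see [build_design()]).
#' @return Eta-squared in `[0, 1]`.
#' @export
two_way_score <- function(dataset, tf, tg, weights = NULL) {
  design <- build_design_2way(dataset, tf, tg, weights = weights)
  eta_squared(ss_decompose(design))
}

#' Apply a pairwise or conditional dependency measure by name
#'
#' Dispatch used by the motif-scoring layer. Correlation-type measures are
#' returned as absolute values (dependency strength): repressing
#' interactions carry negative coefficients, and motif ranking uses the
#' magnitude of the dependency.
#'
#' @param dataset An [expr_dataset()].
#' @param gene_a,gene_b The scored pair.
#' @param measure One of `"PC"`, `"SP"`, `"MI"`, `"2WA"`, `"cPC"`, `"cSP"`,
#'   `"cMI"`.
#' @param conditioning_gene Third gene, required for conditional measures.
#' @param binning Optional [binning_scheme()] for MI-type measures.
#' @param replicate_mean If `TRUE`, chip vectors are replaced by
#'   per-condition replicate means before applying flat-vector measures
#'   (sensitivity-analysis variant; by default replicates are treated as
#'   individual measurements).
#' @return A single dependency score (non-negative except for `2WA`, which
#'   is a ratio in `[0, 1]`).
#' @export
dependency_score <- function(dataset, gene_a, gene_b, measure,
                             conditioning_gene = NULL, binning = NULL,
                             replicate_mean = FALSE) {
  measure <- match.arg(measure, c("PC", "SP", "MI", "2WA", "cPC", "cSP", "cMI"))
  if (measure == "2WA") {
    return(two_way_score(dataset, gene_a, gene_b))
  }
  get_vec <- function(g) {
    v <- gene_profile(dataset, g)
    if (replicate_mean) {
      as.numeric(tapply(v, dataset$chips$condition_id, mean)[conditions(dataset)])
    } else v
  }
  x <- get_vec(gene_a); y <- get_vec(gene_b)
  if (measure %in% c("cPC", "cSP", "cMI")) {
    if (is.null(conditioning_gene)) {
      stop("conditional measures need a conditioning gene", call. = FALSE)
    }
    z <- get_vec(conditioning_gene)
  }
  switch(measure,
         PC = abs(pearson(x, y)),
         SP = abs(spearman(x, y)),
         MI = mutual_information(x, y, binning),
         cPC = abs(conditional_correlation(x, y, z, rank_based = FALSE)),
         cSP = abs(conditional_correlation(x, y, z, rank_based = TRUE)),
         cMI = conditional_mutual_information(x, y, z, binning))
}
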