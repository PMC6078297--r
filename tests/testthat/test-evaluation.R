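test_that("auroc equals the Mann-Whitney statistic including ties", {
  expect_equal(auroc(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0)), 0.75)
  expect_equal(auroc(c(3, 2, 1), c(1, 1, 0)), 1)
  expect_equal(auroc(rep(1, 10), rep(c(0, 1), 5)), 0.5)
  for (seed in 1:25) {
    set.seed(seed)
    n <- 30
    scores <- sample(seq(0, 1, 0.1), n, TRUE)       # plenty of ties
    labels <- rbinom(n, 1, 0.4)
    if (sum(labels) %in% c(0, n)) next
    expect_equal(auroc(scores, labels), bf_auroc(scores, labels),
                 tolerance = 1e-12)
    # complement identity holds exactly under midranks
    expect_equal(auroc(-scores, labels), 1 - auroc(scores, labels),
                 tolerance = 1e-12)
  }
  expect_error(auroc(1:3, c(1, 1, 1)), "both classes")
  expect_error(auroc(c(1, NA, 3), c(1, 0, 1)), "missing")
})

test_that("auroc equals the trapezoidal area under the empirical ROC curve", {
  for (seed in 1:5) {
    set.seed(seed)
    scores <- round(rnorm(40), 1)
    labels <- rbinom(40, 1, 0.5)
    if (sum(labels) %in% c(0, 40)) next
    thr <- sort(unique(scores), decreasing = TRUE)
    tpr <- c(0, sapply(thr, function(t) mean(scores[labels == 1] >= t)), 1)
    fpr <- c(0, sapply(thr, function(t) mean(scores[labels == 0] >= t)), 1)
    trap <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
    expect_equal(auroc(scores, labels), trap, tolerance = 1e-12)
  }
})

test_that("aupr computes the step-wise area and its null approximates prevalence", {
  # hand-computed 4-point example
  expect_equal(aupr(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0)),
               0.5 * 1 + 0.5 * (2 / 3))
  expect_equal(aupr(c(3, 2, 1), c(1, 1, 0)), 1)
  # random scores: AUPR close to prevalence
  set.seed(11)
  n <- 4000; p <- 0.2
  labels <- rbinom(n, 1, p)
  est <- aupr(rnorm(n), labels)
  expect_lt(abs(est - mean(labels)), 0.05)
  expect_error(aupr(1:3, c(0, 0, 0)), "both classes")
})

test_that("difference histograms are unit-area and localize enrichment", {
  # identical samples: difference identically zero
  set.seed(3)
  v <- runif(200, -1, 1)
  h <- difference_histogram(v, v)
  expect_equal(h$difference, rep(0, 20))
  expect_equal(sum(h$density_interacting * (h$bin_high - h$bin_low)), 1,
               tolerance = 1e-12)
  # disjoint masses: positive only in the top bin, negative only at zero
  h2 <- difference_histogram(rep(0.95, 50), rep(0.01, 50))
  expect_equal(which(h2$difference > 0), 20L)
  expect_equal(which(h2$difference < 0), 11L)
  # boundary values fall into the outer bins
  h3 <- difference_histogram(c(-1, 1), c(0, 0))
  expect_equal(h3$density_interacting[c(1, 20)], c(5, 5))
  expect_error(difference_histogram(numeric(0), v), "empty")
  expect_error(difference_histogram(c(0.5, 2), v), "\\[-1, 1\\]")
})

test_that("artificial-like regime concentrates enrichment beyond |PC| = 0.2", {
  sim <- simulate_grn(sim_config("artificial_like",
                                 n_motifs = c(CSC = 30, FFL = 30, DOR = 30),
                                 n_background_genes = 20, seed = 23))
  pairs <- sample_pairs(sim$network, sim$dataset, n_random = 300, seed = 2)
  pc <- vapply(seq_len(nrow(pairs)), function(i)
    pearson(gene_profile(sim$dataset, pairs$gene_a[i]),
            gene_profile(sim$dataset, pairs$gene_b[i])), numeric(1))
  h <- difference_histogram(pc[pairs$label != "random"],
                            pc[pairs$label == "random"])
  outer_mass <- sum(h$difference[abs(h$bin_mid) > 0.2][
    h$difference[abs(h$bin_mid) > 0.2] > 0])
  inner <- h$difference[abs(h$bin_mid) < 0.2]
  expect_gt(outer_mass, 0)
  expect_lt(min(inner), 0)
  expect_gt(sum(h$difference[abs(h$bin_mid) > 0.2]),
            sum(h$difference[abs(h$bin_mid) < 0.2]))
})

test_that("sign-split distributions separate activation from repression", {
  sim <- simulate_grn(sim_config("artificial_like",
                                 n_motifs = c(CSC = 40, FFL = 40, DOR = 40),
                                 repression_fraction = 0.5, seed = 31))
  ssd <- sign_split_distribution(sim$dataset, sim$network)
  rep_mass_neg <- sum((ssd$density_repressing * 0.1)[ssd$bin_mid < 0])
  act_mass_pos <- sum((ssd$density_activating * 0.1)[ssd$bin_mid > 0])
  expect_gt(rep_mass_neg, 0.8)
  expect_gt(act_mass_pos, 0.8)
  expect_lt(attr(ssd, "mean_repressing"), 0)
  # all-activating network cannot be split
  net_act <- sim$network
  net_act$sign <- "activating"
  expect_error(sign_split_distribution(sim$dataset, net_act), "each sign")
  expect_error(sign_split_distribution(sim$dataset,
                                       net_act[, c("regulator", "target")]),
               "sign annotations")
})

test_that("Levene diagnostic matches the reference and detects heteroscedasticity", {
  # shifted copies of one group: statistic exactly 0
  base <- c(-1, 0, 1, 2)
  arr <- array(NA_real_, dim = c(4, 2, 1, 3))
  for (a in 1:2) for (cc in 1:3) arr[, a, 1, cc] <- base + a + cc
  d <- factorial_design(arr, 2)
  lev <- variance_homogeneity_diagnostic(d)
  expect_equal(lev$statistic, 0)
  # oracle: car::leveneTest with mean centering on seeded input
  set.seed(13)
  arr2 <- array(rnorm(4 * 2 * 2 * 5), dim = c(4, 2, 2, 5))
  d2 <- factorial_design(arr2, 3)
  lev2 <- variance_homogeneity_diagnostic(d2)
  grp <- interaction(as.vector(slice.index(arr2, 2)),
                     as.vector(slice.index(arr2, 3)),
                     as.vector(slice.index(arr2, 4)), drop = TRUE)
  ref <- car::leveneTest(as.vector(arr2), grp, center = mean)
  expect_equal(lev2$statistic, ref$`F value`[1], tolerance = 1e-8)
  expect_equal(lev2$p.value, ref$`Pr(>F)`[1], tolerance = 1e-8)
  # power: one group with 10x spread gives a small p
  set.seed(14)
  arr3 <- array(rnorm(20 * 2 * 1 * 4), dim = c(20, 2, 1, 4))
  arr3[, 1, 1, 1] <- rnorm(20, 0, 10)
  lev3 <- variance_homogeneity_diagnostic(factorial_design(arr3, 2))
  expect_lt(lev3$p.value, 1e-4)
  expect_error(variance_homogeneity_diagnostic(
    factorial_design(matrix(1:4, nrow = 1), 1)), "2 replicates")
})

test_that("normality summary recovers known moments", {
  set.seed(21)
  g <- rnorm(10000)
  s <- normality_diagnostic(g)
  expect_lt(abs(s$skewness), 0.1)
  expect_lt(abs(s$excess_kurtosis), 0.2)
  e <- rexp(10000)
  se <- normality_diagnostic(e)
  expect_lt(abs(se$skewness - 2), 0.3)
  expect_lt(se$p.value, 1e-6)
  expect_error(normality_diagnostic(rep(1, 30)), "constant")
  expect_error(normality_diagnostic(rnorm(10)), "at least 20")
})

test_that("autoplot methods return ggplot objects", {
  set.seed(2)
  h <- difference_histogram(runif(50, -1, 1), runif(50, -1, 1))
  expect_s3_class(ggplot2::autoplot(h), "ggplot")
  rep_tbl <- tibble::tibble(task = "DOR_vs_FFL", method = c("PC", "3WA"),
                            auroc = c(0.6, 0.7))
  expect_s3_class(plot_benchmark(rep_tbl), "ggplot")
})
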