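random_design <- function(n_ways, n_conditions = 4, n_replicates = 3, seed = 1) {
  set.seed(seed)
  ab <- switch(n_ways, `1` = c(1, 1), `2` = c(2, 1), `3` = c(2, 2))
  arr <- array(rnorm(n_replicates * prod(ab) * n_conditions),
               dim = c(n_replicates, ab, n_conditions))
  factorial_design(arr, n_ways)
}

test_that("design builder assembles the documented cell layout", {
  ds <- make_dataset(n_genes = 4, n_conditions = 5, n_replicates = 2, seed = 3)
  d <- build_design(ds, "g1", "g2", "g3")
  r <- 2; conds <- conditions(ds)
  for (ci in seq_along(conds)) {
    ch <- ds$chips$chip_id[ds$chips$condition_id == conds[ci]]
    expect_equal(d$response[, 1, 1, ci], unname(ds$values[ch, "g3"]))
    expect_equal(d$response[, 2, 1, ci], unname(ds$values[ch, "g1"]))
    expect_equal(d$response[, 1, 2, ci], unname(ds$values[ch, "g2"]))
    expect_equal(d$response[, 2, 2, ci],
                 unname((ds$values[ch, "g1"] + ds$values[ch, "g2"]) / 2))
  }
  expect_true(all(d$imputed_mask[, 2, 2, ]))
  expect_false(any(d$imputed_mask[, 1, , ]))
  # identical profiles: all four cells equal the common profile
  v <- ds$values
  v[, "g2"] <- v[, "g1"]; v[, "g3"] <- v[, "g1"]
  ds2 <- expr_dataset(v, ds$chips)
  d2 <- build_design(ds2, "g1", "g2", "g3")
  expect_equal(d2$response[, 2, 2, ], d2$response[, 1, 1, ])
  # one condition/replicate: imputed cell is the plain mean
  expect_error(build_design(ds, "g1", "g1", "g3"), "distinct")
  expect_error(build_design(ds, "g1", "g2", "zzz"), "unknown")
})

test_that("linear-scale imputation takes the geometric mean of linearized values", {
  ds <- make_dataset(n_genes = 3, n_conditions = 4, n_replicates = 2, seed = 8)
  d <- build_design(ds, "g1", "g2", "g3", impute = "linear")
  expect_equal(d$response[, 2, 2, 1],
               unname(log2(sqrt(2^ds$values[1:2, "g1"] * 2^ds$values[1:2, "g2"]))))
})

test_that("unbalanced replicate structure is truncated deterministically", {
  ds <- make_dataset(n_genes = 3, n_conditions = 3, n_replicates = 3, seed = 5)
  keep <- ds$chips$chip_id[!(ds$chips$condition_id == "cond2" &
                               ds$chips$replicate == 3)]
  ds2 <- expr_dataset(ds$values[keep, ], ds$chips[ds$chips$chip_id %in% keep, ],
                      tf_genes = ds$tf_genes)
  expect_warning(d <- build_design(ds2, "g1", "g2", "g3"), "truncating")
  expect_equal(dim(d$response)[1], 2L)  # lowest replicate indices kept
  ch <- ds2$chips$chip_id[ds2$chips$condition_id == "cond1"][1:2]
  expect_equal(d$response[, 1, 1, 1], unname(ds2$values[ch, "g3"]))
})

test_that("decomposition matches hand computations on tiny designs", {
  # 1-way, 2 conditions x 2 replicates, values (0,0) and (1,1)
  d <- factorial_design(matrix(c(0, 0, 1, 1), nrow = 2), n_ways = 1)
  dec <- ss_decompose(d)
  expect_equal(dec$terms[["c"]], 1)
  expect_equal(dec$terms[["error"]], 0)
  expect_equal(dec$ss_total, 1)
  expect_equal(eta_squared(dec), 1)
  f <- f_statistic(dec, "c")
  expect_true(is.infinite(f$statistic) && f$p.value == 0 && f$zero_error)
  # groups (0,1) and (1,2): SS_C = 1, SS_error = 1, F = 2
  d2 <- factorial_design(matrix(c(0, 1, 1, 2), nrow = 2), n_ways = 1)
  dec2 <- ss_decompose(d2)
  expect_equal(dec2$terms[["c"]], 1)
  expect_equal(dec2$terms[["error"]], 1)
  f2 <- f_statistic(dec2, "c")
  expect_equal(f2$statistic, 2)
  expect_equal(f2$p.value, pf(2, 1, 2, lower.tail = FALSE))
  # constant input: all terms zero, eta-squared degenerate
  d3 <- factorial_design(array(1, dim = c(2, 2, 2, 3)), n_ways = 3)
  dec3 <- ss_decompose(d3)
  expect_true(all(dec3$terms == 0))
  expect_error(eta_squared(dec3), "degenerate")
  expect_error(normalize_terms(dec3), "degenerate")
})

test_that("decompose matches the explicit-loop oracle and reference ANOVA", {
  for (seed in 1:6) {
    for (nw in 1:3) {
      d <- random_design(nw, n_conditions = 3 + seed %% 4,
                         n_replicates = 2 + seed %% 2, seed = 100 * nw + seed)
      dec <- ss_decompose(d)
      bf <- bf_decompose(d$response)
      for (t in names(dec$terms)) {
        expect_equal(dec$terms[[t]], bf[[t]], tolerance = 1e-10)
      }
      expect_equal(dec$ss_total, bf[["total"]], tolerance = 1e-10)
      expect_equal(sum(dec$terms), dec$ss_total, tolerance = 1e-8)
      # independent reference ANOVA (stats::lm Type-I on balanced data)
      ref <- ref_anova(d$response)
      expect_equal(unname(sum(dec$terms) - dec$terms[["error"]]),
                   sum(ref$`Sum Sq`) - ref$`Sum Sq`[nrow(ref)],
                   tolerance = 1e-8)
      expect_equal(dec$terms[["error"]], ref$`Sum Sq`[nrow(ref)],
                   tolerance = 1e-10)
      expect_equal(dec$terms[["c"]], ref$`Sum Sq`[rownames(ref) == "C"],
                   tolerance = 1e-10)
      if (nw == 3) {
        expect_equal(dec$terms[["ab"]], ref$`Sum Sq`[rownames(ref) == "A:B"],
                     tolerance = 1e-10)
        expect_equal(dec$terms[["abc"]], ref$`Sum Sq`[rownames(ref) == "A:B:C"],
                     tolerance = 1e-10)
      }
      # F and p match the reference
      fc <- f_statistic(dec, "c")
      expect_equal(fc$statistic, ref$`F value`[rownames(ref) == "C"],
                   tolerance = 1e-8)
      expect_equal(fc$p.value, ref$`Pr(>F)`[rownames(ref) == "C"],
                   tolerance = 1e-8)
    }
  }
})

test_that("weighted decomposition matches the weighted loop oracle and conserves SS", {
  for (seed in 1:5) {
    set.seed(seed)
    n_c <- 4 + seed
    arr <- array(rnorm(3 * 2 * 2 * n_c), dim = c(3, 2, 2, n_c))
    w <- runif(n_c, 0.5, 3)
    d <- factorial_design(arr, 3, weights = w)
    dec <- ss_decompose(d)
    bf <- bf_decompose(arr, weights = w)
    for (t in names(dec$terms)) {
      expect_equal(dec$terms[[t]], bf[[t]], tolerance = 1e-10)
    }
    expect_equal(sum(dec$terms), dec$ss_total, tolerance = 1e-8)
  }
})

test_that("SS terms obey scale equivariance, label permutation and nesting", {
  d <- random_design(3, n_conditions = 5, seed = 77)
  dec <- ss_decompose(d)
  # scale equivariance: k^2 on terms, invariance of normalized ratios
  dk <- factorial_design(d$response * 3, 3)
  deck <- ss_decompose(dk)
  expect_equal(deck$terms, dec$terms * 9, tolerance = 1e-10)
  expect_equal(normalize_terms(deck), normalize_terms(dec), tolerance = 1e-10)
  # permuting condition labels leaves terms unchanged
  perm <- c(3, 1, 5, 2, 4)
  dp <- factorial_design(d$response[, , , perm], 3)
  expect_equal(ss_decompose(dp)$terms, dec$terms, tolerance = 1e-10)
  # nesting: dropping the b = 1 level reproduces the direct 2-way terms
  d2 <- factorial_design(d$response[, , 1, , drop = FALSE], 2)
  dec2 <- ss_decompose(d2)
  bf2 <- bf_decompose(d$response[, , 1, , drop = FALSE])
  for (t in names(dec2$terms)) {
    expect_equal(dec2$terms[[t]], bf2[[t]], tolerance = 1e-10)
  }
})

test_that("normalized terms sum to one and lie in [0, 1]", {
  for (seed in 1:20) {
    d <- random_design(3, n_conditions = 4 + seed %% 5, seed = seed)
    nt <- normalize_terms(ss_decompose(d))
    expect_equal(sum(nt), 1, tolerance = 1e-8)
    expect_true(all(nt >= 0 & nt <= 1))
  }
  # 1-way with zero error: normalized SS_C = 1
  d <- factorial_design(matrix(c(0, 0, 1, 1), nrow = 2), n_ways = 1)
  nt <- normalize_terms(ss_decompose(d))
  expect_equal(unname(nt), c(1, 0))
})

test_that("eta squared is consistent with the decomposition under pure noise", {
  ds <- make_dataset(n_genes = 2, n_conditions = 50, n_replicates = 3, seed = 10)
  d <- build_design_1way(ds, "g1")
  dec <- ss_decompose(d)
  expect_equal(eta_squared(dec), dec$terms[["c"]] / dec$ss_total)
  # with identical condition means the condition share stays moderate
  expect_lt(eta_squared(dec), 0.6)
})

test_that("perturbation weights preset upweights perturbed conditions", {
  ds <- make_dataset(n_genes = 3, n_conditions = 4, n_replicates = 2, seed = 2)
  ds$chips$perturbed_gene <- ifelse(ds$chips$condition_id == "cond3", "g1", NA)
  w <- perturbation_weights(ds)
  expect_equal(unname(w[conditions(ds)]), c(1, 1, 2, 1))
  d <- build_design(ds, "g1", "g2", "g3", weights = "perturbation")
  expect_equal(d$weights, c(1, 1, 2, 1))
})
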