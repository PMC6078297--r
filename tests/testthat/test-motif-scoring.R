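test_that("formula serialization round trips and validates", {
  f <- term_formula(c("c", "bc"), "ac", role_order = c("tf_x", "tg_z", "tf_y"))
  expect_equal(format_formula(f), "SSc*SSbc/SSac@(X,Z,Y)")
  expect_equal(parse_formula(format_formula(f)), f)
  fw <- term_formula("ac", role_order = c("tf_y", "tg_z", "tf_x"),
                     use_weights = TRUE)
  expect_equal(format_formula(fw), "SSac@(Y,Z,X)+w")
  recip <- term_formula(character(0), "ac",
                        role_order = c("tf_y", "tg_z", "tf_x"))
  expect_equal(format_formula(recip), "1/SSac@(Y,Z,X)")
  expect_equal(parse_formula("1/SSac@(Y,Z,X)"), recip)
  # SS prefixes are normalized, term budget enforced
  expect_equal(term_formula("SS_AC")$numerator, "ac")
  expect_error(term_formula(c("a", "b", "c"), c("ab", "ac")), "at most 4")
  expect_error(term_formula("zz"), "unknown SS term")
  expect_error(parse_formula("SSa@(X,X,Z)"), "permutation|parse")
})

test_that("every published term combination is expressible and enumerated", {
  table2 <- c(
    "SSac@(X,Y,Z)",                 # in silico, DOR vs CSC
    "SSbc@(X,Y,Z)+w",               # in silico, CSC vs FFL (weights)
    "SSc/SSac*SSbc@(X,Y,Z)",        # in silico, FFL vs DOR
    "1/SSac@(Y,Z,X)",               # E. coli, DOR vs CSC
    "SSc*SSbc/SSac@(X,Z,Y)",        # E. coli, CSC vs FFL
    "SSac/SSbc@(Y,Z,X)",            # E. coli, FFL vs DOR
    "SSa*SSac/SSab@(X,Y,Z)+w",      # S. cerevisiae, DOR vs CSC
    "SSb/SSab@(X,Z,Y)+w",           # S. cerevisiae, CSC vs FFL
    "SSab*SSbc/SSb*SSac@(X,Z,Y)"    # S. cerevisiae, FFL vs DOR (4 terms)
  )
  cands <- candidate_formulas(max_terms = 3)
  canon <- function(s) {
    f <- parse_formula(s)
    format_formula(term_formula(sort(f$numerator), sort(f$denominator),
                                f$role_order, f$use_weights))
  }
  canon_set <- vapply(vapply(cands, format_formula, character(1)), canon,
                      character(1))
  # entries with up to 3 terms lie in the default search space
  for (s in table2[-9]) {
    expect_true(canon(s) %in% canon_set,
                label = paste("enumeration contains", s))
  }
  # the four-term entry is expressible in the grammar
  f4 <- parse_formula(table2[9])
  expect_s3_class(f4, "term_formula")
  expect_length(c(f4$numerator, f4$denominator), 4)
})

test_that("candidate enumeration is deterministic with the documented count", {
  c1 <- candidate_formulas(max_terms = 1)
  expect_length(c1, 72)  # 6 terms x 2 signs x 3 role orders x 2 weight flags
  expect_identical(vapply(c1, format_formula, character(1)),
                   vapply(candidate_formulas(max_terms = 1), format_formula,
                          character(1)))
  # error terms excluded by default, available on request
  all_terms <- unique(unlist(lapply(candidate_formulas(1), function(f)
    c(f$numerator, f$denominator))))
  expect_false(any(c("abc", "error") %in% all_terms))
  with_err <- unique(unlist(lapply(
    candidate_formulas(1, include_error_terms = TRUE),
    function(f) c(f$numerator, f$denominator))))
  expect_true(all(c("abc", "error") %in% with_err))
})

test_that("formula evaluation reduces to eta-squared and flags zero denominators", {
  ds <- make_dataset(n_genes = 3, n_conditions = 10, n_replicates = 2, seed = 12)
  motif <- tibble::tibble(motif_type = "CSC", tf_x = "g1", tf_y = "g2",
                          tg_z = "g3")
  f_eta <- term_formula("c")
  got <- evaluate_formula(ds, motif, f_eta)
  dec <- ss_decompose(build_design(ds, "g1", "g2", "g3"))
  expect_equal(got, eta_squared(dec), tolerance = 1e-12)
  # product/ratio semantics against normalize_terms
  f <- term_formula(c("c", "bc"), "ac")
  nt <- normalize_terms(dec)
  expect_equal(evaluate_formula(ds, motif, f),
               nt[["c"]] * nt[["bc"]] / nt[["ac"]], tolerance = 1e-12)
  # noiseless design with zero denominator term yields +Inf
  meta <- data.frame(chip_id = paste0("c", 1:4),
                     condition_id = rep(c("k1", "k2"), each = 2),
                     replicate = rep(1:2, 2))
  vals <- cbind(g1 = c(0, 0, 1, 1), g2 = c(0, 0, 1, 1), g3 = c(0, 0, 1, 1))
  rownames(vals) <- meta$chip_id
  ds0 <- expr_dataset(vals, meta)
  f_inf <- term_formula("c", "ac")
  expect_true(is.infinite(evaluate_formula(ds0, motif, f_inf)))
  # degenerate (constant) data: missing score
  dsc <- expr_dataset(matrix(1, 4, 3, dimnames = list(meta$chip_id,
                                                      c("g1", "g2", "g3"))),
                      meta)
  expect_true(is.na(evaluate_formula(dsc, motif, f_eta)))
})

test_that("SSc formula is invariant under swapping the two TF roles", {
  ds <- make_dataset(n_genes = 3, n_conditions = 8, n_replicates = 3, seed = 21)
  m1 <- tibble::tibble(motif_type = "FFL", tf_x = "g1", tf_y = "g2", tg_z = "g3")
  m2 <- tibble::tibble(motif_type = "FFL", tf_x = "g2", tf_y = "g1", tg_z = "g3")
  f <- term_formula("c")
  expect_equal(evaluate_formula(ds, m1, f), evaluate_formula(ds, m2, f),
               tolerance = 1e-12)
})

test_that("toy CSC dataset reproduces the documented SS pattern", {
  ok_b_a <- logical(0); ok_bc_ac <- logical(0)
  for (seed in 1:20) {
    td <- toy_datasets(n_conditions = 50, seed = seed)
    nt <- normalize_terms(ss_decompose(
      build_design(td$csc, "tf_x", "tf_y", "tg_z")))
    ok_b_a <- c(ok_b_a, nt[["b"]] > nt[["a"]])
    ok_bc_ac <- c(ok_bc_ac, nt[["bc"]] > nt[["ac"]])
  }
  expect_true(all(ok_b_a))
  expect_true(all(ok_bc_ac))
})

test_that("cross-validated selection behaves on trivial, null and real cases", {
  sim <- simulate_grn(sim_config("artificial_like",
                                 n_motifs = c(CSC = 0, FFL = 30, DOR = 30),
                                 n_background_genes = 2, n_conditions = 60,
                                 seed = 3))
  task <- c("DOR", "FFL")
  m <- sim$motifs
  # single candidate is returned unchanged
  single <- list(term_formula("ac"))
  fit1 <- cross_validated_selection(sim$dataset, m, task, candidates = single,
                                    seed = 1)
  expect_equal(format_formula(fit1$formula), "SSac@(X,Y,Z)")
  expect_true(fit1$cv_auroc >= 0 && fit1$cv_auroc <= 1)
  # permuted labels give near-chance CV AUROC
  set.seed(5)
  mperm <- m
  mperm$motif_type <- sample(mperm$motif_type)
  fitp <- cross_validated_selection(sim$dataset, mperm, task,
                                    candidates = candidate_formulas(1),
                                    seed = 1)
  expect_lt(abs(fitp$cv_auroc - 0.5), 0.15)
  # recovery: DOR vs FFL on artificial-like data is nearly solved
  fit <- cross_validated_selection(sim$dataset, m, task, seed = 1)
  expect_gte(fit$cv_auroc, 0.9)
  # too few motifs per class
  expect_error(cross_validated_selection(sim$dataset, m[1:4, ], task),
               "per class")
  # tidy/glance expose the candidate table and the winner
  expect_equal(nrow(tidy(fit)), length(candidate_formulas()))
  expect_equal(glance(fit)$formula, format_formula(fit$formula))
})

test_that("rank_motifs orders by score with stable ties and missing last", {
  ds <- make_dataset(n_genes = 6, n_conditions = 8, n_replicates = 2, seed = 30)
  motifs <- tibble::tibble(
    motif_type = c("FFL", "DOR", "DOR"),
    tf_x = c("g1", "g2", "g1"), tf_y = c("g2", "g4", "g4"),
    tg_z = c("g3", "g5", "g6"))
  tab <- rank_motifs(ds, motifs, term_formula("c"), c("FFL", "DOR"))
  expect_equal(nrow(tab), 3)
  expect_false(is.unsorted(rev(tab$score)))
  expect_equal(attr(tab, "n_missing"), 0)
  # round trip through the score-table writer
  p <- withr::local_tempfile(fileext = ".tsv")
  write_score_table(tab, p)
  back <- read_score_table(p)
  expect_setequal(back$identifier, tab$identifier)
  expect_equal(back$score[match(tab$identifier, back$identifier)], tab$score)
})
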