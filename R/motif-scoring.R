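ALL_SS_TERMS <- c("a", "b", "c", "ab", "ac", "bc", "abc", "error")
ROLE_LETTERS <- c(tf_x = "X", tf_y = "Y", tg_z = "Z")
# The three role orders in use: which gene occupies the target (third) slot
# varies; the two TF-slot orderings are equivalent under the A/B symmetry of
# the term grammar.
DEFAULT_ROLE_ORDERS <- list(
  c("tf_x", "tf_y", "tg_z"),
  c("tf_y", "tg_z", "tf_x"),
  c("tf_x", "tg_z", "tf_y")
)

canonical_term <- function(t) {
  t <- sub("^SS_?", "", t, ignore.case = TRUE)
  t <- tolower(t)
  if (!all(t %in% ALL_SS_TERMS)) {
    stop("unknown SS term(s): ", paste(setdiff(t, ALL_SS_TERMS), collapse = ", "),
         call. = FALSE)
  }
  t
}

#' Construct a three-way-ANOVA term formula
#'
#' A motif score of the form `prod(numerator) / prod(denominator)` over
#' normalized SS terms of the three-way design, together with the role
#' order used when building the design (which gene is passed to which of
#' the three slots; the third slot is the target slot) and a flag selecting
#' per-condition perturbation weights.
#'
#' @param numerator,denominator Character vectors of SS term names (`"a"`,
#'   `"b"`, `"c"`, `"ab"`, `"ac"`, `"bc"`, `"abc"`, `"error"`, with or
#'   without an `SS` prefix). At most 4 terms in total (enough to express
#'   every published term combination); the default candidate search uses
#'   at most 3.
#' @param role_order Length-3 character permutation over
#'   `c("tf_x", "tf_y", "tg_z")`.
#' @param use_weights Use the perturbation-condition weight preset when
#'   building designs.
#' @return An object of class `term_formula`.
#' @export
term_formula <- function(numerator, denominator = character(),
                         role_order = c("tf_x", "tf_y", "tg_z"),
                         use_weights = FALSE) {
  numerator <- canonical_term(numerator)
  denominator <- if (length(denominator)) canonical_term(denominator) else character(0)
  if (length(numerator) + length(denominator) > 4) {
    stop("at most 4 SS terms per formula", call. = FALSE)
  }
  if (length(numerator) + length(denominator) == 0) {
    stop("formula needs at least one term", call. = FALSE)
  }
  if (length(role_order) != 3 ||
      !setequal(role_order, c("tf_x", "tf_y", "tg_z"))) {
    stop("role_order must be a permutation of tf_x, tf_y, tg_z", call. = FALSE)
  }
  structure(
    list(numerator = numerator, denominator = denominator,
         role_order = role_order, use_weights = isTRUE(use_weights)),
    class = "term_formula"
  )
}

#' Serialize and parse term formulas
#'
#' Compact bit-stable string form, e.g. `"SSc*SSbc/SSac@(X,Z,Y)+w"`:
#' numerator terms joined by `*` (or `1` if empty), denominator terms after
#' `/`, the role order in parentheses (`X` = tf_x, `Y` = tf_y, `Z` = tg_z)
#' and a trailing `+w` when perturbation weights are used.
#'
#' @param formula A [term_formula()].
#' @return `format_formula()` a string; `parse_formula()` a `term_formula`.
#' @export
format_formula <- function(formula) {
  stopifnot(inherits(formula, "term_formula"))
  num <- if (length(formula$numerator)) {
    paste(paste0("SS", formula$numerator), collapse = "*")
  } else "1"
  den <- if (length(formula$denominator)) {
    paste0("/", paste(paste0("SS", formula$denominator), collapse = "*"))
  } else ""
  roles <- paste(ROLE_LETTERS[formula$role_order], collapse = ",")
  paste0(num, den, "@(", roles, ")", if (formula$use_weights) "+w" else "")
}

#' @rdname format_formula
#' @param text Serialized formula string.
#' @export
parse_formula <- function(text) {
  m <- regmatches(text, regexec(
    "^([^/@]+)(?:/([^@]+))?@\\(([XYZ]),([XYZ]),([XYZ])\\)(\\+w)?$", text))[[1]]
  if (length(m) == 0) stop("cannot parse formula: ", text, call. = FALSE)
  split_terms <- function(s) {
    if (is.na(s) || s == "" || s == "1") character(0)
    else strsplit(s, "*", fixed = TRUE)[[1]]
  }
  role_of <- stats::setNames(names(ROLE_LETTERS), ROLE_LETTERS)
  term_formula(
    numerator = split_terms(m[2]),
    denominator = split_terms(m[3]),
    role_order = unname(role_of[c(m[4], m[5], m[6])]),
    use_weights = !is.na(m[7]) && m[7] == "+w"
  )
}

#' @export
print.term_formula <- function(x, ...) {
  cat("<term_formula>", format_formula(x), "\n")
  invisible(x)
}

#' @export
format.term_formula <- function(x, ...) format_formula(x)

# Normalized-SS lookup tables for a motif set: for every role order and
# weight variant needed, a motifs x 8 matrix of log normalized terms.
# log(0) = -Inf; degenerate designs (SS_T = 0) give all-NA rows.
motif_term_table <- function(dataset, motifs, role_orders = DEFAULT_ROLE_ORDERS,
                             weight_variants = c(FALSE, TRUE)) {
  w_preset <- perturbation_weights(dataset)
  tables <- list()
  for (ro in role_orders) {
    for (uw in weight_variants) {
      key <- term_table_key(ro, uw)
      mat <- matrix(NA_real_, nrow = nrow(motifs), ncol = length(ALL_SS_TERMS),
                    dimnames = list(NULL, ALL_SS_TERMS))
      for (i in seq_len(nrow(motifs))) {
        gs <- c(motifs$tf_x[i], motifs$tf_y[i], motifs$tg_z[i])
        names(gs) <- c("tf_x", "tf_y", "tg_z")
        design <- build_design(dataset, gs[[ro[1]]], gs[[ro[2]]], gs[[ro[3]]],
                               weights = if (uw) w_preset else NULL)
        dec <- ss_decompose(design)
        if (dec$ss_total > 0) {
          mat[i, ] <- log(dec$terms[ALL_SS_TERMS] / dec$ss_total)
        }
      }
      tables[[key]] <- mat
    }
  }
  tables
}

term_table_key <- function(role_order, use_weights) {
  paste0(paste(ROLE_LETTERS[role_order], collapse = ""),
         if (use_weights) "+w" else "")
}

# Vectorized formula scores from a precomputed term table.
score_from_table <- function(tables, formula) {
  mat <- tables[[term_table_key(formula$role_order, formula$use_weights)]]
  num <- rowSums(mat[, formula$numerator, drop = FALSE])
  den <- rowSums(mat[, formula$denominator, drop = FALSE])
  s <- exp(num - den)
  s[is.nan(s)] <- NA_real_   # 0/0 within the term products
  s
}

#' Evaluate a term formula on one motif
#'
#' Builds the three-way design with the motif's genes assigned per the
#' formula's role order, decomposes and normalizes it, and returns the
#' product of numerator terms divided by the product of denominator terms.
#' A zero denominator term yields `Inf`; a degenerate design (`SS_T = 0`)
#' yields `NA`.
#'
#' @param dataset An [expr_dataset()].
#' @param motif One-row motif tibble (or list with `tf_x`, `tf_y`, `tg_z`).
#' @param formula A [term_formula()].
#' @return A single score (possibly `Inf` or `NA`).
#' @export
evaluate_formula <- function(dataset, motif, formula) {
  stopifnot(inherits(formula, "term_formula"))
  motif <- tibble::as_tibble(motif[c("tf_x", "tf_y", "tg_z")])
  if (nrow(motif) != 1) stop("evaluate_formula scores one motif; see rank_motifs()",
                             call. = FALSE)
  tables <- motif_term_table(dataset, motif,
                             role_orders = list(formula$role_order),
                             weight_variants = formula$use_weights)
  score_from_table(tables, formula)[[1]]
}

#' Enumerate candidate term formulas
#'
#' Deterministic enumeration of all monomial formulas with at most
#' `max_terms` distinct SS terms, each with exponent +1 (numerator) or -1
#' (denominator), crossed with the three role orders that place each gene
#' in the target slot and with the weight flag. `SS_abc` and `SS_error`
#' represent unexplained variance and are excluded from the default search
#' space.
#'
#' @param max_terms 1, 2 or 3.
#' @param include_error_terms Also search over `abc` and `error`.
#' @param weight_variants Logical vector of weight-flag values to cross in.
#' @return List of [term_formula()] objects.
#' @export
candidate_formulas <- function(max_terms = 3, include_error_terms = FALSE,
                               weight_variants = c(FALSE, TRUE)) {
  if (!max_terms %in% 1:3) stop("max_terms must be 1, 2 or 3", call. = FALSE)
  terms <- if (include_error_terms) ALL_SS_TERMS else setdiff(ALL_SS_TERMS, c("abc", "error"))
  out <- list()
  for (k in seq_len(max_terms)) {
    subsets <- utils::combn(terms, k, simplify = FALSE)
    for (s in subsets) {
      for (mask in 0:(2^k - 1)) {
        in_den <- as.logical(bitwAnd(mask, 2^(seq_len(k) - 1)))
        num <- s[!in_den]; den <- s[in_den]
        for (ro in DEFAULT_ROLE_ORDERS) {
          for (uw in weight_variants) {
            out[[length(out) + 1]] <- term_formula(num, den, role_order = ro,
                                                   use_weights = uw)
          }
        }
      }
    }
  }
  out
}

#' Three-fold cross-validated formula selection
#'
#' Splits labeled motifs into stratified folds (reproducibly under `seed`),
#' computes for every candidate formula the mean held-out AUROC over folds
#' with the task's positive class, and returns the arg-max formula. Ties
#' are broken by fewer terms, then by lexicographic serialization. Missing
#' scores are ranked last.
#'
#' @param dataset An [expr_dataset()].
#' @param motifs Motif tibble whose `motif_type` contains both task classes.
#' @param task `c(positive_type, negative_type)`.
#' @param candidates List of [term_formula()] (default
#'   [candidate_formulas()]).
#' @param folds Number of CV folds (default 3).
#' @param seed Integer seed for the fold assignment (default 0).
#' @return Object of class `cv_formula_fit` with elements `formula`,
#'   `cv_auroc`, `task`, and a per-candidate `results` tibble. Has
#'   [generics::tidy()] and [generics::glance()] methods.
#' @export
cross_validated_selection <- function(dataset, motifs, task,
                                      candidates = candidate_formulas(),
                                      folds = 3, seed = 0L) {
  keep <- motifs$motif_type %in% task
  motifs <- motifs[keep, , drop = FALSE]
  labels <- as.integer(motifs$motif_type == task[1])
  if (sum(labels == 1) < folds || sum(labels == 0) < folds) {
    stop(sprintf("need at least %d motifs per class for %d-fold CV", folds, folds),
         call. = FALSE)
  }
  fold_id <- integer(nrow(motifs))
  with_preserved_seed(seed, {
    for (lab in c(0L, 1L)) {
      idx <- which(labels == lab)
      idx <- idx[sample.int(length(idx))]
      fold_id[idx] <- rep(seq_len(folds), length.out = length(idx))
    }
  })
  need_weights <- any(vapply(candidates, function(f) f$use_weights, logical(1)))
  ros <- unique(lapply(candidates, function(f) f$role_order))
  tables <- motif_term_table(dataset, motifs, role_orders = ros,
                             weight_variants = unique(c(FALSE, need_weights)))
  cv_auroc <- vapply(candidates, function(f) {
    s <- score_from_table(tables, f)
    s[is.na(s)] <- -Inf
    mean(vapply(seq_len(folds), function(k) {
      held <- fold_id == k
      auroc(s[held], labels[held])
    }, numeric(1)))
  }, numeric(1))
  serial <- vapply(candidates, format_formula, character(1))
  n_terms <- vapply(candidates, function(f) length(f$numerator) + length(f$denominator),
                    integer(1))
  ord <- order(-cv_auroc, n_terms, serial)
  best <- ord[1]
  structure(
    list(formula = candidates[[best]], cv_auroc = cv_auroc[best], task = task,
         folds = folds, seed = seed,
         results = tibble::tibble(formula = serial, n_terms = n_terms,
                                  cv_auroc = cv_auroc)[order(-cv_auroc, n_terms, serial), ]),
    class = "cv_formula_fit"
  )
}

#' @export
print.cv_formula_fit <- function(x, ...) {
  cat(sprintf("<cv_formula_fit> %s vs %s: %s (CV AUROC %.3f, %d folds)\n",
              x$task[1], x$task[2], format_formula(x$formula), x$cv_auroc,
              x$folds))
  invisible(x)
}

#' @export
tidy.cv_formula_fit <- function(x, ...) x$results

#' @export
glance.cv_formula_fit <- function(x, ...) {
  tibble::tibble(formula = format_formula(x$formula), cv_auroc = x$cv_auroc,
                 positive = x$task[1], negative = x$task[2],
                 folds = x$folds, n_candidates = nrow(x$results))
}

#' Rank motifs with a term formula
#'
#' Scores every motif with [evaluate_formula()]'s product/ratio (computed in
#' bulk) and returns a score table sorted by decreasing score, ties broken
#' stably by motif identifier, missing scores last.
#'
#' @inheritParams cross_validated_selection
#' @param formula A [term_formula()] or its serialized string.
#' @return Score-table tibble (`identifier`, `method`, `task`, `score`)
#'   with attribute `n_missing`.
#' @export
rank_motifs <- function(dataset, motifs, formula, task = c("CSC", "FFL")) {
  if (is.character(formula)) formula <- parse_formula(formula)
  tables <- motif_term_table(dataset, motifs,
                             role_orders = list(formula$role_order),
                             weight_variants = formula$use_weights)
  s <- score_from_table(tables, formula)
  out <- tibble::tibble(
    identifier = motif_id(motifs),
    method = "3WA",
    task = paste(task, collapse = "_vs_"),
    score = s
  )
  ord <- order(is.na(out$score), -ifelse(is.na(out$score), 0, out$score),
               out$identifier)
  out <- out[ord, ]
  attr(out, "n_missing") <- sum(is.na(s))
  out
}
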