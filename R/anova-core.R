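#' Construct a factorial ANOVA design
#'
#' Low-level constructor for the balanced N-way (N = 1, 2, 3) factorial
#' design consumed by [ss_decompose()]. The response is a 4-dimensional
#' array `y[r, a, b, c]` indexed by replicate, level of factor A, level of
#' factor B, and condition; factors absent for `n_ways < 3` have a single
#' level (the corresponding dimension is 1). In the three-way design built
#' by [build_design()], factor A distinguishes the first TF from the target
#' and factor B the second TF, and the (a = 2, b = 2) cells hold the imputed
#' common activity of the two TFs.
#'
#' @param response Numeric 4-d array `[replicate, A, B, condition]`. For
#'   `n_ways = 1` a replicate x condition matrix is also accepted.
#' @param n_ways 1, 2 or 3.
#' @param weights Optional non-negative per-condition weights (default all
#'   1). Weights act as frequency-style multiplicities of conditions: all
#'   means and squared-deviation sums over conditions are weighted, which
#'   preserves the exact sum-of-squares decomposition.
#' @param imputed_mask Optional logical array marking imputed cells.
#' @return An object of class `factorial_design`.
#' @export
factorial_design <- function(response, n_ways, weights = NULL,
                             imputed_mask = NULL) {
  if (is.matrix(response)) {
    response <- array(response, dim = c(nrow(response), 1L, 1L, ncol(response)))
  }
  if (!is.array(response) || length(dim(response)) != 4L) {
    stop("`response` must be a 4-d array [replicate, A, B, condition]",
         call. = FALSE)
  }
  if (!all(is.finite(response))) stop("all responses must be finite", call. = FALSE)
  d <- dim(response)
  n_ways <- as.integer(n_ways)
  expected_ab <- switch(n_ways, `1` = c(1L, 1L), `2` = c(2L, 1L), `3` = c(2L, 2L))
  if (is.null(expected_ab)) stop("`n_ways` must be 1, 2 or 3", call. = FALSE)
  if (!identical(d[2:3], expected_ab)) {
    stop(sprintf("for n_ways = %d the A/B dimensions must be (%d, %d)",
                 n_ways, expected_ab[1], expected_ab[2]), call. = FALSE)
  }
  if (d[1] < 1 || d[4] < 2) {
    stop("need at least 1 replicate and 2 conditions", call. = FALSE)
  }
  if (is.null(weights)) weights <- rep(1, d[4])
  if (length(weights) != d[4] || any(!is.finite(weights)) || any(weights < 0) ||
      sum(weights) <= 0) {
    stop("`weights` must be non-negative per-condition reals, at least one > 0",
         call. = FALSE)
  }
  structure(
    list(response = response, n_ways = n_ways, weights = as.numeric(weights),
         imputed_mask = imputed_mask),
    class = "factorial_design"
  )
}

#' @export
print.factorial_design <- function(x, ...) {
  d <- dim(x$response)
  cat(sprintf("<factorial_design> %d-way, %d replicate(s) x %dx%d x %d conditions%s\n",
              x$n_ways, d[1], d[2], d[3], d[4],
              if (any(x$weights != 1)) " (weighted)" else ""))
  invisible(x)
}

# Select the replicate chips of each condition, truncating unequal replicate
# counts to the common minimum (keeping the lowest replicate indices) so the
# closed-form balanced decomposition stays exact.
balanced_chips <- function(dataset) {
  info <- dataset$chips
  split_idx <- split(seq_len(nrow(info)), info$condition_id)
  counts <- lengths(split_idx)
  r <- min(counts)
  if (r < 1) stop("every condition needs at least one replicate", call. = FALSE)
  if (any(counts != r)) {
    warning(sprintf(
      "unbalanced replicate structure: truncating all conditions to %d replicate(s)", r),
      call. = FALSE)
  }
  cond_ids <- unique(info$condition_id) # preserve chip order
  picked <- lapply(cond_ids, function(cc) {
    idx <- split_idx[[cc]]
    idx[order(info$replicate[idx])][seq_len(r)]
  })
  list(conditions = cond_ids, chip_idx = picked, n_replicates = r)
}

# Resolve a weights argument: NULL (uniform), a named/plain numeric vector
# over conditions, or the string "perturbation" for the convenience preset.
resolve_weights <- function(dataset, weights, cond_ids, perturbation_factor = 2) {
  if (is.null(weights)) return(rep(1, length(cond_ids)))
  if (identical(weights, "perturbation")) {
    return(perturbation_weights(dataset, factor = perturbation_factor)[cond_ids])
  }
  if (!is.null(names(weights))) {
    missing_w <- setdiff(cond_ids, names(weights))
    if (length(missing_w) > 0) {
      stop("weights missing for condition(s): ", paste(missing_w, collapse = ", "),
           call. = FALSE)
    }
    return(as.numeric(weights[cond_ids]))
  }
  if (length(weights) != length(cond_ids)) {
    stop("unnamed weights must have one entry per condition", call. = FALSE)
  }
  as.numeric(weights)
}

#' Per-condition weights upweighting perturbation conditions
#'
#' Convenience preset: conditions whose chips carry a non-empty
#' `perturbed_gene` metadata entry receive weight `factor`, all others 1.
#'
#' @param dataset An [expr_dataset()].
#' @param factor Weight assigned to perturbation conditions (default 2).
#' @return Named numeric vector over condition ids.
#' @export
perturbation_weights <- function(dataset, factor = 2) {
  info <- dataset$chips
  perturbed <- if ("perturbed_gene" %in% names(info)) {
    !is.na(info$perturbed_gene) & nzchar(as.character(info$perturbed_gene))
  } else rep(FALSE, nrow(info))
  by_cond <- tapply(perturbed, info$condition_id, any)
  w <- ifelse(by_cond, factor, 1)
  stats::setNames(as.numeric(w), names(by_cond))[unique(info$condition_id)]
}

#' Build the three-way factorial design for a gene triple
#'
#' Assembles the response array `y[r, a, b, c]` from the expression profiles
#' of three genes: cell (a = 0, b = 0) holds the target-slot gene
#' (`gene_third`), (a = 1, b = 0) the first gene, (a = 0, b = 1) the second
#' gene, and (a = 1, b = 1) holds, per replicate and condition, the imputed
#' common activity of the first two genes. Because expression values are log
#' fold changes, the default imputation is the arithmetic mean of the two
#' log-scale values, i.e. the geometric mean on the linear scale; set
#' `impute = "linear"` for the geometric mean of the linearized values.
#'
#' @param dataset An [expr_dataset()] of log fold changes.
#' @param gene_first,gene_second,gene_third Distinct gene ids; `gene_third`
#'   occupies the target slot.
#' @param weights `NULL` (uniform), a per-condition numeric vector, or
#'   `"perturbation"` (see [perturbation_weights()]).
#' @param impute `"log"` (default) or `"linear"` common-activity imputation.
#' @return A `factorial_design` with `n_ways = 3`.
#' @export
build_design <- function(dataset, gene_first, gene_second, gene_third,
                         weights = NULL, impute = c("log", "linear")) {
  impute <- match.arg(impute)
  gs <- c(gene_first, gene_second, gene_third)
  if (anyDuplicated(gs)) stop("the three genes must be distinct", call. = FALSE)
  unknown <- setdiff(gs, colnames(dataset$values))
  if (length(unknown) > 0) {
    stop("unknown gene id(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  bal <- balanced_chips(dataset)
  r <- bal$n_replicates
  n_c <- length(bal$conditions)
  # chips x 3 profile matrix restricted to the balanced chip selection
  idx <- unlist(bal$chip_idx)
  prof <- dataset$values[idx, gs, drop = FALSE]
  x <- matrix(prof[, 1], nrow = r)  # r x C
  y <- matrix(prof[, 2], nrow = r)
  z <- matrix(prof[, 3], nrow = r)
  common <- if (impute == "log") (x + y) / 2 else log2(sqrt(2^x * 2^y))
  resp <- array(NA_real_, dim = c(r, 2L, 2L, n_c))
  resp[, 1, 1, ] <- z
  resp[, 2, 1, ] <- x
  resp[, 1, 2, ] <- y
  resp[, 2, 2, ] <- common
  mask <- array(FALSE, dim = dim(resp))
  mask[, 2, 2, ] <- TRUE
  w <- resolve_weights(dataset, weights, bal$conditions)
  out <- factorial_design(resp, n_ways = 3L, weights = w, imputed_mask = mask)
  out$conditions <- bal$conditions
  out$genes <- gs
  out
}

#' Build the two-way (gene x condition) design for a gene pair
#'
#' Factor A distinguishes the TF (a = 1) from the target gene (a = 0);
#' factor C indexes conditions.
#'
#' @inheritParams build_design
#' @param tf,tg Distinct gene ids.
#' @return A `factorial_design` with `n_ways = 2`.
#' @export
build_design_2way <- function(dataset, tf, tg, weights = NULL) {
  if (identical(tf, tg)) stop("the two genes must be distinct", call. = FALSE)
  unknown <- setdiff(c(tf, tg), colnames(dataset$values))
  if (length(unknown) > 0) {
    stop("unknown gene id(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  bal <- balanced_chips(dataset)
  r <- bal$n_replicates
  idx <- unlist(bal$chip_idx)
  prof <- dataset$values[idx, c(tf, tg), drop = FALSE]
  resp <- array(NA_real_, dim = c(r, 2L, 1L, length(bal$conditions)))
  resp[, 1, 1, ] <- matrix(prof[, 2], nrow = r)  # target at a = 0
  resp[, 2, 1, ] <- matrix(prof[, 1], nrow = r)  # TF at a = 1
  w <- resolve_weights(dataset, weights, bal$conditions)
  out <- factorial_design(resp, n_ways = 2L, weights = w)
  out$conditions <- bal$conditions
  out$genes <- c(tf, tg)
  out
}

#' Build the one-way (condition) design for a single gene
#'
#' @inheritParams build_design
#' @param gene A gene id.
#' @return A `factorial_design` with `n_ways = 1`.
#' @export
build_design_1way <- function(dataset, gene, weights = NULL) {
  if (!gene %in% colnames(dataset$values)) {
    stop("unknown gene id: ", gene, call. = FALSE)
  }
  bal <- balanced_chips(dataset)
  idx <- unlist(bal$chip_idx)
  resp <- matrix(dataset$values[idx, gene], nrow = bal$n_replicates)
  w <- resolve_weights(dataset, weights, bal$conditions)
  out <- factorial_design(resp, n_ways = 1L, weights = w)
  out$conditions <- bal$conditions
  out$genes <- gene
  out
}

# Which SS terms exist for each number of ways (besides error).
ss_term_names <- function(n_ways) {
  switch(n_ways,
         `1` = "c",
         `2` = c("a", "c", "ac"),
         `3` = c("a", "b", "c", "ab", "ac", "bc", "abc"))
}

#' Sum-of-squares decomposition of a factorial design
#'
#' Partitions the total sum of squared deviations from the (weighted) grand
#' mean into the 2, 4 or 8 terms of a balanced 1-, 2- or 3-way fixed-effects
#' ANOVA: main effects, interactions and the within-cell error term. With
#' per-condition weights, every mean and every squared-deviation sum over
#' conditions is weighted, so the exact identity `SS_T = sum of terms`
#' is preserved.
#'
#' @param design A [factorial_design()].
#' @return An object of class `ss_decomp`: named `terms` (sums of squares),
#'   named `df`, plus `ss_total`, `df_total` and `n_ways`. Floating-point
#'   negatives above `-1e-12` (relative) are clamped to zero.
#' @export
ss_decompose <- function(design) {
  stopifnot(inherits(design, "factorial_design"))
  yy <- design$response
  d <- dim(yy)
  r <- d[1]; na <- d[2]; nb <- d[3]; nc <- d[4]
  w <- design$weights
  wp <- w / sum(w)          # normalized condition weights
  sw <- sum(w)              # effective number of conditions
  m_abc <- apply(yy, c(2, 3, 4), mean)            # cell means over replicates
  dim(m_abc) <- c(na, nb, nc)
  wc <- function(arr_c) sum(arr_c * wp)           # weighted mean over c
  m_ab <- apply(sweep(m_abc, 3, wp, "*"), c(1, 2), sum)
  m_ac <- apply(m_abc, c(1, 3), mean)             # mean over b
  m_bc <- apply(m_abc, c(2, 3), mean)             # mean over a
  m_a <- rowMeans(matrix(m_ab, nrow = na, ncol = nb))
  m_b <- colMeans(matrix(m_ab, nrow = na, ncol = nb))
  m_c <- apply(m_abc, 3, mean)
  grand <- wc(m_c)

  terms <- c(a = NA_real_, b = NA_real_, c = NA_real_, ab = NA_real_,
             ac = NA_real_, bc = NA_real_, abc = NA_real_)
  terms["a"] <- r * nb * sw * sum((m_a - grand)^2)
  terms["b"] <- r * na * sw * sum((m_b - grand)^2)
  terms["c"] <- r * na * nb * sum(w * (m_c - grand)^2)
  ab_dev <- sweep(sweep(m_ab, 1, m_a, "-"), 2, m_b, "-") + grand
  terms["ab"] <- r * sw * sum(ab_dev^2)
  ac_dev <- sweep(sweep(m_ac, 1, m_a, "-"), 2, m_c, "-") + grand
  terms["ac"] <- r * nb * sum(sweep(ac_dev^2, 2, w, "*"))
  bc_dev <- sweep(sweep(m_bc, 1, m_b, "-"), 2, m_c, "-") + grand
  terms["bc"] <- r * na * sum(sweep(bc_dev^2, 2, w, "*"))
  abc_dev <- m_abc
  for (a in seq_len(na)) for (b in seq_len(nb)) for (cc in seq_len(nc)) {
    abc_dev[a, b, cc] <- m_abc[a, b, cc] - m_ab[a, b] - m_ac[a, cc] - m_bc[b, cc] +
      m_a[a] + m_b[b] + m_c[cc] - grand
  }
  terms["abc"] <- r * sum(sweep(abc_dev^2, 3, w, "*"))
  resid <- sweep(yy, c(2, 3, 4), m_abc, "-")
  err <- sum(sweep(resid^2, 4, w, "*"))
  ss_total <- sum(sweep((yy - grand)^2, 4, w, "*"))

  keep <- ss_term_names(design$n_ways)
  terms <- c(terms[keep], error = err)
  tol <- 1e-12 * max(1, ss_total)
  if (any(terms < -tol)) {
    stop("internal error: negative sum of squares beyond tolerance", call. = FALSE)
  }
  terms[terms < 0] <- 0

  df <- c(a = na - 1L, b = nb - 1L, c = nc - 1L,
          ab = (na - 1L) * (nb - 1L), ac = (na - 1L) * (nc - 1L),
          bc = (nb - 1L) * (nc - 1L), abc = (na - 1L) * (nb - 1L) * (nc - 1L))
  df <- c(df[keep], error = na * nb * nc * (r - 1L))
  structure(
    list(terms = terms, df = df, ss_total = ss_total,
         df_total = r * na * nb * nc - 1L, n_ways = design$n_ways,
         weighted = any(design$weights != design$weights[1])),
    class = "ss_decomp"
  )
}

#' @export
print.ss_decomp <- function(x, ...) {
  cat(sprintf("<ss_decomp> %d-way ANOVA, SS_T = %.6g\n", x$n_ways, x$ss_total))
  print(tidy.ss_decomp(x))
  invisible(x)
}

#' Tidy a sum-of-squares decomposition
#'
#' @param x An `ss_decomp`.
#' @param ... Unused.
#' @return A tibble with one row per SS term: `term`, `ss`, `df`,
#'   `proportion` (of `SS_T`), `statistic` (F against the error term) and
#'   `p.value` (NA for the error term itself).
#' @importFrom generics tidy
#' @export
tidy.ss_decomp <- function(x, ...) {
  nm <- names(x$terms)
  fs <- vapply(setdiff(nm, "error"), function(t) {
    if (x$df[["error"]] < 1) return(c(NA_real_, NA_real_))
    f <- f_statistic(x, t)
    c(f$statistic, f$p.value)
  }, numeric(2))
  tibble::tibble(
    term = nm,
    ss = unname(x$terms),
    df = unname(as.integer(x$df)),
    proportion = if (x$ss_total > 0) unname(x$terms) / x$ss_total else NA_real_,
    statistic = c(unname(fs[1, ]), NA_real_),
    p.value = c(unname(fs[2, ]), NA_real_)
  )
}

#' Glance at a decomposition
#'
#' @param x An `ss_decomp`.
#' @param ... Unused.
#' @return One-row tibble with `ss_total`, `df_total`, `n_ways`,
#'   `eta_sq_c` (condition eta-squared) and `f_eta` (the variance-ratio
#'   companion `V_C / V_T`).
#' @importFrom generics glance
#' @export
glance.ss_decomp <- function(x, ...) {
  eta <- if (x$ss_total > 0) x$terms[["c"]] / x$ss_total else NA_real_
  f_eta <- if (x$ss_total > 0) {
    (x$terms[["c"]] / x$df[["c"]]) / (x$ss_total / x$df_total)
  } else NA_real_
  tibble::tibble(ss_total = x$ss_total, df_total = x$df_total,
                 n_ways = x$n_ways, eta_sq_c = eta, f_eta = f_eta)
}

#' F statistic and p-value for one SS term
#'
#' `F = (SS_term / df_term) / (SS_error / df_error)`, with the p-value from
#' the F distribution on `(df_term, df_error)` degrees of freedom. A zero
#' error sum of squares yields `F = Inf`, `p = 0`, flagged via
#' `zero_error = TRUE`.
#'
#' @param decomp An `ss_decomp`.
#' @param term One of the decomposition's term names (not `"error"`).
#' @return List with `statistic`, `p.value`, `df`, `zero_error`.
#' @export
f_statistic <- function(decomp, term) {
  stopifnot(inherits(decomp, "ss_decomp"))
  if (!term %in% names(decomp$terms) || term == "error") {
    stop("unknown term: ", term, call. = FALSE)
  }
  df_e <- decomp$df[["error"]]
  if (df_e < 1) stop("error degrees of freedom must be >= 1", call. = FALSE)
  ms_t <- decomp$terms[[term]] / decomp$df[[term]]
  ms_e <- decomp$terms[["error"]] / df_e
  if (ms_e == 0) {
    return(list(statistic = Inf, p.value = 0,
                df = c(decomp$df[[term]], df_e), zero_error = TRUE))
  }
  f <- ms_t / ms_e
  list(statistic = f,
       p.value = stats::pf(f, decomp$df[[term]], df_e, lower.tail = FALSE),
       df = c(decomp$df[[term]], df_e), zero_error = FALSE)
}

#' Condition eta-squared of a decomposition
#'
#' The fraction of total variance explained by the condition factor,
#' `SS_C / SS_T`, used as a non-linear dependency score.
#'
#' @param decomp An `ss_decomp`.
#' @return A ratio in `[0, 1]`.
#' @export
eta_squared <- function(decomp) {
  stopifnot(inherits(decomp, "ss_decomp"))
  if (decomp$ss_total <= 0) {
    stop("degenerate input: total sum of squares is zero", call. = FALSE)
  }
  decomp$terms[["c"]] / decomp$ss_total
}

#' Normalize SS terms to fractions of the total
#'
#' Divides every term (including error) by `SS_T`; the returned ratios lie
#' in `[0, 1]` and sum to 1.
#'
#' @param decomp An `ss_decomp`.
#' @return Named numeric vector of ratios.
#' @export
normalize_terms <- function(decomp) {
  stopifnot(inherits(decomp, "ss_decomp"))
  if (decomp$ss_total <= 0) {
    stop("degenerate input: total sum of squares is zero", call. = FALSE)
  }
  decomp$terms / decomp$ss_total
}
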