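# Independent oracles used across the suite. These are deliberately written
# as explicit loops / direct definitions, independent of the package's
# vectorized implementations.

# Brute-force balanced N-way SS decomposition by explicit deviation sums,
# with optional per-condition frequency weights.
bf_decompose <- function(arr, weights = rep(1, dim(arr)[4])) {
  d <- dim(arr)
  R <- d[1]; A <- d[2]; B <- d[3]; C <- d[4]
  w <- weights
  sw <- sum(w)
  wm <- function(vals_by_c) sum(vals_by_c * w) / sw  # weighted mean over c

  grand <- 0
  for (cc in 1:C) {
    s <- 0
    for (r in 1:R) for (a in 1:A) for (b in 1:B) s <- s + arr[r, a, b, cc]
    grand <- grand + w[cc] * s / (R * A * B)
  }
  grand <- grand / sw

  m_abc <- array(0, dim = c(A, B, C))
  for (a in 1:A) for (b in 1:B) for (cc in 1:C) {
    m_abc[a, b, cc] <- mean(arr[, a, b, cc])
  }
  m_a <- numeric(A); m_b <- numeric(B); m_c <- numeric(C)
  for (a in 1:A) m_a[a] <- wm(sapply(1:C, function(cc) mean(m_abc[a, , cc])))
  for (b in 1:B) m_b[b] <- wm(sapply(1:C, function(cc) mean(m_abc[, b, cc])))
  for (cc in 1:C) m_c[cc] <- mean(m_abc[, , cc])
  m_ab <- matrix(0, A, B)
  for (a in 1:A) for (b in 1:B) m_ab[a, b] <- wm(m_abc[a, b, ])
  m_ac <- matrix(0, A, C)
  for (a in 1:A) for (cc in 1:C) m_ac[a, cc] <- mean(m_abc[a, , cc])
  m_bc <- matrix(0, B, C)
  for (b in 1:B) for (cc in 1:C) m_bc[b, cc] <- mean(m_abc[, b, cc])

  ss <- c(a = 0, b = 0, c = 0, ab = 0, ac = 0, bc = 0, abc = 0,
          error = 0, total = 0)
  for (a in 1:A) ss["a"] <- ss["a"] + R * B * sw * (m_a[a] - grand)^2
  for (b in 1:B) ss["b"] <- ss["b"] + R * A * sw * (m_b[b] - grand)^2
  for (cc in 1:C) ss["c"] <- ss["c"] + R * A * B * w[cc] * (m_c[cc] - grand)^2
  for (a in 1:A) for (b in 1:B) {
    ss["ab"] <- ss["ab"] + R * sw * (m_ab[a, b] - m_a[a] - m_b[b] + grand)^2
  }
  for (a in 1:A) for (cc in 1:C) {
    ss["ac"] <- ss["ac"] +
      R * B * w[cc] * (m_ac[a, cc] - (grand + (m_c[cc] - grand) + (m_a[a] - grand)))^2
  }
  for (b in 1:B) for (cc in 1:C) {
    ss["bc"] <- ss["bc"] + R * A * w[cc] * (m_bc[b, cc] - m_b[b] - m_c[cc] + grand)^2
  }
  for (a in 1:A) for (b in 1:B) for (cc in 1:C) {
    dev <- m_abc[a, b, cc] - m_ab[a, b] - m_ac[a, cc] - m_bc[b, cc] +
      m_a[a] + m_b[b] + m_c[cc] - grand
    ss["abc"] <- ss["abc"] + R * w[cc] * dev^2
  }
  for (r in 1:R) for (a in 1:A) for (b in 1:B) for (cc in 1:C) {
    ss["error"] <- ss["error"] + w[cc] * (arr[r, a, b, cc] - m_abc[a, b, cc])^2
    ss["total"] <- ss["total"] + w[cc] * (arr[r, a, b, cc] - grand)^2
  }
  ss
}

# Reference ANOVA through stats::lm/anova (balanced, unweighted designs).
ref_anova <- function(arr) {
  df <- data.frame(
    y = as.vector(arr),
    A = factor(as.vector(slice.index(arr, 2))),
    B = factor(as.vector(slice.index(arr, 3))),
    C = factor(as.vector(slice.index(arr, 4)))
  )
  drop <- c(if (dim(arr)[2] == 1) "A", if (dim(arr)[3] == 1) "B")
  rhs <- setdiff(c("A", "B", "C"), drop)
  form <- stats::as.formula(paste("y ~", paste(rhs, collapse = " * ")))
  stats::anova(stats::lm(form, df))
}

# Plug-in MI from a contingency table of bin labels.
bf_mi <- function(bx, by) {
  tab <- table(bx, by)
  p <- tab / sum(tab)
  px <- rowSums(p); py <- colSums(p)
  s <- 0
  for (i in seq_along(px)) for (j in seq_along(py)) {
    if (p[i, j] > 0) s <- s + p[i, j] * log(p[i, j] / (px[i] * py[j]))
  }
  as.numeric(s)
}

bf_entropy <- function(...) {
  tab <- table(...)
  p <- tab[tab > 0] / sum(tab)
  -sum(p * log(p))
}

# AUROC by brute force over all positive-negative pairs (ties = 1/2).
bf_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  s <- 0
  for (p in pos) for (n in neg) s <- s + (p > n) + 0.5 * (p == n)
  s / (length(pos) * length(neg))
}

# Brute-force motif enumeration over all ordered gene triples.
bf_enumerate <- function(network) {
  e <- network[network$regulator != network$target, c("regulator", "target")]
  has <- function(u, v) any(e$regulator == u & e$target == v)
  nodes <- sort(unique(c(e$regulator, e$target)))
  out <- list()
  for (x in nodes) for (y in nodes) for (z in nodes) {
    if (length(unique(c(x, y, z))) < 3) next
    mutual <- has(x, y) && has(y, x)
    if (has(y, x) && has(x, z) && !mutual) {
      type <- if (has(y, z)) "FFL" else "CSC"
      out[[length(out) + 1]] <- data.frame(motif_type = type, tf_x = x,
                                           tf_y = y, tg_z = z)
    }
    if (x < y && has(x, z) && has(y, z) && !has(x, y) && !has(y, x)) {
      out[[length(out) + 1]] <- data.frame(motif_type = "DOR", tf_x = x,
                                           tf_y = y, tg_z = z)
    }
  }
  if (length(out) == 0) {
    return(data.frame(motif_type = character(), tf_x = character(),
                      tf_y = character(), tg_z = character()))
  }
  do.call(rbind, out)
}

# Seeded random expression dataset with condition/replicate structure.
make_dataset <- function(n_genes = 5, n_conditions = 6, n_replicates = 2,
                         seed = 1) {
  set.seed(seed)
  gene_ids <- paste0("g", seq_len(n_genes))
  meta <- data.frame(
    chip_id = paste0("c", seq_len(n_conditions * n_replicates)),
    condition_id = rep(paste0("cond", seq_len(n_conditions)), each = n_replicates),
    replicate = rep(seq_len(n_replicates), times = n_conditions)
  )
  vals <- matrix(rnorm(nrow(meta) * n_genes), nrow = nrow(meta),
                 dimnames = list(meta$chip_id, gene_ids))
  expr_dataset(vals, meta, tf_genes = gene_ids[1:2])
}

sorted_motifs <- function(m) {
  m <- as.data.frame(m)[, c("motif_type", "tf_x", "tf_y", "tg_z")]
  m[order(m$motif_type, m$tf_x, m$tf_y, m$tg_z), , drop = FALSE]
}
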