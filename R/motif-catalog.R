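#' Enumerate three-gene motifs from a gold-standard network
#'
#' Scans a directed regulatory network for cascade chains (CSC:
#' `tf_y -> tf_x -> tg_z`, no `tf_y -> tg_z`), feed-forward loops (FFL:
#' `tf_y -> tf_x`, `tf_x -> tg_z`, `tf_y -> tg_z`) and dense-overlapping
#' regulon pairs (DOR: `tf_x -> tg_z`, `tf_y -> tg_z`, no TF:TF edge in
#' either direction). The patterns are mutually exclusive: a triple with all
#' three edges is an FFL only. Self-loops are ignored. Triples whose TF:TF
#' edge is mutual (`x -> y` and `y -> x`) have an ambiguous chain direction
#' and are excluded with a message unless `emit_mutual = TRUE`, in which
#' case both orientations are emitted. DOR instances list the two TFs in
#' lexicographic order. The target gene may itself be a TF.
#'
#' @param network Edge-list tibble (columns `regulator`, `target`).
#' @param emit_mutual Emit both orientations for mutual TF:TF edges instead
#'   of excluding the triple.
#' @return Tibble with columns `motif_type` (`"CSC"`, `"FFL"`, `"DOR"`),
#'   `tf_x`, `tf_y`, `tg_z`.
#' @export
enumerate_motifs <- function(network, emit_mutual = FALSE) {
  edges <- unique(paste(network$regulator, network$target, sep = "\r"))
  parts <- strsplit(edges, "\r", fixed = TRUE)
  reg <- vapply(parts, `[[`, character(1), 1)
  tgt <- vapply(parts, `[[`, character(1), 2)
  keep <- reg != tgt
  reg <- reg[keep]; tgt <- tgt[keep]
  edge_set <- new.env(parent = emptyenv())
  for (i in seq_along(reg)) assign(paste0(reg[i], "\r", tgt[i]), TRUE, envir = edge_set)
  has_edge <- function(u, v) !is.null(edge_set[[paste0(u, "\r", v)]])

  out_type <- character(0); out_x <- character(0)
  out_y <- character(0); out_z <- character(0)
  n_mutual_skipped <- 0L

  targets_of <- split(tgt, reg)
  # CSC / FFL: walk TF:TF edges y -> x, then x -> z
  for (i in seq_along(reg)) {
    y <- reg[i]; x <- tgt[i]
    zs <- targets_of[[x]]
    if (is.null(zs)) next
    mutual <- has_edge(x, y)
    for (z in zs) {
      if (z == y || z == x) next
      if (mutual && !emit_mutual) {
        n_mutual_skipped <- n_mutual_skipped + 1L
        next
      }
      type <- if (has_edge(y, z)) "FFL" else "CSC"
      out_type <- c(out_type, type); out_x <- c(out_x, x)
      out_y <- c(out_y, y); out_z <- c(out_z, z)
    }
  }
  # DOR: unordered regulator pairs of each target, with no TF:TF edge
  regs_of <- split(reg, tgt)
  for (z in names(regs_of)) {
    rs <- sort(unique(regs_of[[z]]))
    if (length(rs) < 2) next
    for (i in seq_len(length(rs) - 1)) {
      for (j in seq(i + 1, length(rs))) {
        u <- rs[i]; v <- rs[j]
        if (has_edge(u, v) || has_edge(v, u)) next
        out_type <- c(out_type, "DOR"); out_x <- c(out_x, u)
        out_y <- c(out_y, v); out_z <- c(out_z, z)
      }
    }
  }
  if (n_mutual_skipped > 0) {
    message(sprintf("%d triple(s) with mutual TF:TF edges excluded from CSC/FFL enumeration",
                    n_mutual_skipped))
  }
  tibble::tibble(motif_type = out_type, tf_x = out_x, tf_y = out_y, tg_z = out_z)
}

#' Motif row identifiers
#'
#' @param motifs Motif tibble as from [enumerate_motifs()].
#' @return Character vector `type:tf_x:tf_y:tg_z`.
#' @export
motif_id <- function(motifs) {
  paste(motifs$motif_type, motifs$tf_x, motifs$tf_y, motifs$tg_z, sep = ":")
}

#' Sample interacting and random gene pairs
#'
#' Labels every (non-self-loop) edge of the network as `TF:TF` or `TF:TG`
#' according to whether the target is itself a regulator, and draws
#' `n_random` unordered non-adjacent gene pairs uniformly without
#' replacement from the dataset's gene universe. Used for the
#' enrichment/difference histogram analyses.
#'
#' @param network Edge-list tibble.
#' @param dataset An [expr_dataset()] supplying the gene universe.
#' @param n_random Number of random (non-edge) pairs to draw.
#' @param seed Integer seed; the sample is reproducible under it.
#' @return Tibble with columns `gene_a`, `gene_b`, `label` in
#'   `{"TF:TF", "TF:TG", "random"}`.
#' @export
sample_pairs <- function(network, dataset, n_random, seed = 0L) {
  if (n_random < 1) stop("n_random must be >= 1", call. = FALSE)
  gene_ids <- genes(dataset)
  tf_set <- union(unique(network$regulator), dataset$tf_genes)
  edges <- network[network$regulator != network$target, , drop = FALSE]
  inter <- tibble::tibble(
    gene_a = edges$regulator, gene_b = edges$target,
    label = ifelse(edges$target %in% tf_set, "TF:TF", "TF:TG")
  )
  n <- length(gene_ids)
  adj_key <- unique(c(paste(edges$regulator, edges$target, sep = "\r"),
                      paste(edges$target, edges$regulator, sep = "\r")))
  # count unordered adjacent pairs among the gene universe
  pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  adj_pairs <- unique(pair_key(edges$regulator, edges$target))
  adj_pairs <- adj_pairs[vapply(strsplit(adj_pairs, "\r", fixed = TRUE),
                                function(p) all(p %in% gene_ids), logical(1))]
  available <- n * (n - 1) / 2 - length(adj_pairs)
  if (available < n_random) {
    stop(sprintf("only %d non-edge pairs available, %d requested",
                 available, n_random), call. = FALSE)
  }
  adj_env <- new.env(parent = emptyenv())
  for (k in adj_pairs) assign(k, TRUE, envir = adj_env)
  chosen_a <- character(0); chosen_b <- character(0)
  seen <- new.env(parent = emptyenv())
  with_preserved_seed(seed, {
    while (length(chosen_a) < n_random) {
      need <- n_random - length(chosen_a)
      i <- sample.int(n, 4 * need + 16, replace = TRUE)
      j <- sample.int(n, 4 * need + 16, replace = TRUE)
      for (k in seq_along(i)) {
        if (i[k] == j[k]) next
        a <- gene_ids[min(i[k], j[k])]; b <- gene_ids[max(i[k], j[k])]
        key <- paste(a, b, sep = "\r")
        if (!is.null(adj_env[[key]]) || !is.null(seen[[key]])) next
        assign(key, TRUE, envir = seen)
        chosen_a <- c(chosen_a, a); chosen_b <- c(chosen_b, b)
        if (length(chosen_a) == n_random) break
      }
    }
  })
  dplyr::bind_rows(inter,
                   tibble::tibble(gene_a = chosen_a, gene_b = chosen_b,
                                  label = "random"))
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_preserved_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Discriminating edge for a pairwise motif classification task
#'
#' For CSC vs FFL the two motifs differ in the `tf_y -> tg_z` edge, so the
#' (tf_y, tg_z) pair is scored and higher dependency ranks toward FFL. Any
#' task involving DOR scores the (tf_x, tf_y) pair — present in CSC and FFL,
#' absent in DOR — and higher dependency ranks away from DOR.
#'
#' @param task Character vector `c(positive_type, negative_type)` with
#'   distinct entries from `{"CSC", "FFL", "DOR"}`.
#' @return List with `edge` (the two roles scored), `conditioning` (the
#'   remaining role, used by conditional measures), `high_type` (the motif
#'   type expected to score high) and `orientation` (+1 if the positive
#'   class is `high_type`, else -1).
#' @export
discriminating_edge <- function(task) {
  types <- c("CSC", "FFL", "DOR")
  if (length(task) != 2 || !all(task %in% types) || task[1] == task[2]) {
    stop("task must be two distinct motif types", call. = FALSE)
  }
  key <- paste(sort(task), collapse = "/")
  spec <- switch(key,
    "CSC/FFL" = list(edge = c("tf_y", "tg_z"), conditioning = "tf_x",
                     high_type = "FFL"),
    "CSC/DOR" = list(edge = c("tf_x", "tf_y"), conditioning = "tg_z",
                     high_type = "CSC"),
    "DOR/FFL" = list(edge = c("tf_x", "tf_y"), conditioning = "tg_z",
                     high_type = "FFL"))
  spec$orientation <- if (task[1] == spec$high_type) 1 else -1
  spec
}

#' Score motifs with a pairwise or conditional dependency measure
#'
#' Applies the measure to each motif's discriminating edge for the given
#' task; conditional measures condition on the third motif gene. The sign
#' convention makes higher scores always rank toward the task's positive
#' class (the first element of `task`). Degenerate profiles yield missing
#' scores.
#'
#' @param motifs Motif tibble (columns `motif_type`, `tf_x`, `tf_y`,
#'   `tg_z`).
#' @param dataset An [expr_dataset()].
#' @param measure One of `"PC"`, `"SP"`, `"MI"`, `"2WA"`, `"cPC"`, `"cSP"`,
#'   `"cMI"`.
#' @param task `c(positive_type, negative_type)`.
#' @inheritParams dependency_score
#' @return The motif tibble with an added `score` column.
#' @export
pairwise_motif_score <- function(motifs, dataset, measure, task,
                                 binning = NULL, replicate_mean = FALSE) {
  de <- discriminating_edge(task)
  score <- vapply(seq_len(nrow(motifs)), function(i) {
    row <- motifs[i, ]
    ga <- row[[de$edge[1]]]; gb <- row[[de$edge[2]]]
    cg <- row[[de$conditioning]]
    tryCatch(
      de$orientation * dependency_score(dataset, ga, gb, measure,
                                        conditioning_gene = cg,
                                        binning = binning,
                                        replicate_mean = replicate_mean),
      error = function(e) {
        if (grepl("unknown gene", conditionMessage(e))) stop(e)
        NA_real_
      })
  }, numeric(1))
  out <- motifs
  out$score <- score
  out
}
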