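#' Construct an expression dataset
#'
#' Container for a replicated gene-expression experiment: a chips x genes
#' matrix of log2 fold changes together with the condition/replicate
#' structure of the chips and an optional set of genes flagged as
#' transcription factors. Replicates are chips sharing a `condition_id`;
#' time points of a time course are treated as separate conditions.
#'
#' @param values Numeric matrix, chips in rows and genes in columns, with
#'   row names (chip ids) and column names (gene ids). All values must be
#'   finite; missing values are rejected because balanced factorial designs
#'   are required downstream.
#' @param chip_info Data frame with columns `chip_id`, `condition_id` and
#'   `replicate` (integer >= 1). Every row of `values` must have exactly one
#'   metadata row. Extra columns (e.g. `perturbed_gene`, `perturbation_type`)
#'   are carried along.
#' @param tf_genes Character vector of gene ids to flag as transcription
#'   factors. Must be a subset of the column names of `values`. A gene may
#'   be both a TF and a target.
#'
#' @return An object of class `expr_dataset` with elements `values`,
#'   `chips` (a tibble) and `tf_genes`.
#' @export
expr_dataset <- function(values, chip_info, tf_genes = character()) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (chips x genes)", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must have chip ids as row names and gene ids as column names",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) stop("duplicate chip ids", call. = FALSE)
  if (anyDuplicated(colnames(values))) stop("duplicate gene ids", call. = FALSE)
  if (!all(is.finite(values))) {
    stop("expression values must all be finite (missing values are not imputed)",
         call. = FALSE)
  }
  chip_info <- tibble::as_tibble(chip_info)
  required <- c("chip_id", "condition_id", "replicate")
  missing_cols <- setdiff(required, names(chip_info))
  if (length(missing_cols) > 0) {
    stop("chip metadata lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  chip_info$chip_id <- as.character(chip_info$chip_id)
  chip_info$condition_id <- as.character(chip_info$condition_id)
  chip_info$replicate <- as.integer(chip_info$replicate)
  if (anyDuplicated(chip_info$chip_id)) stop("duplicate chip ids in metadata", call. = FALSE)
  orphans <- setdiff(rownames(values), chip_info$chip_id)
  if (length(orphans) > 0) {
    stop("chip(s) without metadata row: ", paste(orphans, collapse = ", "),
         call. = FALSE)
  }
  if (any(is.na(chip_info$replicate)) || any(chip_info$replicate < 1L)) {
    stop("replicate indices must be integers >= 1", call. = FALSE)
  }
  chip_info <- chip_info[match(rownames(values), chip_info$chip_id), , drop = FALSE]
  tf_genes <- unique(as.character(tf_genes))
  unknown_tf <- setdiff(tf_genes, colnames(values))
  if (length(unknown_tf) > 0) {
    stop("tf_genes not in dataset: ", paste(unknown_tf, collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(values = values, chips = chip_info, tf_genes = tf_genes),
    class = "expr_dataset"
  )
}

#' @export
print.expr_dataset <- function(x, ...) {
  cat(sprintf(
    "<expr_dataset> %d chips x %d genes, %d conditions, %d TF(s) flagged\n",
    nrow(x$values), ncol(x$values),
    length(unique(x$chips$condition_id)), length(x$tf_genes)
  ))
  invisible(x)
}

#' @export
dim.expr_dataset <- function(x) dim(x$values)

#' Gene and condition accessors
#'
#' @param dataset An [expr_dataset()].
#' @return Character vectors of gene ids, chip ids or condition ids.
#' @export
genes <- function(dataset) colnames(dataset$values)

#' @rdname genes
#' @export
chips <- function(dataset) rownames(dataset$values)

#' @rdname genes
#' @export
conditions <- function(dataset) unique(dataset$chips$condition_id)

#' Extract one gene's expression profile across chips
#'
#' @param dataset An [expr_dataset()].
#' @param gene A gene id present in the dataset.
#' @return Named numeric vector over chips.
#' @export
gene_profile <- function(dataset, gene) {
  if (!gene %in% colnames(dataset$values)) {
    stop("unknown gene id: ", gene, call. = FALSE)
  }
  dataset$values[, gene]
}

#' Tidy view of an expression dataset
#'
#' @param x An [expr_dataset()].
#' @param ... Unused.
#' @return A tibble with one row per (chip, gene) measurement and columns
#'   `chip_id`, `condition_id`, `replicate`, `gene_id`, `value`, `is_tf`.
#' @importFrom tibble as_tibble
#' @export
as_tibble.expr_dataset <- function(x, ...) {
  long <- tibble::tibble(
    chip_id = rep(rownames(x$values), times = ncol(x$values)),
    gene_id = rep(colnames(x$values), each = nrow(x$values)),
    value = as.vector(x$values)
  )
  long <- dplyr::left_join(long, x$chips, by = "chip_id")
  long$is_tf <- long$gene_id %in% x$tf_genes
  dplyr::select(long, "chip_id", "condition_id", "replicate", "gene_id",
                "value", "is_tf", dplyr::everything())
}

#' Read an expression matrix and chip metadata from TSV files
#'
#' The matrix file has a header row naming the genes and one row per chip
#' (first column `chip_id`). If the first column instead contains gene ids
#' (genes as rows), the matrix is transposed automatically and a message is
#' emitted. The metadata file has columns `chip_id`, `condition_id`,
#' `replicate` and optional perturbation columns.
#'
#' @param matrix_path,metadata_path Paths to the two TSV files.
#' @param tf_genes Optional character vector of TF gene ids.
#' @return An [expr_dataset()].
#' @export
read_expression <- function(matrix_path, metadata_path, tf_genes = character()) {
  meta <- readr::read_tsv(metadata_path, show_col_types = FALSE,
                          progress = FALSE)
  # base strtod parsing is correctly rounded, giving bit-exact round trips
  raw <- utils::read.delim(matrix_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (nrow(raw) == 0) stop("empty expression matrix: ", matrix_path, call. = FALSE)
  first_col <- as.character(raw[[1]])
  meta_chips <- as.character(meta$chip_id)
  values <- as.matrix(raw[, -1, drop = FALSE])
  if (!is.numeric(values)) stop("non-numeric cells in expression matrix", call. = FALSE)
  if (any(first_col %in% meta_chips)) {
    rownames(values) <- first_col
  } else if (any(names(raw)[-1] %in% meta_chips)) {
    message("gene ids found in first column; transposing matrix to chips x genes")
    values <- t(values)
    colnames(values) <- first_col
  } else {
    stop("neither rows nor columns of the matrix match metadata chip ids",
         call. = FALSE)
  }
  expr_dataset(values, meta, tf_genes = tf_genes)
}

#' Write an expression dataset to TSV files
#'
#' Inverse of [read_expression()]; values are written with full (round-trip)
#' precision so that read-after-write reproduces the dataset bit-exactly.
#'
#' @param dataset An [expr_dataset()].
#' @param matrix_path,metadata_path Output paths.
#' @return `dataset`, invisibly.
#' @export
write_expression <- function(dataset, matrix_path, metadata_path) {
  # format values at 17 significant digits so binary doubles round trip
  chr <- apply(dataset$values, 2, function(col) sprintf("%.17g", col))
  tab <- tibble::as_tibble(chr)
  tab <- dplyr::bind_cols(tibble::tibble(chip_id = rownames(dataset$values)), tab)
  readr::write_tsv(tab, matrix_path, progress = FALSE)
  readr::write_tsv(dataset$chips, metadata_path, progress = FALSE)
  invisible(dataset)
}

#' Convert raw log-scale intensities to log fold changes
#'
#' Subtracts, per gene, the mean over the replicates of a reference
#' condition. The reference condition is retained in the output (its
#' post-transformation column means are zero).
#'
#' @param raw An [expr_dataset()] of log-scale intensities.
#' @param reference_condition Condition id to use as baseline.
#' @return An [expr_dataset()] of log fold changes.
#' @export
compute_log_fold_change <- function(raw, reference_condition) {
  ref_chips <- raw$chips$chip_id[raw$chips$condition_id == reference_condition]
  if (length(ref_chips) == 0) {
    stop("reference condition not present: ", reference_condition, call. = FALSE)
  }
  ref_means <- colMeans(raw$values[ref_chips, , drop = FALSE])
  out <- raw
  out$values <- sweep(raw$values, 2, ref_means, "-")
  out
}

#' Read a directed regulatory network from a TSV edge list
#'
#' Accepts the DREAM5 gold-standard dialect: two or three tab-separated
#' columns `regulator`, `target` and an optional third column that is either
#' a sign (`+`/`-`) or a 0/1 flag (rows flagged 0 are dropped; 1 or absent
#' means an edge of unknown sign). A header row is detected and skipped.
#' Duplicate edges are collapsed with a warning; self-loops are kept but
#' flagged (motif enumeration ignores them).
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `regulator`, `target`, `sign` (one of
#'   `"activating"`, `"repressing"`, `"unknown"`) and `self_loop`.
#' @export
read_network <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty network file: ", path, call. = FALSE)
  if (grepl("^regulator\\b", lines[[1]], ignore.case = TRUE)) {
    lines <- lines[-1]
    if (length(lines) == 0) stop("network file has a header but no edges", call. = FALSE)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_fields <- lengths(fields)
  bad <- which(n_fields < 2 | n_fields > 3)
  if (length(bad) > 0) {
    stop("malformed network row(s) at line(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  edges <- tibble::tibble(
    regulator = vapply(fields, `[[`, character(1), 1),
    target = vapply(fields, `[[`, character(1), 2),
    flag = vapply(fields, function(f) if (length(f) >= 3) f[[3]] else "1",
                  character(1))
  )
  ok_flags <- c("+", "-", "0", "1")
  if (!all(edges$flag %in% ok_flags)) {
    stop("third network column must be one of +, -, 0, 1", call. = FALSE)
  }
  edges <- edges[edges$flag != "0", , drop = FALSE]
  edges$sign <- dplyr::case_match(edges$flag,
    "+" ~ "activating", "-" ~ "repressing", .default = "unknown")
  edges$flag <- NULL
  n_before <- nrow(edges)
  edges <- dplyr::distinct(edges, .data$regulator, .data$target,
                           .keep_all = TRUE)
  if (nrow(edges) < n_before) {
    warning(sprintf("%d duplicate edge row(s) collapsed", n_before - nrow(edges)),
            call. = FALSE)
  }
  edges$self_loop <- edges$regulator == edges$target
  edges
}

#' Write a regulatory network as a TSV edge list
#'
#' @param network Tibble as returned by [read_network()] (columns
#'   `regulator`, `target`, optional `sign`).
#' @param path Output path.
#' @return `network`, invisibly.
#' @export
write_network <- function(network, path) {
  sign <- if ("sign" %in% names(network)) network$sign else rep("unknown", nrow(network))
  flag <- dplyr::case_match(sign, "activating" ~ "+", "repressing" ~ "-",
                            .default = "1")
  out <- tibble::tibble(regulator = network$regulator, target = network$target,
                        sign_or_flag = flag)
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(network)
}

#' Read and write motif score tables
#'
#' A score table has one row per (identifier, method, task) with a finite or
#' missing score. [write_score_table()] emits rows in a deterministic order
#' (sorted by identifier, then method, then task) so identical tables give
#' byte-identical files.
#'
#' @param table Tibble with columns `identifier`, `method`, `task`, `score`.
#' @param path File path.
#' @return The (sorted) tibble; [write_score_table()] returns it invisibly.
#' @export
write_score_table <- function(table, path) {
  required <- c("identifier", "method", "task", "score")
  if (!all(required %in% names(table))) {
    stop("score table needs columns: ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  key <- table[, c("identifier", "method", "task")]
  if (anyDuplicated(key)) {
    stop("score table has duplicate (identifier, method, task) rows", call. = FALSE)
  }
  out <- dplyr::arrange(tibble::as_tibble(table[required]),
                        .data$identifier, .data$method, .data$task)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(out)
}

#' @rdname write_score_table
#' @export
read_score_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(
                    identifier = readr::col_character(),
                    method = readr::col_character(),
                    task = readr::col_character(),
                    score = readr::col_double()
                  ))
}
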