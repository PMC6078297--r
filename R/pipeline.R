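ALL_METHODS <- c("PC", "SP", "MI", "2WA", "cPC", "cSP", "cMI", "3WA")
DEFAULT_TASKS <- list(c("DOR", "CSC"), c("CSC", "FFL"), c("FFL", "DOR"))

task_id <- function(task) paste(task, collapse = "_vs_")

#' Benchmark run configuration
#'
#' Either `sim` (a [sim_config()]) for a fully simulated run, or the three
#' input paths for expression matrix, chip metadata and gold-standard
#' network. Tasks are pairs `c(positive_type, negative_type)`; `formula`
#' is `"cv"` (cross-validated selection per task) or a named list of
#' serialized term formulas keyed by task id (e.g. `"DOR_vs_CSC"`).
#'
#' @param sim Optional [sim_config()].
#' @param matrix_path,metadata_path,network_path Input TSVs (ignored when
#'   `sim` is given).
#' @param tasks List of task pairs (default: DOR vs CSC, CSC vs FFL,
#'   FFL vs DOR).
#' @param methods Methods to run (subset of PC, SP, MI, 2WA, cPC, cSP, cMI,
#'   3WA).
#' @param formula `"cv"` or named list of formula strings per task id.
#' @param folds CV folds for formula selection (default 3).
#' @param seed Integer seed governing every random choice of the run.
#' @param output_dir Directory for score tables and the report.
#' @return List of class `run_config`.
#' @export
run_config <- function(sim = NULL, matrix_path = NULL, metadata_path = NULL,
                       network_path = NULL, tasks = DEFAULT_TASKS,
                       methods = ALL_METHODS, formula = "cv", folds = 3,
                       seed = 0L, output_dir = tempfile("benchmark")) {
  if (length(tasks) == 0) stop("tasks must be non-empty", call. = FALSE)
  methods <- match.arg(methods, ALL_METHODS, several.ok = TRUE)
  if (is.null(sim) && (is.null(matrix_path) || is.null(metadata_path) ||
                       is.null(network_path))) {
    stop("provide either `sim` or all three input paths", call. = FALSE)
  }
  if (is.list(formula)) {
    lapply(formula, parse_formula)  # must parse
  } else if (!identical(formula, "cv")) {
    stop('`formula` must be "cv" or a named list of formula strings', call. = FALSE)
  }
  structure(list(sim = sim, matrix_path = matrix_path,
                 metadata_path = metadata_path, network_path = network_path,
                 tasks = tasks, methods = methods, formula = formula,
                 folds = folds, seed = as.integer(seed),
                 output_dir = output_dir),
            class = "run_config")
}

#' Run the full motif-classification benchmark
#'
#' Orchestrates simulate/load, motif enumeration, scoring with every
#' requested method, and AUROC/AUPR evaluation per task. Score tables and
#' the evaluation report (`task`, `method`, `auroc`, `aupr`, `n_pos`,
#' `n_neg`) are written as TSVs into the output directory; for 3WA with
#' `formula = "cv"`, the selected formula and its CV AUROC are written to
#' `formulas.tsv` and logged. Fully reproducible under the config seed. Any
#' stage error removes partial outputs and aborts with a stage-named
#' message.
#'
#' @param config A [run_config()].
#' @return The evaluation-report tibble, invisibly carrying attribute
#'   `formulas` (3WA formula choices) and `output_dir`.
#' @export
run_benchmark <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  fail <- function(stage, e) {
    file.remove(written[file.exists(written)])
    stop(sprintf("benchmark stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  }
  inputs <- tryCatch({
    if (!is.null(config$sim)) {
      sim <- simulate_grn(config$sim)
      list(dataset = sim$dataset, network = sim$network, motifs = sim$motifs)
    } else {
      dataset <- read_expression(config$matrix_path, config$metadata_path)
      network <- read_network(config$network_path)
      list(dataset = dataset, network = network,
           motifs = enumerate_motifs(network))
    }
  }, error = function(e) fail("input", e))

  report <- NULL
  formulas <- NULL
  for (task in config$tasks) {
    tid <- task_id(task)
    keep <- inputs$motifs$motif_type %in% task
    task_motifs <- inputs$motifs[keep, , drop = FALSE]
    labels <- as.integer(task_motifs$motif_type == task[1])
    if (sum(labels) == 0 || sum(labels) == length(labels)) {
      fail("scoring", simpleError(sprintf("task %s: both motif classes required", tid)))
    }
    for (method in config$methods) {
      scored <- tryCatch({
        if (method == "3WA") {
          if (identical(config$formula, "cv")) {
            fit <- cross_validated_selection(inputs$dataset, task_motifs, task,
                                             folds = config$folds,
                                             seed = config$seed)
            message(sprintf("task %s: selected %s (CV AUROC %.3f)", tid,
                            format_formula(fit$formula), fit$cv_auroc))
            formulas <- dplyr::bind_rows(formulas, glance(fit))
            f <- fit$formula
          } else {
            f <- parse_formula(config$formula[[tid]])
          }
          tab <- rank_motifs(inputs$dataset, task_motifs, f, task)
          # restore motif order for label alignment
          tab[match(motif_id(task_motifs), tab$identifier), ]
        } else {
          s <- pairwise_motif_score(task_motifs, inputs$dataset, method, task)
          tibble::tibble(identifier = motif_id(s), method = method, task = tid,
                         score = s$score)
        }
      }, error = function(e) fail(sprintf("scoring %s/%s", tid, method), e))
      n_missing <- sum(is.na(scored$score))
      if (n_missing > 0) {
        message(sprintf("task %s method %s: %d missing score(s) ranked last",
                        tid, method, n_missing))
      }
      s <- scored$score
      s[is.na(s)] <- -Inf
      row <- tryCatch(
        tibble::tibble(task = tid, method = method,
                       auroc = auroc(s, labels), aupr = aupr(s, labels),
                       n_pos = sum(labels), n_neg = sum(labels == 0)),
        error = function(e) fail(sprintf("evaluation %s/%s", tid, method), e))
      report <- dplyr::bind_rows(report, row)
      path <- file.path(config$output_dir,
                        sprintf("scores_%s_%s.tsv", tid, method))
      write_score_table(scored, path)
      written <- c(written, path)
    }
  }
  report_path <- file.path(config$output_dir, "report.tsv")
  readr::write_tsv(report, report_path, progress = FALSE)
  if (!is.null(formulas)) {
    readr::write_tsv(formulas, file.path(config$output_dir, "formulas.tsv"),
                     progress = FALSE)
  }
  attr(report, "formulas") <- formulas
  attr(report, "output_dir") <- config$output_dir
  invisible(report)
}
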