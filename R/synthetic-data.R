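# Saturating response primitives. Single-regulator responses use tanh;
# two-regulator targets use an AND-like product of sigmoidal activations so
# that the target genuinely depends jointly on both TFs.
sat_response <- function(u, strength, sign = 1) tanh(sign * strength * u)
sig01 <- function(u) (1 + tanh(u)) / 2
# Two-regulator AND gate: product of sigmoidal activations, rescaled to a
# dynamic range comparable to the single-regulator tanh response.
and_response <- function(u1, u2, k1, k2, s1 = 1, s2 = 1, amplitude = 2) {
  amplitude * (2 * sig01(s1 * k1 * u1) * sig01(s2 * k2 * u2) - 1)
}

toy_chip_meta <- function(n_conditions, n_replicates) {
  tibble::tibble(
    chip_id = paste0("chip", sprintf("%03d", seq_len(n_conditions * n_replicates))),
    condition_id = rep(paste0("cond", sprintf("%03d", seq_len(n_conditions))),
                       each = n_replicates),
    replicate = rep(seq_len(n_replicates), times = n_conditions)
  )
}

toy_assemble <- function(cond_mat, n_replicates, noise_sd) {
  n_conditions <- nrow(cond_mat)
  meta <- toy_chip_meta(n_conditions, n_replicates)
  vals <- cond_mat[rep(seq_len(n_conditions), each = n_replicates), , drop = FALSE]
  vals <- vals + matrix(stats::rnorm(length(vals), 0, noise_sd),
                        nrow = nrow(vals))
  rownames(vals) <- meta$chip_id
  expr_dataset(vals, meta, tf_genes = c("tf_x", "tf_y"))
}

#' Four toy three-gene datasets
#'
#' Small designed datasets that exhibit the characteristic expression
#' patterns of the three motif types, plus a fully correlated control:
#'
#' * `correlated` — all three genes follow one shared condition signal.
#' * `csc` — `tf_y` follows the latent signal, `tf_x = alpha * tf_y` plus
#'   condition-level stage noise, `tg_z = alpha * tf_x` plus stage noise
#'   (a regulator chain with attenuation at each stage).
#' * `dor` — `tf_x` and `tf_y` follow two orthogonal condition signals and
#'   `tg_z` responds AND-like (product of sigmoidal activations) to both.
#' * `ffl` — `tf_y` latent, `tf_x = alpha * tf_y` plus stage noise, `tg_z`
#'   AND-like in both TFs.
#'
#' The latent signal is a deterministic induction gradient across
#' conditions (0 to 2, so the regulated genes have non-zero mean response);
#' stage noise and replicate noise are i.i.d. Gaussian under `seed`. All
#' values are on the log-fold-change scale.
#'
#' @param n_conditions Number of conditions (>= 4; default 50).
#' @param n_replicates Replicates per condition (default 3).
#' @param noise_sd Standard deviation of both the condition-level stage
#'   noise and the replicate noise (default 0.3).
#' @param alpha Chain transmission coefficient (default 0.8).
#' @param strength Saturating-response slope for AND-like targets
#'   (default 1.2).
#' @param seed Integer seed.
#' @return Named list of four [expr_dataset()]s: `correlated`, `csc`,
#'   `dor`, `ffl`.
#' @export
toy_datasets <- function(n_conditions = 50, n_replicates = 3, noise_sd = 0.3,
                         alpha = 0.8, strength = 1.2, seed = 0L) {
  if (n_conditions < 4) stop("need at least 4 conditions", call. = FALSE)
  with_preserved_seed(seed, {
    cc <- seq_len(n_conditions)
    latent <- seq(0, 2, length.out = n_conditions)
    ortho <- 1 + cos(2 * pi * (cc - 1) / n_conditions)
    stage <- function() stats::rnorm(n_conditions, 0, noise_sd)

    m_corr <- cbind(tf_x = latent, tf_y = latent, tg_z = latent)

    y_csc <- latent
    x_csc <- alpha * y_csc + stage()
    z_csc <- alpha * x_csc + stage()
    m_csc <- cbind(tf_x = x_csc, tf_y = y_csc, tg_z = z_csc)

    x_dor <- latent + stage()
    y_dor <- ortho + stage()
    z_dor <- and_response(x_dor, y_dor, strength, strength) + stage()
    m_dor <- cbind(tf_x = x_dor, tf_y = y_dor, tg_z = z_dor)

    y_ffl <- latent
    x_ffl <- alpha * y_ffl + stage()
    z_ffl <- and_response(x_ffl, y_ffl, strength, strength) + stage()
    m_ffl <- cbind(tf_x = x_ffl, tf_y = y_ffl, tg_z = z_ffl)

    list(correlated = toy_assemble(m_corr, n_replicates, noise_sd),
         csc = toy_assemble(m_csc, n_replicates, noise_sd),
         dor = toy_assemble(m_dor, n_replicates, noise_sd),
         ffl = toy_assemble(m_ffl, n_replicates, noise_sd))
  })
}

#' Simulation configuration
#'
#' Bundles the parameters of [simulate_grn()] with regime presets. The
#' `artificial_like` regime emulates clean simulated benchmark data: strong
#' edges, little noise, no confounding, so true edges are strongly enriched
#' for high absolute correlation. The `real_like` regime emulates real
#' compendia: latent confounding inputs to every gene, inflated
#' condition-level and replicate noise, and a positive shift of the
#' correlation distribution, so that true-edge and random-pair correlation
#' distributions largely overlap.
#'
#' @param regime `"artificial_like"` or `"real_like"`.
#' @param n_motifs Named counts per motif type (`CSC`, `FFL`, `DOR`).
#' @param n_background_genes Unregulated background genes (default 50).
#' @param n_conditions,n_replicates Design size (defaults 100 x 3).
#' @param edge_strength Range of saturating-response slopes sampled per
#'   edge (default `c(0.8, 1.5)`).
#' @param replicate_noise_sd I.i.d. Gaussian noise per chip; regime default
#'   0.1 (artificial-like) or 0.8 (real-like).
#' @param stage_noise_sd Condition-level noise added to every regulated
#'   gene; regime default 0.3 or 0.7.
#' @param confounder_strength Std. dev. of per-gene loadings on
#'   `n_confounders` latent condition factors; regime default 0 or 0.7.
#' @param n_confounders Number of latent confounding factors (default 3).
#' @param tf_activity_sd Std. dev. of the hidden post-transcriptional
#'   component of TF activity: regulation propagates TF activities
#'   (mRNA + hidden component) while chips measure only mRNA, so TF:TF
#'   mRNA correlations are suppressed relative to the functional coupling;
#'   regime default 0 (artificial-like) or 1.8 (real-like).
#' @param positive_shift Loading of every gene on one shared positive
#'   factor (shifts pairwise correlations toward positive values); regime
#'   default 0 or 0.1.
#' @param repression_fraction Fraction of edges drawn as repressing
#'   (default 0.2).
#' @param seed Integer seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(regime = c("artificial_like", "real_like"),
                       n_motifs = c(CSC = 100, FFL = 100, DOR = 100),
                       n_background_genes = 50,
                       n_conditions = 100, n_replicates = 3,
                       edge_strength = c(0.8, 1.5),
                       replicate_noise_sd = NULL,
                       stage_noise_sd = NULL,
                       confounder_strength = NULL,
                       n_confounders = 3,
                       tf_activity_sd = NULL,
                       positive_shift = NULL,
                       repression_fraction = 0.2,
                       seed = 0L) {
  regime <- match.arg(regime)
  real <- regime == "real_like"
  cfg <- list(
    regime = regime,
    n_motifs = n_motifs,
    n_background_genes = n_background_genes,
    n_conditions = n_conditions,
    n_replicates = n_replicates,
    edge_strength = edge_strength,
    replicate_noise_sd = replicate_noise_sd %||% if (real) 0.8 else 0.1,
    stage_noise_sd = stage_noise_sd %||% if (real) 0.7 else 0.3,
    confounder_strength = confounder_strength %||% if (real) 0.7 else 0,
    n_confounders = n_confounders,
    tf_activity_sd = tf_activity_sd %||% if (real) 1.8 else 0,
    positive_shift = positive_shift %||% if (real) 0.1 else 0,
    repression_fraction = repression_fraction,
    seed = seed
  )
  stopifnot(all(cfg$n_motifs >= 0), cfg$n_conditions >= 2, cfg$n_replicates >= 1,
            cfg$replicate_noise_sd >= 0, cfg$stage_noise_sd >= 0,
            cfg$repression_fraction >= 0, cfg$repression_fraction <= 1)
  if (!all(c("CSC", "FFL", "DOR") %in% names(cfg$n_motifs))) {
    stop("n_motifs must be named with CSC, FFL, DOR", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a regulatory network with embedded labeled motifs
#'
#' Builds disjoint CSC, FFL and DOR gene triples plus unregulated
#' background genes and simulates steady-state log-fold-change expression:
#' each condition draws fresh root-TF activities (conditions act as
#' perturbations), downstream genes respond through saturating transforms
#' of their regulator (AND-like product of sigmoidal activations at
#' two-regulator targets), a `repression_fraction` of edges acts with
#' negative sign, and the real-like regime adds latent confounding factors,
#' a shared positive-shift factor and inflated noise. Replicates add i.i.d.
#' Gaussian noise; per-gene condition profiles are centered so values are
#' log-fold-change-like.
#'
#' @param config A [sim_config()].
#' @return List with elements `network` (signed edge-list tibble),
#'   `dataset` (an [expr_dataset()]) and `motifs` (labeled motif tibble
#'   consistent with [enumerate_motifs()] on `network`).
#' @export
simulate_grn <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  nm <- config$n_motifs
  ids <- function(type, n, role) {
    if (n == 0) return(character(0))
    paste0(type, sprintf("%03d", seq_len(n)), "_", role)
  }
  motifs <- dplyr::bind_rows(lapply(c("CSC", "FFL", "DOR"), function(t) {
    n <- nm[[t]]
    tibble::tibble(motif_type = t, tf_x = ids(t, n, "x"), tf_y = ids(t, n, "y"),
                   tg_z = ids(t, n, "z"))
  }))
  background <- if (config$n_background_genes > 0) {
    paste0("bg", sprintf("%03d", seq_len(config$n_background_genes)))
  } else character(0)
  gene_ids <- c(rbind(motifs$tf_x, motifs$tf_y, motifs$tg_z), background)
  if (anyDuplicated(gene_ids)) stop("gene identifiers collide", call. = FALSE)

  edges <- dplyr::bind_rows(
    tibble::tibble(regulator = motifs$tf_y[motifs$motif_type != "DOR"],
                   target = motifs$tf_x[motifs$motif_type != "DOR"]),
    tibble::tibble(regulator = motifs$tf_x, target = motifs$tg_z),
    tibble::tibble(regulator = motifs$tf_y[motifs$motif_type != "CSC"],
                   target = motifs$tg_z[motifs$motif_type != "CSC"])
  )

  n_c <- config$n_conditions
  n_genes <- length(gene_ids)
  with_preserved_seed(config$seed, {
    edges$strength <- stats::runif(nrow(edges), config$edge_strength[1],
                                   config$edge_strength[2])
    edges$sign_num <- ifelse(stats::runif(nrow(edges)) < config$repression_fraction,
                             -1, 1)
    estr <- function(r, t) {
      i <- which(edges$regulator == r & edges$target == t)
      c(edges$strength[i], edges$sign_num[i])
    }
    cond_expr <- matrix(0, nrow = n_c, ncol = n_genes,
                        dimnames = list(NULL, gene_ids))
    stage <- function() stats::rnorm(n_c, 0, config$stage_noise_sd)
    for (g in background) cond_expr[, g] <- stats::rnorm(n_c)
    pt <- function() stats::rnorm(n_c, 0, config$tf_activity_sd)
    for (i in seq_len(nrow(motifs))) {
      t <- motifs$motif_type[i]
      gx <- motifs$tf_x[i]; gy <- motifs$tf_y[i]; gz <- motifs$tg_z[i]
      # regulation acts through TF activities (mRNA plus a hidden
      # post-transcriptional component); chips measure only the mRNA
      if (t == "DOR") {
        x <- stats::rnorm(n_c); y <- stats::rnorm(n_c)
        y_act <- y + pt()
      } else {
        y <- stats::rnorm(n_c)
        y_act <- y + pt()
        e_yx <- estr(gy, gx)
        x <- sat_response(y_act, e_yx[1], e_yx[2]) + stage()
      }
      x_act <- x + pt()
      if (t == "CSC") {
        e_xz <- estr(gx, gz)
        z <- sat_response(x_act, e_xz[1], e_xz[2]) + stage()
      } else {
        e_xz <- estr(gx, gz); e_yz <- estr(gy, gz)
        z <- and_response(x_act, y_act, e_xz[1], e_yz[1], e_xz[2], e_yz[2]) + stage()
      }
      cond_expr[, gx] <- x; cond_expr[, gy] <- y; cond_expr[, gz] <- z
    }
    if (config$confounder_strength > 0) {
      fac <- matrix(stats::rnorm(n_c * config$n_confounders), nrow = n_c)
      load <- matrix(stats::rnorm(n_genes * config$n_confounders,
                                  0, config$confounder_strength),
                     ncol = config$n_confounders)
      cond_expr <- cond_expr + fac %*% t(load)
    }
    if (config$positive_shift > 0) {
      shared <- stats::rnorm(n_c)
      cond_expr <- cond_expr + config$positive_shift * shared
    }
    cond_expr <- sweep(cond_expr, 2, colMeans(cond_expr), "-")
    meta <- toy_chip_meta(n_c, config$n_replicates)
    vals <- cond_expr[rep(seq_len(n_c), each = config$n_replicates), , drop = FALSE]
    vals <- vals + matrix(stats::rnorm(length(vals), 0, config$replicate_noise_sd),
                          nrow = nrow(vals))
    rownames(vals) <- meta$chip_id
    tf_genes <- unique(edges$regulator)
    dataset <- expr_dataset(vals, meta, tf_genes = tf_genes)
  })
  network <- tibble::tibble(
    regulator = edges$regulator, target = edges$target,
    sign = ifelse(edges$sign_num < 0, "repressing", "activating"),
    self_loop = FALSE
  )
  list(network = network, dataset = dataset, motifs = motifs)
}
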