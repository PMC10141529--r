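#' Configuration for the synthetic single-cell reference
#'
#' Defines the generative model the simulator draws from: per-gene base
#' means on a log10-uniform grid, multiplicative lognormal subject effects
#' (the cross-subject variation the gene weights target), planted marker
#' genes up-regulated `marker_fold`-fold in their own cluster, and
#' negative-binomial counts (size `nb_dispersion`; large size approaches
#' Poisson).
#'
#' @param n_genes,n_clusters,n_subjects,cells_per_cluster_per_subject
#'   Dimensions of the reference.
#' @param markers_per_cluster Planted markers per cluster (disjoint sets).
#' @param marker_fold Fold-change of a planted marker in its cluster (> 1
#'   plants signal; exactly 1 is the null with no signal).
#' @param nb_dispersion Negative-binomial size parameter (> 0).
#' @param base_mean_log_range Length-2 range of log10 base mean expression.
#' @param subject_effect_sd SD of the per-(gene, subject) lognormal effect.
#' @param cell_noise_sd SD of an extra per-cell lognormal scaling (0 = none).
#' @param seed Integer seed; the whole reference is deterministic under it.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 2000, n_clusters = 9, n_subjects = 4,
                              cells_per_cluster_per_subject = 50,
                              markers_per_cluster = 30, marker_fold = 8,
                              nb_dispersion = 2,
                              base_mean_log_range = c(-1, 2),
                              subject_effect_sd = 0.3, cell_noise_sd = 0,
                              seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_clusters = as.integer(n_clusters),
              n_subjects = as.integer(n_subjects),
              cells_per_cluster_per_subject =
                as.integer(cells_per_cluster_per_subject),
              markers_per_cluster = as.integer(markers_per_cluster),
              marker_fold = as.numeric(marker_fold),
              nb_dispersion = as.numeric(nb_dispersion),
              base_mean_log_range = as.numeric(base_mean_log_range),
              subject_effect_sd = as.numeric(subject_effect_sd),
              cell_noise_sd = as.numeric(cell_noise_sd),
              seed = as.integer(seed))
  with(cfg, {
    if (any(c(n_genes, n_clusters, n_subjects, cells_per_cluster_per_subject,
              markers_per_cluster) < 1))
      stop("all dimensions must be >= 1")
    if (markers_per_cluster * n_clusters > n_genes)
      stop("markers_per_cluster * n_clusters must not exceed n_genes")
    if (marker_fold < 1) stop("marker_fold must be >= 1")
    if (nb_dispersion <= 0) stop("nb_dispersion must be positive")
    if (length(base_mean_log_range) != 2 ||
        base_mean_log_range[1] > base_mean_log_range[2])
      stop("base_mean_log_range must be an increasing length-2 range")
    if (subject_effect_sd < 0 || cell_noise_sd < 0)
      stop("noise SDs must be non-negative")
  })
  structure(cfg, class = "simulation_config")
}

#' Simulate a multi-subject single-cell reference with planted markers
#'
#' Draws a negative-binomial cells x genes count matrix under the model of
#' [simulation_config()]: gene base means are log10-uniform, every
#' (gene, subject) pair carries a lognormal multiplicative effect, each
#' cluster's planted markers are multiplied by `marker_fold` in that cluster
#' only, and counts are NB(mean, size = nb_dispersion). The planted marker
#' ledger is attached so recovery can be scored.
#'
#' @param cfg A [simulation_config()].
#' @return An [sc_reference()] with attributes `planted_markers` (named list
#'   cluster -> gene ids), `config`, and `tree` (a default two-level
#'   [cluster_tree()], see [default_tree()]).
#' @export
simulate_reference <- function(cfg = simulation_config()) {
  stopifnot(inherits(cfg, "simulation_config"))
  restore <- .Random.seed_guard(cfg$seed)
  on.exit(restore(), add = TRUE)

  genes <- sprintf("g%04d", seq_len(cfg$n_genes))
  clusters <- sprintf("C%d", seq_len(cfg$n_clusters))
  subjects <- sprintf("S%d", seq_len(cfg$n_subjects))

  base_mean <- 10^stats::runif(cfg$n_genes, cfg$base_mean_log_range[1],
                               cfg$base_mean_log_range[2])
  marker_pool <- sample(genes, cfg$markers_per_cluster * cfg$n_clusters)
  planted <- split(marker_pool,
                   rep(clusters, each = cfg$markers_per_cluster))[clusters]
  subj_eff <- matrix(exp(stats::rnorm(cfg$n_genes * cfg$n_subjects, 0,
                                      cfg$subject_effect_sd)),
                     cfg$n_genes, cfg$n_subjects,
                     dimnames = list(genes, subjects))

  n_cells <- cfg$n_clusters * cfg$n_subjects * cfg$cells_per_cluster_per_subject
  counts <- matrix(0, n_cells, cfg$n_genes)
  cell_cluster <- character(n_cells)
  cell_subject <- character(n_cells)
  row <- 0L
  for (k in clusters) {
    fold <- rep(1, cfg$n_genes)
    fold[match(planted[[k]], genes)] <- cfg$marker_fold
    for (s in subjects) {
      mu_base <- base_mean * subj_eff[, s] * fold
      for (i in seq_len(cfg$cells_per_cluster_per_subject)) {
        row <- row + 1L
        mu <- mu_base
        if (cfg$cell_noise_sd > 0)
          mu <- mu * exp(stats::rnorm(1, 0, cfg$cell_noise_sd))
        counts[row, ] <- stats::rnbinom(cfg$n_genes, mu = mu,
                                        size = cfg$nb_dispersion)
        cell_cluster[row] <- k
        cell_subject[row] <- s
      }
    }
  }
  dimnames(counts) <- list(sprintf("cell%05d", seq_len(n_cells)), genes)
  ref <- sc_reference(counts, cell_cluster, cell_subject)
  attr(ref, "planted_markers") <- planted
  attr(ref, "config") <- cfg
  attr(ref, "tree") <- default_tree(clusters)
  ref
}

#' Default two-level tree over cluster labels
#'
#' For 9 clusters the groups have sizes 4, 3 and 2, mirroring a reference
#' with four tumor subtype clusters plus two groups of normal epithelial
#' subtypes; other cluster counts are split into up to three contiguous,
#' near-equal groups.
#'
#' @param cluster_labels Character vector of cluster labels.
#' @return A [cluster_tree()].
#' @export
default_tree <- function(cluster_labels) {
  K <- length(cluster_labels)
  sizes <- if (K == 9) c(4, 3, 2) else {
    ng <- min(3, K)
    d <- diff(round(seq(0, K, length.out = ng + 1)))
    d[d > 0]
  }
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1
  groups <- lapply(seq_along(sizes),
                   function(i) cluster_labels[starts[i]:ends[i]])
  names(groups) <- paste0("G", seq_along(groups))
  cluster_tree(groups)
}

# Dirichlet draws via normalized gamma variates; rows on the simplex
rdirichlet_mat <- function(n, alpha) {
  K <- length(alpha)
  x <- matrix(stats::rgamma(n * K, shape = alpha, rate = 1), n, K,
              byrow = TRUE)
  zero <- rowSums(x) == 0  # numerically possible for tiny alpha
  if (any(zero)) x[zero, ] <- 1
  x / rowSums(x)
}

#' Simulate pseudo-bulk mixtures with known proportions
#'
#' Draws per-sample cell-type proportions from a Dirichlet distribution and
#' builds bulk profiles either as exact linear mixtures of the reference
#' cluster mean-CPM profiles (`mode = "exact"`, the noiseless identity
#' Y = B_full P used as the fidelity benchmark) or by sampling and summing
#' real cells (`mode = "cells"`, which adds sampling noise and — when
#' restricted to a held-out subject — cross-subject shift).
#'
#' @param ref An [sc_reference()].
#' @param n_samples Number of pseudo-bulk samples.
#' @param mode `"exact"` or `"cells"`.
#' @param dirichlet_alpha Dirichlet concentration; scalar (recycled) or one
#'   value per cluster.
#' @param cells_per_sample Cells drawn per sample in `"cells"` mode.
#' @param subjects Optional subject labels to draw cells from (e.g. a
#'   held-out subject); default all subjects.
#' @param seed Integer seed.
#' @return A list of class `pseudobulk`: `bulk` (genes x samples matrix),
#'   `true_proportions` (clusters x samples, columns on the simplex),
#'   `mode`, `seed`.
#' @export
simulate_pseudobulk <- function(ref, n_samples = 20,
                                mode = c("exact", "cells"),
                                dirichlet_alpha = 1, cells_per_sample = 500,
                                subjects = NULL, seed = 1L) {
  stopifnot(inherits(ref, "sc_reference"))
  mode <- match.arg(mode)
  K <- length(ref$cluster_levels)
  alpha <- rep_len(dirichlet_alpha, K)
  stopifnot(all(alpha > 0), n_samples >= 1)

  restore <- .Random.seed_guard(as.integer(seed))
  on.exit(restore(), add = TRUE)

  P <- t(rdirichlet_mat(n_samples, alpha))
  dimnames(P) <- list(ref$cluster_levels,
                      sprintf("pb%03d", seq_len(n_samples)))

  if (mode == "exact") {
    profiles <- cluster_profiles(ref)$profiles  # clusters x genes
    bulk <- t(profiles) %*% P                   # genes x samples
  } else {
    if (is.null(subjects)) subjects <- unique(ref$subjects)
    eligible <- split(which(ref$subjects %in% subjects),
                      ref$clusters[ref$subjects %in% subjects])
    empty <- setdiff(ref$cluster_levels, names(eligible))
    if (length(empty) > 0)
      stop("no eligible cells for cluster(s): ",
           paste(empty, collapse = ", "))
    bulk <- matrix(0, length(ref$gene_ids), n_samples,
                   dimnames = list(ref$gene_ids, colnames(P)))
    for (m in seq_len(n_samples)) {
      n_k <- stats::rmultinom(1, cells_per_sample, P[, m])[, 1]
      total <- numeric(length(ref$gene_ids))
      for (k in ref$cluster_levels) {
        if (n_k[k] == 0) next
        picks <- sample(eligible[[k]], n_k[k], replace = TRUE)
        total <- total + colSums(ref$counts[picks, , drop = FALSE])
      }
      bulk[, m] <- total
    }
    bulk <- normalize_cpm(bulk)
  }
  structure(list(bulk = bulk, true_proportions = P, mode = mode,
                 seed = as.integer(seed)),
            class = "pseudobulk")
}

#' Grid search over marker-selection parameters on pseudo-bulk data
#'
#' For every combination of `n_b`, `n_bs`, `n_min`, `n_max`: selects markers,
#' builds the (tree-guided) signatures, deconvolves a fixed pseudo-bulk set,
#' and records the recovery metrics. The best point maximizes the Pearson
#' correlation with the true proportions; ties go to the smaller residual
#' sum, then to the smaller (`n_bs`, `n_max`).
#'
#' @param ref An [sc_reference()].
#' @param pb A [simulate_pseudobulk()] dataset (the fixed tuning substrate).
#' @param grid Data frame or tibble with columns `n_b`, `n_bs`, `n_min`,
#'   `n_max` (one row per grid point), e.g. from `expand.grid()`.
#' @param tree Optional [cluster_tree()]; defaults to the reference's
#'   attached tree, or a flat fit when none exists.
#' @param seed Seed passed to each marker-selection run.
#' @return A tibble of class `tuning_result` with the grid columns plus
#'   `pearson_r`, `residual_sum`, `total_deviance`, `n_markers`; the winning
#'   row index is in the `best` attribute.
#' @export
tune_parameters <- function(ref, pb, grid, tree = attr(ref, "tree"),
                            seed = 1L) {
  stopifnot(inherits(ref, "sc_reference"), inherits(pb, "pseudobulk"))
  grid <- tibble::as_tibble(grid)
  stopifnot(all(c("n_b", "n_bs", "n_min", "n_max") %in% names(grid)),
            nrow(grid) > 0)
  profiles <- cluster_profiles(ref)

  rows <- purrr::pmap(grid, function(n_b, n_bs, n_min, n_max, ...) {
    cfg <- marker_config(n_b = n_b, n_bs = n_bs, n_min = n_min,
                         n_max = n_max, seed = seed)
    markers <- select_all_markers(ref, cfg)
    sig <- build_signature(ref, markers, profiles = profiles)
    gsig <- if (!is.null(tree)) group_signature(sig, ref, tree) else NULL
    est <- tree_deconvolve(pb$bulk, sig, tree, gsig)
    metrics <- evaluate_recovery(est, pb$true_proportions)
    tibble::tibble(n_b = n_b, n_bs = n_bs, n_min = n_min, n_max = n_max,
                   pearson_r = metrics$pearson_r,
                   residual_sum = metrics$residual_sum,
                   total_deviance = metrics$total_deviance,
                   n_markers = length(sig$gene_ids))
  })
  out <- dplyr::bind_rows(rows)
  best <- order(-out$pearson_r, out$residual_sum, out$n_bs, out$n_max)[1]
  structure(out, class = c("tuning_result", class(out)), best = best)
}
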