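#' Marker-selection configuration
#'
#' Bundles the tunable parameters of the bootstrap marker-selection stage.
#' Defaults are the values tuned on pseudo-bulk data: 4 background clusters
#' per bootstrap, 100 bootstrap repetitions, and between 28 and 35 markers
#' per cluster.
#'
#' @param n_b Background clusters drawn per bootstrap (must be <= K - 1).
#' @param n_bs Number of bootstrap repetitions.
#' @param n_min,n_max Lower/upper bound on markers retained per cluster
#'   (before cross-cluster deduplication).
#' @param cells_per_cluster_cap Cells subsampled per cluster per bootstrap;
#'   caps the rank-sum test sizes so large clusters do not dominate.
#' @param dbscan_eps_mads DBSCAN neighbourhood radius, in units of the MAD of
#'   the score distribution.
#' @param dbscan_min_samples DBSCAN core-point threshold (neighbourhood
#'   count, the point itself included).
#' @param seed Integer seed; all bootstrap randomness derives from it.
#' @return A list of class `marker_config`.
#' @export
marker_config <- function(n_b = 4, n_bs = 100, n_min = 28, n_max = 35,
                          cells_per_cluster_cap = 100,
                          dbscan_eps_mads = 3, dbscan_min_samples = 5,
                          seed = 1L) {
  cfg <- list(n_b = as.integer(n_b), n_bs = as.integer(n_bs),
              n_min = as.integer(n_min), n_max = as.integer(n_max),
              cells_per_cluster_cap = as.integer(cells_per_cluster_cap),
              dbscan_eps_mads = as.numeric(dbscan_eps_mads),
              dbscan_min_samples = as.integer(dbscan_min_samples),
              seed = as.integer(seed))
  with(cfg, {
    if (n_min > n_max) stop("n_min must be <= n_max")
    if (any(c(n_b, n_bs, n_min, n_max, cells_per_cluster_cap,
              dbscan_min_samples) < 1))
      stop("all counts in marker_config must be >= 1")
    if (dbscan_eps_mads <= 0) stop("dbscan_eps_mads must be positive")
  })
  structure(cfg, class = "marker_config")
}

# one-sided Mann-Whitney (target > background) per gene column, normal
# approximation with tie and continuity correction, matching
# wilcox.test(exact = FALSE, correct = TRUE, alternative = "greater").
# mat: cells x genes, first n1 rows are the target cells.
mw_greater_pvals <- function(mat, n1) {
  .mw_greater_pvals_cpp(mat, as.integer(n1))
}

# deterministic per-cluster seed stream derived from the config seed
cluster_seed <- function(cfg, ref, cluster) {
  k <- match(cluster, ref$cluster_levels)
  (cfg$seed %% 100000L) * 10000L + k * 131L
}

#' Bootstrap Wilcoxon marker scores for one cluster
#'
#' For each of `n_bs` bootstrap repetitions: draw `n_b` background clusters
#' uniformly without replacement, subsample up to `cells_per_cluster_cap`
#' cells from the target and from each background cluster, and score every
#' gene with a one-sided Wilcoxon rank-sum test (target cells > pooled
#' background cells) on cell-level CPM. The aggregated score is the median
#' over bootstraps of `-log10(p)` (p floored at 1e-300); genes whose median
#' target-minus-background mean difference is not positive are zeroed, so
#' only overexpression can qualify a marker.
#'
#' @param ref An [sc_reference()].
#' @param cluster Target cluster label.
#' @param cfg A [marker_config()].
#' @param cpm Optional precomputed cell CPM matrix (cells x genes).
#' @return Tibble with columns `gene_id`, `score`, `median_diff`, sorted by
#'   descending score with lexicographic gene-id tie-break.
#' @export
bootstrap_scores <- function(ref, cluster, cfg = marker_config(),
                             cpm = NULL) {
  stopifnot(inherits(ref, "sc_reference"), inherits(cfg, "marker_config"))
  if (!cluster %in% ref$cluster_levels) stop("unknown cluster: ", cluster)
  others <- setdiff(ref$cluster_levels, cluster)
  if (length(others) < cfg$n_b)
    stop("need at least n_b = ", cfg$n_b, " candidate background clusters, ",
         "found ", length(others))
  if (is.null(cpm)) cpm <- cell_cpm(ref)

  cells_of <- split(seq_along(ref$clusters), ref$clusters)
  target_cells <- cells_of[[cluster]]
  G <- ncol(cpm)
  logp <- diffs <- matrix(0, cfg$n_bs, G)

  old <- .Random.seed_guard(cluster_seed(cfg, ref, cluster))
  on.exit(old(), add = TRUE)
  for (b in seq_len(cfg$n_bs)) {
    bg_clusters <- sample(others, cfg$n_b)
    t_idx <- cap_sample(target_cells, cfg$cells_per_cluster_cap)
    b_idx <- unlist(lapply(cells_of[bg_clusters], cap_sample,
                           cfg$cells_per_cluster_cap), use.names = FALSE)
    sub <- cpm[c(t_idx, b_idx), , drop = FALSE]
    pb <- mw_greater_pvals(sub, length(t_idx))
    logp[b, ] <- -log10(pmax(pb, 1e-300))
    diffs[b, ] <- colMeans(sub[seq_along(t_idx), , drop = FALSE]) -
      colMeans(sub[-seq_along(t_idx), , drop = FALSE])
  }
  score <- apply(logp, 2, stats::median)
  med_diff <- apply(diffs, 2, stats::median)
  score[med_diff <= 0] <- 0

  out <- tibble::tibble(gene_id = ref$gene_ids, score = score,
                        median_diff = med_diff)
  out[order(-out$score, out$gene_id), ]
}

cap_sample <- function(idx, cap) {
  if (length(idx) <= cap) idx else sample(idx, cap)
}

# set the RNG to a known state and return a restorer
.Random.seed_guard <- function(seed) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }
}

#' One-dimensional DBSCAN
#'
#' Classic DBSCAN specialised to points on the line: core points have at
#' least `min_samples` points (themselves included) within `eps`; chains of
#' core points closer than `eps` form clusters; non-core points within `eps`
#' of a core point join its cluster (nearest core wins); everything else is
#' noise (label 0).
#'
#' @param x Numeric vector of 1-D points.
#' @param eps Neighbourhood radius (> 0).
#' @param min_samples Core-point neighbourhood count threshold.
#' @return Integer vector of cluster labels aligned with `x`; 0 marks noise.
#' @export
dbscan_1d <- function(x, eps, min_samples) {
  stopifnot(eps > 0, min_samples >= 1)
  n <- length(x)
  if (n == 0) return(integer(0))
  o <- order(x)
  xs <- x[o]
  # neighbour counts within eps via binary search on the sorted values
  lo <- findInterval(xs - eps, xs, left.open = TRUE) + 1
  hi <- findInterval(xs + eps, xs)
  is_core <- (hi - lo + 1) >= min_samples

  labels_sorted <- integer(n)
  cl <- 0L
  core_pos <- which(is_core)
  if (length(core_pos) > 0) {
    gaps <- c(TRUE, diff(xs[core_pos]) > eps)
    core_cl <- cumsum(gaps)
    cl <- max(core_cl)
    labels_sorted[core_pos] <- core_cl
    # border points: nearest core within eps
    non_core <- which(!is_core)
    if (length(non_core) > 0) {
      core_x <- xs[core_pos]
      pos <- findInterval(xs[non_core], core_x)
      left <- pmax(pos, 1L)
      right <- pmin(pos + 1L, length(core_x))
      dl <- abs(xs[non_core] - core_x[left])
      dr <- abs(xs[non_core] - core_x[right])
      use_left <- dl <= dr
      nearest <- ifelse(use_left, left, right)
      dist <- pmin(dl, dr)
      reach <- dist <= eps
      labels_sorted[non_core[reach]] <- core_cl[nearest[reach]]
    }
  }
  labels <- integer(n)
  labels[o] <- labels_sorted
  labels
}

#' Select an optimal marker list from a score table by outlier analysis
#'
#' Runs DBSCAN on the one-dimensional score distribution with
#' `eps = dbscan_eps_mads * MAD(positive scores)` (floored at 1e-6; genes
#' with zero score are the uninformative majority and carry no scale
#' information). The bulk of
#' uninformative genes forms the dominant density cluster; candidate markers
#' are the noise points scoring above that cluster's maximum — the genes
#' whose scores are density outliers on the high side. The candidate set is
#' then clipped to the `[n_min, n_max]` band: truncated to the top `n_max` by
#' score, or extended with the next-highest-scoring positive genes up to
#' `n_min`. If fewer than `n_min` genes score positively, all positive-score
#' genes are returned with a warning.
#'
#' @param scores Score table from [bootstrap_scores()] (columns `gene_id`,
#'   `score`).
#' @param cfg A [marker_config()].
#' @return Tibble with `rank`, `gene_id`, `score`, ordered by descending
#'   score (gene id breaks ties).
#' @export
dbscan_outlier_select <- function(scores, cfg = marker_config()) {
  scores <- tibble::as_tibble(scores)
  if (nrow(scores) == 0) stop("empty score table")
  stopifnot(all(c("gene_id", "score") %in% names(scores)))
  scores <- scores[order(-scores$score, scores$gene_id), ]

  positive <- scores[scores$score > 0, ]
  if (nrow(positive) < cfg$n_min) {
    warning("only ", nrow(positive), " genes with positive score ",
            "(n_min = ", cfg$n_min, "); returning all of them")
    sel <- positive
  } else {
    # scale from the positive scores: most genes score exactly 0 (no
    # overexpression), which would collapse a whole-vector MAD to 0
    eps <- cfg$dbscan_eps_mads * max(stats::mad(positive$score), 1e-6)
    labels <- dbscan_1d(scores$score, eps, cfg$dbscan_min_samples)
    candidates <- scores[integer(0), ]
    if (any(labels > 0)) {
      main <- as.integer(names(which.max(table(labels[labels > 0]))))
      top_of_main <- max(scores$score[labels == main])
      candidates <- scores[labels == 0 & scores$score > top_of_main, ]
    } else {
      candidates <- positive  # everything is noise: rely on the clip below
    }
    candidates <- candidates[candidates$score > 0, ]
    if (nrow(candidates) > cfg$n_max) {
      sel <- candidates[seq_len(cfg$n_max), ]
    } else if (nrow(candidates) < cfg$n_min) {
      extra <- positive[!positive$gene_id %in% candidates$gene_id, ]
      sel <- rbind(candidates, extra[seq_len(cfg$n_min - nrow(candidates)), ])
    } else {
      sel <- candidates
    }
  }
  sel <- sel[order(-sel$score, sel$gene_id), ]
  tibble::tibble(rank = seq_len(nrow(sel)), gene_id = sel$gene_id,
                 score = sel$score)
}

#' Select marker genes for every cluster
#'
#' Applies [bootstrap_scores()] and [dbscan_outlier_select()] to each cluster
#' in turn, then resolves genes selected by several clusters by keeping each
#' gene only in its highest-scoring cluster (ties go to the lexicographically
#' first cluster label), so that signature rows are unique. The
#' pre-deduplication lists are preserved in the `pre_dedup` attribute.
#'
#' @param ref An [sc_reference()].
#' @param cfg A [marker_config()]; its `seed` drives every bootstrap draw.
#' @return A tibble of class `marker_set` with columns `cluster`, `rank`,
#'   `gene_id`, `score`; attributes `config` (the `marker_config`) and
#'   `pre_dedup` (the per-cluster lists before deduplication).
#' @export
select_all_markers <- function(ref, cfg = marker_config()) {
  stopifnot(inherits(ref, "sc_reference"))
  cpm <- cell_cpm(ref)
  per_cluster <- lapply(ref$cluster_levels, function(k) {
    sc <- bootstrap_scores(ref, k, cfg, cpm = cpm)
    sel <- dbscan_outlier_select(sc, cfg)
    tibble::tibble(cluster = k, sel)
  })
  pre <- dplyr::bind_rows(per_cluster)

  # duplicate genes go to their best cluster; ties to the first label
  dedup <- pre[order(pre$gene_id, -pre$score, pre$cluster), ]
  dedup <- dedup[!duplicated(dedup$gene_id), ]
  out <- dedup[order(match(dedup$cluster, ref$cluster_levels),
                     -dedup$score, dedup$gene_id), ]
  out <- dplyr::group_by(out, .data$cluster)
  out <- dplyr::mutate(out, rank = dplyr::row_number())
  out <- dplyr::ungroup(out)
  out <- out[, c("cluster", "rank", "gene_id", "score")]

  structure(out, class = c("marker_set", class(out)),
            config = cfg, pre_dedup = pre)
}
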