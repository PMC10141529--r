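# deterministic toy reference: counts chosen by hand so group-by means and
# CVs can be recomputed independently in the tests
toy_reference <- function() {
  counts <- rbind(
    c(10, 0, 5, 1),   # A / s1
    c(12, 0, 3, 1),   # A / s1
    c(8, 2, 4, 2),    # A / s2
    c(10, 2, 6, 2),   # A / s2
    c(0, 20, 1, 1),   # B / s1
    c(2, 18, 1, 3),   # B / s1
    c(0, 22, 3, 1),   # B / s2
    c(1, 19, 1, 3),   # B / s2
    c(5, 5, 10, 0),   # C / s1
    c(5, 5, 12, 0),   # C / s2
    c(6, 4, 9, 1),    # C / s2
    c(4, 6, 11, 1))   # C / s1
  dimnames(counts) <- list(sprintf("cell%02d", 1:12), paste0("g", 1:4))
  sc_reference(counts,
               clusters = rep(c("A", "B", "C"), each = 4),
               subjects = c("s1", "s1", "s2", "s2",
                            "s1", "s1", "s2", "s2",
                            "s1", "s2", "s2", "s1"))
}

# small simulated reference for pipeline-level tests; fast (~1 s)
small_sim_ref <- function(seed = 7, marker_fold = 8, n_clusters = 4) {
  simulate_reference(simulation_config(
    n_genes = 300, n_clusters = n_clusters, n_subjects = 2,
    cells_per_cluster_per_subject = 15, markers_per_cluster = 8,
    marker_fold = marker_fold, seed = seed))
}

small_marker_config <- function(seed = 7, n_b = 2, ...) {
  marker_config(n_b = n_b, n_bs = 10, n_min = 5, n_max = 10,
                cells_per_cluster_cap = 30, seed = seed, ...)
}

# independent O(n^2) DBSCAN oracle (graph flood-fill over core points,
# border points to nearest core, ties to the lower cluster id)
naive_dbscan_1d <- function(x, eps, min_samples) {
  n <- length(x)
  d <- abs(outer(x, x, "-"))
  core <- rowSums(d <= eps) >= min_samples
  labels <- integer(n)
  cl <- 0L
  for (i in order(x)) {
    if (!core[i] || labels[i] != 0) next
    cl <- cl + 1L
    frontier <- i
    labels[i] <- cl
    while (length(frontier) > 0) {
      nb <- which(core & labels == 0 &
                    apply(d[, frontier, drop = FALSE] <= eps, 1, any))
      labels[nb] <- cl
      frontier <- nb
    }
  }
  for (i in which(!core)) {
    near <- which(core & d[i, ] <= eps)
    if (length(near) > 0) {
      best <- near[order(d[i, near], labels[near])][1]
      labels[i] <- labels[best]
    }
  }
  labels
}

# exhaustive simplex grid search minimizing the same weighted objective the
# NNLS solves (after renormalization); step on the 3-simplex
grid_search_simplex3 <- function(y, B, w, step = 0.01) {
  best <- NULL
  best_obj <- Inf
  for (a in seq(0, 1, by = step)) {
    for (b in seq(0, 1 - a, by = step)) {
      p <- c(a, b, 1 - a - b)
      # profile out the overall scale: objective at the best s >= 0
      bp <- as.numeric(B %*% p)
      den <- sum(w * bp^2)
      s <- if (den > 0) max(0, sum(w * y * bp) / den) else 0
      obj <- sum(w * (y - s * bp)^2)
      if (obj < best_obj) {
        best_obj <- obj
        best <- p
      }
    }
  }
  best
}

expect_simplex_columns <- function(P, tol = 1e-8) {
  expect_true(all(P >= -1e-12))
  expect_true(all(abs(colSums(P) - 1) <= tol))
}
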