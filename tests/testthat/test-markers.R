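test_that("marker config validates its bounds", {
  expect_error(marker_config(n_min = 10, n_max = 5), "n_min")
  expect_error(marker_config(n_bs = 0), ">= 1")
  expect_error(marker_config(dbscan_eps_mads = 0), "positive")
})

test_that("bootstrap scores agree with wilcox.test on every gene", {
  # n_b = K - 1, n_bs = 1, no cap: the procedure reduces to one global
  # one-vs-rest Wilcoxon test per gene
  ref <- small_sim_ref(seed = 3)
  cfg <- marker_config(n_b = 3, n_bs = 1, n_min = 2, n_max = 5,
                       cells_per_cluster_cap = 1000, seed = 1)
  sc <- bootstrap_scores(ref, "C2", cfg)

  cpm <- ref$counts / rowSums(ref$counts) * 1e6
  tgt <- ref$clusters == "C2"
  set.seed(14)
  for (g in sample(ref$gene_ids, 25)) {
    got <- sc$score[sc$gene_id == g]
    if (mean(cpm[tgt, g]) - mean(cpm[!tgt, g]) <= 0) {
      expect_equal(got, 0)
    } else {
      p <- suppressWarnings(
        stats::wilcox.test(cpm[tgt, g], cpm[!tgt, g],
                           alternative = "greater", exact = FALSE,
                           correct = TRUE)$p.value)
      expect_equal(got, -log10(max(p, 1e-300)), tolerance = 1e-12)
    }
  }
})

test_that("complete separation yields the closed-form rank-sum score", {
  # one gene at a fixed CPM in every target cell and absent elsewhere:
  # every bootstrap sees the same complete separation at the same sizes
  n_per <- 20
  K <- 4
  counts <- matrix(0, n_per * K, 3,
                   dimnames = list(sprintf("c%02d", 1:(n_per * K)),
                                   c("marker", "fillA", "fillB")))
  counts[, "fillA"] <- 50
  counts[, "fillB"] <- 50
  tgt <- 1:n_per
  counts[tgt, "marker"] <- 100
  counts[tgt, "fillA"] <- 0  # keep totals equal so marker CPM is constant
  ref <- sc_reference(counts, clusters = rep(paste0("K", 1:K), each = n_per),
                      subjects = rep(c("s1", "s2"), n_per * K / 2))
  cfg <- marker_config(n_b = 2, n_bs = 5, n_min = 1, n_max = 2,
                       cells_per_cluster_cap = 100, seed = 42)
  sc <- bootstrap_scores(ref, "K1", cfg)

  # oracle: normal-approximation rank-sum p for 20 vs 40 fully separated
  x <- c(rep(1, n_per), rep(0, 2 * n_per))
  p <- stats::wilcox.test(x[1:n_per], x[-(1:n_per)], alternative = "greater",
                          exact = FALSE, correct = TRUE)$p.value
  expect_equal(sc$score[sc$gene_id == "marker"], -log10(p),
               tolerance = 1e-10)
})

test_that("flat genes never score and background checks are enforced", {
  ref <- small_sim_ref(seed = 4)
  const_ref <- sc_reference(cbind(a = rep(5, 8), b = rep(7, 8)),
                            clusters = rep(c("A", "B"), each = 4),
                            subjects = rep(c("s1", "s2"), 4))
  sc <- bootstrap_scores(const_ref, "A",
                         marker_config(n_b = 1, n_bs = 3, n_min = 1,
                                       n_max = 1, seed = 1))
  expect_true(all(sc$score == 0))

  expect_error(bootstrap_scores(ref, "C1", marker_config(n_b = 5, seed = 1)),
               "background")
  expect_error(bootstrap_scores(ref, "nope", marker_config(seed = 1)),
               "unknown cluster")
})

test_that("few-background enumeration brackets the aggregated score", {
  # with K = 3 and n_b = 1 there are exactly 2 possible background choices;
  # the median over bootstraps must lie between the two enumerated scores
  ref <- small_sim_ref(seed = 5, n_clusters = 3)
  cfg <- marker_config(n_b = 1, n_bs = 20, n_min = 2, n_max = 5,
                       cells_per_cluster_cap = 1000, seed = 2)
  sc <- bootstrap_scores(ref, "C1", cfg)

  cpm <- ref$counts / rowSums(ref$counts) * 1e6
  tgt <- ref$clusters == "C1"
  set.seed(15)
  for (g in sample(ref$gene_ids, 10)) {
    enum <- sapply(c("C2", "C3"), function(bg) {
      sel <- ref$clusters == bg
      p <- suppressWarnings(
        stats::wilcox.test(cpm[tgt, g], cpm[sel, g], alternative = "greater",
                           exact = FALSE, correct = TRUE)$p.value)
      -log10(max(p, 1e-300))
    })
    got <- sc$score[sc$gene_id == g]
    if (got > 0)
      expect_true(got >= min(enum) - 1e-9 && got <= max(enum) + 1e-9)
  }
  # determinism under a repeated seed
  expect_identical(sc, bootstrap_scores(ref, "C1", cfg))
})

test_that("1-D DBSCAN matches a naive quadratic implementation", {
  set.seed(31)
  for (i in 1:25) {
    n <- sample(5:80, 1)
    x <- round(c(rnorm(n, 0, 1), rnorm(sample(0:10, 1), 8, 0.2)), 2)
    eps <- runif(1, 0.05, 1.5)
    ms <- sample(2:6, 1)
    expect_identical(dbscan_1d(x, eps, ms), naive_dbscan_1d(x, eps, ms),
                     label = sprintf("case %d (n=%d eps=%.2f ms=%d)",
                                     i, length(x), eps, ms))
  }
})

test_that("outlier selection isolates a planted high-score block", {
  set.seed(8)
  scores <- tibble::tibble(
    gene_id = sprintf("g%04d", 1:2000),
    score = c(30 + 3 * (1:30), abs(rnorm(1970, 0.5, 0.3))))
  cfg <- marker_config(n_min = 28, n_max = 35, seed = 1)
  sel <- dbscan_outlier_select(scores, cfg)
  expect_setequal(sel$gene_id, sprintf("g%04d", 1:30))
  expect_equal(sel$score, sort(sel$score, decreasing = TRUE))
  expect_equal(sel$rank, seq_len(nrow(sel)))
})

test_that("outlier selection degenerate and fallback contracts hold", {
  cfg <- marker_config(n_min = 3, n_max = 5, seed = 1)
  # one shared positive score: MAD 0, eps floored, one dense cluster,
  # no outliers -> top n_min by (score, gene_id)
  flat <- tibble::tibble(gene_id = paste0("g", sprintf("%02d", 1:10)),
                         score = rep(2, 10))
  sel <- dbscan_outlier_select(flat, cfg)
  expect_identical(sel$gene_id, c("g01", "g02", "g03"))

  # fewer than n_min positive-score genes: return all of them, warn
  sparse <- tibble::tibble(gene_id = paste0("g", 1:6),
                           score = c(5, 2, 0, 0, 0, 0))
  expect_warning(sel2 <- dbscan_outlier_select(sparse, cfg), "positive")
  expect_identical(sel2$gene_id, c("g1", "g2"))

  expect_error(dbscan_outlier_select(sparse[0, ], cfg), "empty")
})

test_that("marker selection recovers disjoint planted sets and dedups", {
  ref <- small_sim_ref(seed = 6, n_clusters = 2)
  cfg <- small_marker_config(seed = 6, n_b = 1)
  ms <- select_all_markers(ref, cfg)
  planted <- attr(ref, "planted_markers")
  for (k in names(planted)) {
    sel <- ms$gene_id[ms$cluster == k]
    expect_gt(length(intersect(sel, planted[[k]])) /
                length(union(sel, planted[[k]])), 0.6)
  }
  expect_false(anyDuplicated(ms$gene_id) > 0)

  # deterministic: same config, same reference, identical object
  expect_identical(ms, select_all_markers(ref, cfg))

  pre <- attr(ms, "pre_dedup")
  expect_true(all(table(pre$cluster) >= cfg$n_min))
  expect_true(all(table(pre$cluster) <= cfg$n_max))
})

test_that("duplicated markers are assigned to their best-scoring cluster", {
  # 'shared' is expressed 60 in A, 30 in B, 0 in C; with n_b = K - 1 every
  # bootstrap uses both other clusters as background, so it scores highly
  # for A (complete separation) and mildly for B (above C, below A)
  n <- 6
  # per-cell totals all equal 200, so CPM ranks mirror the raw counts
  counts <- cbind(shared = c(rep(60, n), rep(35, n), rep(0, n)),
                  a1 = c(rep(40, n), rep(0, n), rep(0, n)),
                  b1 = c(rep(0, n), rep(40, n), rep(0, n)),
                  pad = c(rep(0, n), rep(25, n), rep(0, n)),
                  c1 = c(rep(0, n), rep(0, n), rep(100, n)),
                  fill = rep(100, 3 * n))
  rownames(counts) <- sprintf("c%02d", 1:(3 * n))
  ref <- sc_reference(counts, clusters = rep(c("A", "B", "C"), each = n),
                      subjects = rep(c("s1", "s2"), 3 * n / 2))
  ms <- select_all_markers(ref, marker_config(n_b = 2, n_bs = 5, n_min = 1,
                                              n_max = 3, seed = 3))
  pre <- attr(ms, "pre_dedup")
  expect_true(all(c("A", "B") %in% pre$cluster[pre$gene_id == "shared"]))
  expect_identical(ms$cluster[ms$gene_id == "shared"], "A")
  expect_false(anyDuplicated(ms$gene_id) > 0)
})

test_that("scaling a marker's target expression never lowers its score", {
  base <- small_sim_ref(seed = 9, n_clusters = 3, marker_fold = 2)
  planted <- attr(base, "planted_markers")
  g <- planted$C1[1]
  cfg <- marker_config(n_b = 1, n_bs = 6, n_min = 2, n_max = 4,
                       cells_per_cluster_cap = 30, seed = 4)
  boosted <- base$counts
  boosted[base$clusters == "C1", g] <- boosted[base$clusters == "C1", g] * 5
  ref_b <- sc_reference(boosted, base$clusters, base$subjects)
  s0 <- bootstrap_scores(base, "C1", cfg)
  s1 <- bootstrap_scores(ref_b, "C1", cfg)
  expect_gte(s1$score[s1$gene_id == g], s0$score[s0$gene_id == g])
})
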