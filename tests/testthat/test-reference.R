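test_that("CPM normalization matches the per-element definition", {
  expect_equal(normalize_cpm(matrix(c(2, 3, 5), ncol = 1)),
               matrix(c(2e5, 3e5, 5e5), ncol = 1))

  already <- matrix(c(4e5, 6e5), ncol = 1)
  expect_equal(normalize_cpm(already), already)

  set.seed(11)
  m <- matrix(sample(0:50, 6), 3, 2, dimnames = list(paste0("g", 1:3),
                                                     c("a", "b")))
  out <- normalize_cpm(m)
  for (j in 1:2) for (i in 1:3)
    expect_equal(out[i, j], m[i, j] / sum(m[, j]) * 1e6)
  expect_identical(rownames(out), rownames(m))
})

test_that("CPM normalization is idempotent and rejects zero columns", {
  set.seed(2)
  m <- matrix(rpois(30, 4) + 1, 6, 5)
  once <- normalize_cpm(m)
  expect_equal(normalize_cpm(once), once, tolerance = 1e-9)

  bad <- cbind(sampleA = c(1, 2), sampleB = c(0, 0))
  expect_error(normalize_cpm(bad), "sampleB")
})

test_that("reference construction enforces its invariants", {
  counts <- matrix(1:12, 4, 3, dimnames = list(paste0("c", 1:4),
                                               paste0("g", 1:3)))
  expect_error(sc_reference(counts, clusters = c("A", "A", "A", "B"),
                            subjects = rep("s1", 4)),
               "at least 2 cells")
  expect_error(sc_reference(counts, clusters = rep("A", 4),
                            subjects = c("s1", NA, "s1", "s1")),
               "exactly one cluster")
  neg <- counts; neg[1, 1] <- -1
  expect_error(sc_reference(neg, rep("A", 4), rep("s1", 4)), "non-negative")
})

test_that("cluster profiles equal brute-force group means of cell CPM", {
  ref <- toy_reference()
  prof <- cluster_profiles(ref)

  cpm <- ref$counts / rowSums(ref$counts) * 1e6
  for (k in c("A", "B", "C")) {
    manual <- colMeans(cpm[ref$clusters == k, ])
    expect_equal(unname(prof$profiles[k, ]), unname(manual))
  }
  # subject-level stack agrees with the (subject, cluster) group-by
  for (i in seq_len(nrow(prof$meta))) {
    sel <- ref$clusters == prof$meta$cluster[i] &
      ref$subjects == prof$meta$subject[i]
    expect_equal(unname(prof$subject_profiles[i, ]),
                 unname(colMeans(cpm[sel, , drop = FALSE])))
    expect_equal(prof$meta$n_cells[i], sum(sel))
  }
})

test_that("cluster profiles hit the stated special cases", {
  counts <- rbind(c(10, 0), c(10, 0), c(5, 0), c(5, 0))
  dimnames(counts) <- list(paste0("c", 1:4), c("g1", "g2"))
  ref <- sc_reference(counts, clusters = rep("A", 4),
                      subjects = c("s1", "s1", "s2", "s2"))
  expect_equal(unname(cluster_profiles(ref)$profiles["A", ]), c(1e6, 0))

  # two subjects with opposite pure profiles pool to 50/50
  counts2 <- rbind(c(10, 0), c(10, 0), c(0, 10), c(0, 10))
  dimnames(counts2) <- list(paste0("c", 1:4), c("g1", "g2"))
  ref2 <- sc_reference(counts2, clusters = rep("A", 4),
                       subjects = c("s1", "s1", "s2", "s2"))
  expect_equal(unname(cluster_profiles(ref2)$profiles["A", ]), c(5e5, 5e5))
})

test_that("cluster profiles are invariant to cell order", {
  ref <- toy_reference()
  set.seed(5)
  perm <- sample(length(ref$cell_ids))
  ref_p <- sc_reference(ref$counts[perm, ], ref$clusters[perm],
                        ref$subjects[perm])
  prof <- cluster_profiles(ref)$profiles
  prof_p <- cluster_profiles(ref_p)$profiles
  # row order follows first appearance, so align labels before comparing
  expect_setequal(rownames(prof_p), rownames(prof))
  expect_equal(prof_p[rownames(prof), ], prof)
})

test_that("gene weights match hand-computed coefficient-of-variation pooling", {
  ref <- toy_reference()
  w <- gene_weights(ref)

  cpm <- ref$counts / rowSums(ref$counts) * 1e6
  manual_w <- sapply(ref$gene_ids, function(g) {
    cv2_cell <- cv2_subj <- c()
    for (k in c("A", "B", "C")) {
      x <- cpm[ref$clusters == k, g]
      cv2_cell <- c(cv2_cell,
                    if (mean(x) > 0) var(x) / mean(x)^2 else NA)
      sm <- tapply(cpm[ref$clusters == k, g], ref$subjects[ref$clusters == k],
                   mean)
      cv2_subj <- c(cv2_subj,
                    if (mean(sm) > 0) var(sm) / mean(sm)^2 else NA)
    }
    1 / (1 + mean(cv2_subj, na.rm = TRUE) + mean(cv2_cell, na.rm = TRUE))
  })
  expect_equal(w, manual_w)
  expect_true(all(w > 0 & w <= 1))
})

test_that("gene weights: constant genes weigh 1 and noise never helps", {
  # a large constant filler keeps per-cell totals nearly fixed, so CPM
  # tracks counts and the CV terms behave predictably
  counts <- cbind(filler = rep(1000, 8), flat = rep(5, 8),
                  vary = c(1, 9, 2, 8, 1, 9, 2, 8))
  rownames(counts) <- paste0("c", 1:8)
  ref <- sc_reference(counts, clusters = rep(c("A", "B"), each = 4),
                      subjects = rep(c("s1", "s2"), 4))
  w <- gene_weights(ref)
  expect_gt(w["flat"], 0.99)
  expect_lt(w["vary"], w["flat"])

  # adding pure noise to one gene's counts lowers (never raises) its weight
  noisy <- counts
  set.seed(9)
  noisy[, "flat"] <- noisy[, "flat"] + rpois(8, 20) * rbinom(8, 1, 0.5)
  ref_n <- sc_reference(noisy, ref$clusters, ref$subjects)
  expect_lte(gene_weights(ref_n)["flat"], w["flat"])
})

test_that("signature assembly restricts, deduplicates and orders rows", {
  ref <- toy_reference()
  markers <- tibble::tibble(
    cluster = c("A", "A", "B", "C"),
    rank = c(1L, 2L, 1L, 1L),
    gene_id = c("g1", "g3", "g2", "g3"))  # g3 chosen by A and C
  sig <- build_signature(ref, markers)
  expect_identical(sig$gene_ids, c("g1", "g3", "g2"))
  expect_identical(unname(sig$marker_cluster["g3"]), "A")
  expect_identical(sig$cluster_labels, c("A", "B", "C"))
  prof <- cluster_profiles(ref)$profiles
  expect_equal(sig$values, t(prof[, sig$gene_ids]))

  expect_error(build_signature(ref, tibble::tibble(
    cluster = "A", rank = 1L, gene_id = "nope")), "nope")
})

test_that("exclusive per-cluster markers give a diagonal-dominant signature", {
  counts <- 10 * cbind(c(1, 1, 0, 0, 0, 0), c(0, 0, 1, 1, 0, 0),
                       c(0, 0, 0, 0, 1, 1), c(1, 1, 1, 1, 1, 1))
  dimnames(counts) <- list(paste0("c", 1:6), paste0("g", 1:4))
  ref <- sc_reference(counts, clusters = rep(c("A", "B", "C"), each = 2),
                      subjects = rep(c("s1", "s2"), 3))
  sig <- build_signature(ref, tibble::tibble(
    cluster = c("A", "B", "C"), rank = 1L, gene_id = c("g1", "g2", "g3")))
  v <- sig$values
  for (i in 1:3) expect_true(all(v[i, i] > v[i, -i]))
})

test_that("group signature pools member clusters and collapses to identity", {
  ref <- toy_reference()
  markers <- tibble::tibble(cluster = c("A", "B", "C"), rank = 1L,
                            gene_id = c("g1", "g2", "g3"))
  sig <- build_signature(ref, markers)

  trivial <- singleton_tree(c("A", "B", "C"))
  gsig <- group_signature(sig, ref, trivial)
  expect_equal(unname(gsig$values), unname(sig$values))

  tree <- cluster_tree(list(AB = c("A", "B"), CC = "C"))
  gsig2 <- group_signature(sig, ref, tree)
  cpm <- ref$counts / rowSums(ref$counts) * 1e6
  manual <- colMeans(cpm[ref$clusters %in% c("A", "B"), sig$gene_ids])
  expect_equal(unname(gsig2$values[, "AB"]), unname(manual))
  # equal cell counts: pooled mean equals the unweighted mean of members
  expect_equal(unname(gsig2$values[, "AB"]),
               unname((sig$values[, "A"] + sig$values[, "B"]) / 2))

  expect_error(group_signature(sig, ref,
                               cluster_tree(list(g = c("A", "B", "D")))),
               "D")
  expect_error(group_signature(sig, ref, cluster_tree(list(g = c("A", "B")))),
               "does not cover")
})
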