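#' Construct an annotated single-cell reference
#'
#' Bundles a cells-by-genes count matrix with per-cell cluster and subject
#' labels. This is the reference object the whole deconvolution pipeline
#' consumes: clusters define the cell types whose proportions are estimated,
#' subjects define the biological replicates used to weight genes by their
#' cross-subject stability.
#'
#' @param counts Non-negative numeric matrix, cells in rows, genes in columns.
#'   Sparse matrices (from [Matrix::readMM()]) are densified. Row and column
#'   names, when present, must agree with `cell_ids` / `gene_ids`.
#' @param clusters Character vector, one cluster label per cell.
#' @param subjects Character vector, one subject (donor) label per cell.
#' @param gene_ids,cell_ids Optional identifier vectors; default to the
#'   dimnames of `counts`.
#' @return An object of class `sc_reference`: a list with elements `counts`
#'   (dense matrix, cells x genes), `gene_ids`, `cell_ids`, `clusters`,
#'   `subjects`, and `cluster_levels` (unique cluster labels in order of first
#'   appearance).
#' @examples
#' counts <- matrix(rpois(60, 5), nrow = 6,
#'                  dimnames = list(paste0("c", 1:6), paste0("g", 1:10)))
#' ref <- sc_reference(counts,
#'                     clusters = rep(c("A", "B"), each = 3),
#'                     subjects = rep(c("s1", "s2"), 3))
#' ref
#' @export
sc_reference <- function(counts, clusters, subjects,
                         gene_ids = colnames(counts),
                         cell_ids = rownames(counts)) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(ncol(counts)))
  if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_len(nrow(counts)))
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  clusters <- as.character(clusters)
  subjects <- as.character(subjects)

  if (length(gene_ids) != ncol(counts))
    stop("`gene_ids` length does not match the number of gene columns")
  if (length(cell_ids) != nrow(counts))
    stop("`cell_ids` length does not match the number of cell rows")
  if (anyDuplicated(gene_ids)) stop("duplicate gene ids in reference")
  if (anyDuplicated(cell_ids)) stop("duplicate cell ids in reference")
  if (length(clusters) != nrow(counts) || length(subjects) != nrow(counts))
    stop("`clusters` and `subjects` must have one entry per cell")
  if (anyNA(clusters) || anyNA(subjects))
    stop("every cell needs exactly one cluster and one subject label")
  if (!all(is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and non-negative")
  tab <- table(clusters)
  if (any(tab < 2))
    stop("every cluster needs at least 2 cells; offending: ",
         paste(names(tab)[tab < 2], collapse = ", "))

  dimnames(counts) <- list(cell_ids, gene_ids)
  structure(
    list(counts = counts, gene_ids = gene_ids, cell_ids = cell_ids,
         clusters = clusters, subjects = subjects,
         cluster_levels = unique(clusters)),
    class = "sc_reference"
  )
}

#' @export
print.sc_reference <- function(x, ...) {
  cat("<sc_reference> ", length(x$cell_ids), " cells x ", length(x$gene_ids),
      " genes; ", length(x$cluster_levels), " clusters, ",
      length(unique(x$subjects)), " subjects\n", sep = "")
  invisible(x)
}

#' Define a two-level cluster tree
#'
#' Groups cluster labels into named coarse groups for the tree-guided
#' deconvolution: proportions are first estimated across groups, then within
#' each group across its member clusters. The groups must partition the
#' cluster label set.
#'
#' @param groups Named list of character vectors; each element is one group,
#'   its value the member cluster labels.
#' @return An object of class `cluster_tree` (the validated named list).
#' @examples
#' cluster_tree(list(tumor = c("CMS1", "CMS2", "CMS3", "CMS4"),
#'                   crypt = c("stem_TA", "goblet", "intermediate"),
#'                   enterocyte = c("mature_ent1", "mature_ent2")))
#' @export
cluster_tree <- function(groups) {
  if (!is.list(groups) || length(groups) == 0)
    stop("`groups` must be a non-empty list of cluster label vectors")
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    names(groups) <- paste0("G", seq_along(groups))
  groups <- lapply(groups, as.character)
  if (any(lengths(groups) == 0)) stop("every group must be non-empty")
  all_labels <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(all_labels))
    stop("cluster labels appear in more than one group: ",
         paste(unique(all_labels[duplicated(all_labels)]), collapse = ", "))
  structure(groups, class = "cluster_tree")
}

#' Trivial tree with one singleton group per cluster
#'
#' @param cluster_labels Character vector of cluster labels.
#' @return A `cluster_tree` whose groups are the clusters themselves; the
#'   tree-guided fit collapses to the flat fit under this tree.
#' @export
singleton_tree <- function(cluster_labels) {
  cluster_tree(stats::setNames(as.list(cluster_labels), cluster_labels))
}

check_tree_partition <- function(tree, cluster_labels) {
  members <- unlist(tree, use.names = FALSE)
  missing <- setdiff(members, cluster_labels)
  if (length(missing) > 0)
    stop("tree labels not present in the reference/signature: ",
         paste(missing, collapse = ", "))
  uncovered <- setdiff(cluster_labels, members)
  if (length(uncovered) > 0)
    stop("tree does not cover clusters: ", paste(uncovered, collapse = ", "))
  invisible(TRUE)
}

#' Counts-per-million normalization
#'
#' Scales every column of a genes-by-samples (or, transposed, genes-by-cells)
#' matrix to sum to one million. All deconvolution algebra in this package is
#' done on this common linear scale so that bulk samples and reference
#' profiles are directly comparable.
#'
#' @param mat Non-negative numeric matrix, genes in rows, samples in columns.
#' @return Matrix of the same shape with each column summing to 1e6.
#' @examples
#' normalize_cpm(matrix(c(2, 3, 5), ncol = 1))
#' @export
normalize_cpm <- function(mat) {
  mat <- as.matrix(mat)
  if (any(mat < 0)) stop("negative values are not allowed")
  cs <- colSums(mat)
  if (any(cs <= 0)) {
    bad <- colnames(mat)[cs <= 0]
    if (is.null(bad)) bad <- which(cs <= 0)
    stop("column(s) with zero total: ", paste(bad, collapse = ", "))
  }
  sweep(mat, 2, cs / 1e6, "/")
}

# per-cell CPM, cells x genes; cells with zero totals are an error because a
# cell with no counts carries no expression information
cell_cpm <- function(ref) {
  rs <- rowSums(ref$counts)
  if (any(rs <= 0))
    stop("cell(s) with zero total counts: ",
         paste(ref$cell_ids[rs <= 0], collapse = ", "))
  ref$counts / rs * 1e6
}

#' Per-cluster and per-subject mean expression profiles
#'
#' Computes, on the CPM scale, the pooled mean profile of every cluster (the
#' columns of the signature matrix before marker restriction) and the mean
#' profile of every (subject, cluster) pair with at least one cell (the input
#' to the cross-subject gene weights).
#'
#' @param ref An [sc_reference()].
#' @return A list with `profiles` (clusters x genes matrix of mean cell CPM),
#'   `subject_profiles` (rows = observed (subject, cluster) pairs), `meta`
#'   (tibble indexing `subject_profiles`: cluster, subject, n_cells), and
#'   `single_subject_clusters` (labels of clusters seen in only one subject).
#' @export
cluster_profiles <- function(ref) {
  stopifnot(inherits(ref, "sc_reference"))
  cpm <- cell_cpm(ref)
  labs <- ref$cluster_levels
  profiles <- matrix(0, length(labs), ncol(cpm),
                     dimnames = list(labs, ref$gene_ids))
  for (k in labs) {
    idx <- which(ref$clusters == k)
    if (length(idx) == 0) stop("cluster has no cells: ", k)
    profiles[k, ] <- colMeans(cpm[idx, , drop = FALSE])
  }

  key <- paste(ref$subjects, ref$clusters, sep = "\r")
  combos <- unique(key)
  sp <- matrix(0, length(combos), ncol(cpm),
               dimnames = list(combos, ref$gene_ids))
  n_cells <- integer(length(combos))
  for (i in seq_along(combos)) {
    idx <- which(key == combos[i])
    sp[i, ] <- colMeans(cpm[idx, , drop = FALSE])
    n_cells[i] <- length(idx)
  }
  parts <- strsplit(combos, "\r", fixed = TRUE)
  meta <- tibble::tibble(
    subject = vapply(parts, `[`, "", 1),
    cluster = vapply(parts, `[`, "", 2),
    n_cells = n_cells
  )
  subj_per_cluster <- tapply(meta$subject, meta$cluster,
                             function(s) length(unique(s)))
  single <- names(subj_per_cluster)[subj_per_cluster < 2]

  list(profiles = profiles, subject_profiles = sp, meta = meta,
       single_subject_clusters = single)
}

#' Gene reliability weights from cross-subject and cross-cell variation
#'
#' Each gene g is weighted by `w_g = 1 / (1 + CV2_subj(g) + CV2_cell(g))`,
#' where `CV2_subj` is the squared coefficient of variation of the
#' subject-level cluster-mean CPM of g (averaged over clusters with at least
#' two subjects) and `CV2_cell` is the within-cluster cell-level squared CV
#' (averaged over clusters). Stable housekeeping-like genes get weights near
#' 1; genes volatile across donors or across cells within a cell type are
#' down-weighted in the least-squares fit. Genes never observed get the
#' minimum weight seen among expressed genes.
#'
#' @param ref An [sc_reference()].
#' @param genes Character vector of gene ids (must exist in `ref`); default
#'   all genes.
#' @param profiles Optional precomputed [cluster_profiles()] output.
#' @return Named numeric vector of weights in (0, 1].
#' @export
gene_weights <- function(ref, genes = ref$gene_ids, profiles = NULL) {
  stopifnot(inherits(ref, "sc_reference"))
  missing <- setdiff(genes, ref$gene_ids)
  if (length(missing) > 0)
    stop("genes absent from reference: ", paste(missing, collapse = ", "))
  if (is.null(profiles)) profiles <- cluster_profiles(ref)
  if (length(profiles$single_subject_clusters) > 0)
    warning("cluster(s) observed in a single subject contribute no ",
            "cross-subject variation: ",
            paste(profiles$single_subject_clusters, collapse = ", "))

  cpm <- cell_cpm(ref)[, genes, drop = FALSE]
  labs <- ref$cluster_levels

  cv2_subj <- cv2_cell <- matrix(NA_real_, length(labs), length(genes),
                                 dimnames = list(labs, genes))
  for (k in labs) {
    idx <- ref$clusters == k
    x <- cpm[idx, , drop = FALSE]
    m <- colMeans(x)
    v <- apply(x, 2, stats::var)
    cc <- ifelse(m > 0, v / m^2, NA_real_)
    cv2_cell[k, ] <- cc

    rows <- profiles$meta$cluster == k
    if (sum(rows) >= 2) {
      sp <- profiles$subject_profiles[rows, genes, drop = FALSE]
      ms <- colMeans(sp)
      vs <- apply(sp, 2, stats::var)
      cv2_subj[k, ] <- ifelse(ms > 0, vs / ms^2, NA_real_)
    } else {
      cv2_subj[k, ] <- 0  # single-subject cluster: no subject axis
    }
  }
  mean_na <- function(m) {
    out <- colMeans(m, na.rm = TRUE)
    out[is.nan(out)] <- NA_real_
    out
  }
  s2 <- mean_na(cv2_subj)
  c2 <- mean_na(cv2_cell)
  expressed <- colSums(cpm) > 0
  w <- 1 / (1 + ifelse(is.na(s2), 0, s2) + ifelse(is.na(c2), 0, c2))
  if (any(!expressed)) {
    if (!any(expressed)) stop("no expressed gene among `genes`")
    w[!expressed] <- min(w[expressed])
  }
  stats::setNames(w, genes)
}

#' Build the signature matrix B over selected marker genes
#'
#' Restricts the cluster mean-CPM profiles to the union of the per-cluster
#' marker genes and attaches the gene reliability weights. Row order is
#' stable: clusters in reference order, markers within a cluster by rank;
#' a gene selected by several clusters appears once, under the cluster it was
#' assigned to.
#'
#' @param ref An [sc_reference()].
#' @param markers A marker set from [select_all_markers()], or any tibble with
#'   columns `cluster`, `rank`, `gene_id`.
#' @param profiles Optional precomputed [cluster_profiles()] output.
#' @param weights Optional precomputed [gene_weights()] vector over the
#'   marker genes.
#' @return An object of class `signature_matrix`: list with `values`
#'   (marker-genes x clusters matrix, CPM scale), `gene_ids`,
#'   `cluster_labels`, `gene_weights`, `marker_cluster` (named map gene ->
#'   selecting cluster).
#' @export
build_signature <- function(ref, markers, profiles = NULL, weights = NULL) {
  stopifnot(inherits(ref, "sc_reference"))
  markers <- tibble::as_tibble(markers)
  stopifnot(all(c("cluster", "rank", "gene_id") %in% names(markers)))
  absent <- setdiff(unique(markers$gene_id), ref$gene_ids)
  if (length(absent) > 0)
    stop("marker gene(s) absent from reference: ",
         paste(absent, collapse = ", "))

  ord <- order(match(markers$cluster, ref$cluster_levels), markers$rank)
  m <- markers[ord, ]
  m <- m[!duplicated(m$gene_id), ]

  if (is.null(profiles)) profiles <- cluster_profiles(ref)
  values <- t(profiles$profiles[, m$gene_id, drop = FALSE])
  if (any(rowSums(values) == 0))
    stop("marker gene(s) with all-zero signature row: ",
         paste(m$gene_id[rowSums(values) == 0], collapse = ", "))
  if (is.null(weights))
    weights <- gene_weights(ref, m$gene_id, profiles = profiles)
  weights <- weights[m$gene_id]

  structure(
    list(values = values, gene_ids = m$gene_id,
         cluster_labels = ref$cluster_levels,
         gene_weights = weights,
         marker_cluster = stats::setNames(m$cluster, m$gene_id)),
    class = "signature_matrix"
  )
}

#' @export
print.signature_matrix <- function(x, ...) {
  cat("<signature_matrix> ", length(x$gene_ids), " marker genes x ",
      length(x$cluster_labels), " ",
      if (!is.null(attr(x, "grouped"))) "groups" else "clusters", "\n",
      sep = "")
  invisible(x)
}

#' Collapse a signature to cluster groups
#'
#' Builds the coarse (level-1) signature for the tree-guided fit: one column
#' per group, equal to the pooled mean CPM profile over all cells of the
#' group's member clusters, over the same marker rows as `sig`.
#'
#' @param sig A [build_signature()] result.
#' @param ref The [sc_reference()] the signature was built from.
#' @param tree A [cluster_tree()] partitioning `sig$cluster_labels`.
#' @return A `signature_matrix` whose columns are the tree groups.
#' @export
group_signature <- function(sig, ref, tree) {
  stopifnot(inherits(sig, "signature_matrix"), inherits(ref, "sc_reference"),
            inherits(tree, "cluster_tree"))
  check_tree_partition(tree, sig$cluster_labels)
  cpm <- cell_cpm(ref)[, sig$gene_ids, drop = FALSE]
  values <- matrix(0, length(sig$gene_ids), length(tree),
                   dimnames = list(sig$gene_ids, names(tree)))
  for (g in names(tree)) {
    idx <- ref$clusters %in% tree[[g]]
    if (!any(idx)) stop("group has no cells: ", g)
    values[, g] <- colMeans(cpm[idx, , drop = FALSE])
  }
  out <- structure(
    list(values = values, gene_ids = sig$gene_ids,
         cluster_labels = names(tree),
         gene_weights = sig$gene_weights,
         marker_cluster = sig$marker_cluster),
    class = "signature_matrix"
  )
  attr(out, "grouped") <- TRUE
  out
}
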