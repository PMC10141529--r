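#' Read a bulk expression matrix from TSV/CSV
#'
#' Expects gene identifiers in the first column and sample identifiers in
#' the header. Duplicate gene rows are collapsed by summation (with a
#' warning); negative or non-numeric entries are errors.
#'
#' @param path File path; the delimiter is inferred from the extension
#'   (`.csv` = comma, anything else tab).
#' @return Genes x samples numeric matrix with dimnames.
#' @export
read_bulk <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          colClasses = "character", quote = "")
  if (ncol(df) < 2) stop("malformed header in ", path,
                         ": need a gene column plus at least one sample")
  genes <- df[[1]]
  vals <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow(vals), ncol(vals),
                                 dimnames = dimnames(vals)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop("non-numeric value at gene '", genes[bad[1]], "', sample '",
         colnames(num)[bad[2]], "'")
  }
  if (any(num < 0)) {
    bad <- which(num < 0, arr.ind = TRUE)[1, ]
    stop("negative value at gene '", genes[bad[1]], "', sample '",
         colnames(num)[bad[2]], "'")
  }
  if (anyDuplicated(genes)) {
    n_dup <- sum(duplicated(genes))
    warning(n_dup, " duplicated gene id(s) collapsed by sum")
    num <- rowsum(num, genes, reorder = FALSE)
  } else {
    rownames(num) <- genes
  }
  if (anyDuplicated(colnames(num))) stop("duplicate sample ids in ", path)
  num
}

#' Write a bulk expression matrix as TSV
#'
#' @param mat Genes x samples matrix with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bulk <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a single-cell reference from Matrix Market or dense TSV files
#'
#' The matrix is cells x genes, either a Matrix Market triplet file
#' accompanied by `genes_path` (one gene id per line, first column used) and
#' a cell annotation table, or a dense TSV with cell ids in the first
#' column (then `genes_path` may be omitted). The cell annotation TSV needs
#' columns `cell_id`, `cluster`, `subject`; cells missing from the
#' annotation are dropped with a message.
#'
#' @param matrix_path Counts matrix (`.mtx` or dense TSV).
#' @param cells_path Cell annotation TSV.
#' @param genes_path Gene id file (required for `.mtx`).
#' @return An [sc_reference()].
#' @export
read_reference <- function(matrix_path, cells_path, genes_path = NULL) {
  ann <- utils::read.table(cells_path, header = TRUE, sep = "\t",
                           colClasses = "character", quote = "")
  need <- c("cell_id", "cluster", "subject")
  if (!all(need %in% names(ann)))
    stop("cell annotation must have columns: ", paste(need, collapse = ", "))

  if (grepl("\\.mtx$", matrix_path, ignore.case = TRUE)) {
    if (is.null(genes_path)) stop("`genes_path` is required for .mtx input")
    m <- as.matrix(Matrix::readMM(matrix_path))
    genes <- utils::read.table(genes_path, header = FALSE, sep = "\t",
                               colClasses = "character", quote = "")[[1]]
    if (length(genes) != ncol(m))
      stop("gene file length (", length(genes),
           ") does not match matrix columns (", ncol(m), ")")
    if (nrow(ann) != nrow(m))
      stop("cell annotation rows (", nrow(ann),
           ") do not match matrix rows (", nrow(m), ")")
    cell_ids <- ann$cell_id
  } else {
    df <- utils::read.table(matrix_path, header = TRUE, sep = "\t",
                            check.names = FALSE, quote = "")
    cell_ids <- as.character(df[[1]])
    m <- as.matrix(df[, -1, drop = FALSE])
    genes <- colnames(m)
  }
  dimnames(m) <- list(cell_ids, genes)

  keep <- cell_ids %in% ann$cell_id
  if (any(!keep))
    message(sum(!keep), " cell(s) without annotation dropped")
  if (!any(keep)) stop("no matrix cell id matches the annotation (",
                       nrow(ann), " annotated, ", length(cell_ids),
                       " in matrix)")
  m <- m[keep, , drop = FALSE]
  ann <- ann[match(rownames(m), ann$cell_id), ]
  sc_reference(m, clusters = ann$cluster, subjects = ann$subject)
}

#' Write a single-cell reference as Matrix Market + annotation files
#'
#' @param ref An [sc_reference()].
#' @param dir Output directory (created if needed). Writes `matrix.mtx`
#'   (cells x genes triplets), `genes.tsv`, `cells.tsv`.
#' @return The directory path, invisibly.
#' @export
write_reference <- function(ref, dir) {
  stopifnot(inherits(ref, "sc_reference"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::Matrix(ref$counts, sparse = TRUE),
                  file.path(dir, "matrix.mtx"))
  writeLines(ref$gene_ids, file.path(dir, "genes.tsv"))
  utils::write.table(
    data.frame(cell_id = ref$cell_ids, cluster = ref$clusters,
               subject = ref$subjects),
    file.path(dir, "cells.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(dir)
}

#' Read a cluster tree from YAML or JSON
#'
#' The file maps group names to lists of cluster labels.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return A [cluster_tree()].
#' @export
read_tree <- function(path) {
  obj <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  cluster_tree(lapply(obj, as.character))
}

#' Write a marker set as TSV
#'
#' Columns: cluster, rank, gene_id, score.
#'
#' @param markers A [select_all_markers()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_markers <- function(markers, path) {
  utils::write.table(as.data.frame(markers)[, c("cluster", "rank",
                                                "gene_id", "score")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a marker set TSV
#'
#' @param path TSV written by [write_markers()].
#' @return Tibble with columns cluster, rank, gene_id, score.
#' @export
read_markers <- function(path) {
  tibble::as_tibble(utils::read.table(path, header = TRUE, sep = "\t",
                                      quote = "",
                                      colClasses = c("character", "integer",
                                                     "character", "numeric")))
}

#' Run the full deconvolution pipeline to disk
#'
#' Marker selection, signature construction, tree-guided deconvolution, and
#' (when ground truth is supplied) recovery evaluation, with every output
#' written under `out_dir`: `markers.tsv`, `proportions.tsv`, `diag.json`,
#' and `run_manifest.json` (input checksums, configuration, seed, package
#' version — enough to reproduce the run). Identical inputs and seed give
#' byte-identical outputs; on error, partial outputs are removed.
#'
#' @param bulk_path Bulk matrix TSV/CSV.
#' @param ref_matrix_path,ref_cells_path,ref_genes_path Reference files, as
#'   in [read_reference()].
#' @param out_dir Output directory.
#' @param tree_path Optional cluster tree YAML/JSON; `NULL` = flat fit.
#' @param cfg A [marker_config()].
#' @param truth Optional clusters x samples matrix of true proportions; adds
#'   an `evaluation` block to the diagnostics.
#' @return Invisibly, a list with the in-memory results (`markers`,
#'   `signature`, `estimate`, optional `evaluation`, `paths`).
#' @export
run_pipeline <- function(bulk_path, ref_matrix_path, ref_cells_path,
                         ref_genes_path = NULL, out_dir,
                         tree_path = NULL, cfg = marker_config(),
                         truth = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- file.path(out_dir, c("markers.tsv", "proportions.tsv",
                                  "diag.json", "run_manifest.json"))
  ok <- FALSE
  on.exit(if (!ok) unlink(outputs), add = TRUE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  bulk <- stage("read_bulk", read_bulk(bulk_path))
  ref <- stage("read_reference",
               read_reference(ref_matrix_path, ref_cells_path,
                              ref_genes_path))
  tree <- if (!is.null(tree_path)) stage("read_tree", read_tree(tree_path))
          else NULL

  markers <- stage("markers", select_all_markers(ref, cfg))
  sig <- stage("signature", build_signature(ref, markers))
  gsig <- if (!is.null(tree)) stage("signature",
                                    group_signature(sig, ref, tree))
          else NULL
  est <- stage("deconvolve", tree_deconvolve(bulk, sig, tree, gsig))
  evaluation <- if (!is.null(truth))
    stage("evaluate", evaluate_recovery(est, as.matrix(truth)))

  write_markers(markers, outputs[1])
  utils::write.table(
    data.frame(cluster = rownames(est$proportions), est$proportions,
               check.names = FALSE),
    outputs[2], sep = "\t", quote = FALSE, row.names = FALSE)

  diag <- list(samples = est$diagnostics,
               gene_overlap = est$gene_overlap)
  if (!is.null(evaluation)) diag$evaluation <- evaluation
  jsonlite::write_json(diag, outputs[3], auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)

  inputs <- c(bulk = bulk_path, ref_matrix = ref_matrix_path,
              ref_cells = ref_cells_path)
  if (!is.null(ref_genes_path)) inputs["ref_genes"] <- ref_genes_path
  if (!is.null(tree_path)) inputs["tree"] <- tree_path
  manifest <- list(
    inputs = as.list(inputs),
    input_md5 = as.list(tools::md5sum(unname(inputs))),
    config = unclass(cfg),
    seed = cfg$seed,
    package_version = as.character(utils::packageVersion("treedeconv")))
  jsonlite::write_json(manifest, outputs[4], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  ok <- TRUE
  invisible(list(markers = markers, signature = sig, estimate = est,
                 evaluation = evaluation, paths = outputs))
}
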