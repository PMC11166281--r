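#' Construct a hierarchical reference atlas
#'
#' Bundles normalized reference expression profiles with leaf labels, the
#' label hierarchy, per-type marker lists and the level-1 marker panel.
#' Validates that every leaf maps to exactly one ancestor per level.
#'
#' @param profiles Normalized genes x reference-cells matrix.
#' @param labels Tibble with `barcode` and one column per level
#'   (`level1`, `level2`, ..., finest = leaf).
#' @param tree Tibble mapping each leaf to its ancestors (one column per
#'   level).
#' @param markers Tibble of per-type marker genes (`level3`, `gene_id`).
#' @param panel Character vector: the level-1 marker panel (39 genes in the
#'   default generative model).
#' @return A list of class `reference_atlas`.
#' @export
reference_atlas <- function(profiles, labels, tree, markers, panel) {
  levels_ <- grep("^level", names(tree), value = TRUE)
  leaf <- levels_[length(levels_)]
  if (anyDuplicated(tree[[leaf]]))
    stop("leaf labels must be unique in the tree", call. = FALSE)
  for (lv in levels_) {
    chk <- unique(tree[, c(leaf, lv)])
    if (anyDuplicated(chk[[leaf]]))
      stop("leaf maps to more than one ancestor at ", lv, call. = FALSE)
  }
  if (!all(labels[[leaf]] %in% tree[[leaf]]))
    stop("reference labels outside the tree", call. = FALSE)
  if (ncol(profiles) != nrow(labels) ||
      !identical(colnames(profiles), labels$barcode))
    stop("profiles and labels misaligned", call. = FALSE)
  structure(list(profiles = profiles, labels = labels, tree = tree,
                 markers = markers, panel = panel, levels = levels_,
                 leaf_level = leaf),
            class = "reference_atlas")
}

#' @export
print.reference_atlas <- function(x, ...) {
  cat("<reference_atlas> ", ncol(x$profiles), " cells, ",
      nrow(x$tree), " leaf types, levels: ",
      paste(x$levels, collapse = " > "), "\n", sep = "")
  invisible(x)
}

#' Hierarchical weighted-kNN cell annotation with confidence scores
#'
#' Fits a PCA on the reference over its most variable genes, projects query
#' cells into the same space, and lets the `k` nearest reference cells vote
#' with Gaussian kernel weights (bandwidth = distance to the k-th
#' neighbour). The leaf score of a cell is the winning leaf's weight
#' fraction; at each coarser level the score of a candidate label is the
#' summed weight fraction of all leaves descending from it, the label is the
#' argmax (ties broken lexicographically) and cells scoring below
#' `unclassified_threshold` are flagged unclassified.
#'
#' @param query Normalized genes x cells matrix.
#' @param atlas A [reference_atlas()].
#' @param k Neighbours (default 30).
#' @param n_pcs PCs (default 20).
#' @param n_var_genes Variable genes for the reference PCA (default 2000).
#' @param unclassified_threshold Score below which a cell is unclassified
#'   (default 0.5).
#' @return A tibble: `barcode`, `level`, `label`, `score`, `unclassified`.
#' @export
annotate_cells <- function(query, atlas, k = 30, n_pcs = 20,
                           n_var_genes = 2000, unclassified_threshold = 0.5) {
  shared <- intersect(rownames(query), rownames(atlas$profiles))
  if (length(shared) < 50)
    stop("query and atlas share fewer than 50 genes", call. = FALSE)
  ref <- atlas$profiles[shared, , drop = FALSE]
  qry <- query[shared, , drop = FALSE]
  v <- rowVars_fast(ref)
  vg <- order(-v, rownames(ref))[seq_len(min(n_var_genes, length(shared)))]
  fit <- pca_fit(t(ref[vg, , drop = FALSE]), n_pcs)
  qs <- pca_project(t(qry[vg, , drop = FALSE]), fit)
  k <- min(k, ncol(ref))
  nn <- knn_search(qs, fit$scores, k)
  leaf <- atlas$leaf_level
  leaf_labels <- atlas$labels[[leaf]]
  leaves <- sort(unique(atlas$tree[[leaf]]))
  n <- nrow(qs)
  # Gaussian kernel weights; bandwidth = distance to the k-th neighbour
  bw <- nn$dist[, k]
  bw[bw == 0] <- 1e-12
  w <- exp(-(nn$dist / bw)^2 / 2)
  wsum <- rowSums(w)
  # per-cell leaf weight fractions
  leaf_frac <- matrix(0, n, length(leaves), dimnames = list(NULL, leaves))
  lab_idx <- matrix(match(leaf_labels[nn$index], leaves), n, k)
  for (j in seq_len(k)) {
    m <- cbind(seq_len(n), lab_idx[, j])
    leaf_frac[m] <- leaf_frac[m] + w[, j]
  }
  leaf_frac <- leaf_frac / wsum
  out <- vector("list", length(atlas$levels))
  for (li in seq_along(atlas$levels)) {
    lv <- atlas$levels[li]
    anc <- atlas$tree[[lv]][match(leaves, atlas$tree[[leaf]])]
    groups <- sort(unique(anc))
    sc <- leaf_frac %*% outer(anc, groups, "==")
    colnames(sc) <- groups
    win <- max.col(sc, ties.method = "first")  # columns sorted: lexicographic
    score <- sc[cbind(seq_len(n), win)]
    out[[li]] <- tibble::tibble(
      barcode = rownames(qs) %||% colnames(query),
      level = li, label = groups[win], score = as.numeric(score),
      unclassified = score < unclassified_threshold)
  }
  dplyr::bind_rows(out)
}

rowVars_fast <- function(m) {
  m2 <- if (methods::is(m, "sparseMatrix")) {
    Matrix::rowMeans(m^2) - Matrix::rowMeans(m)^2
  } else rowMeans(m^2) - rowMeans(m)^2
  n <- ncol(m)
  as.numeric(m2) * n / max(n - 1, 1)
}

#' Fraction of annotated (classified) cells per level
#'
#' @param result Output of [annotate_cells()], optionally joined with
#'   grouping columns.
#' @param group_by Optional character vector of grouping columns.
#' @return A tibble with `level`, optional groups, `n`, and
#'   `annotated_fraction` in \[0, 1\].
#' @export
annotated_fraction <- function(result, group_by = NULL) {
  if (!nrow(result)) stop("empty annotation result", call. = FALSE)
  result |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c("level", group_by)))) |>
    dplyr::summarise(n = dplyr::n(),
                     annotated_fraction = mean(!.data$unclassified),
                     .groups = "drop")
}

#' Deterministic 2-D PCA embedding
#'
#' First two principal components of the variable-gene submatrix, with
#' loadings sign-fixed (largest-magnitude loading positive). A stand-in
#' embedding for silhouette-style cluster diagnostics.
#'
#' @param norm Normalized genes x cells matrix (>= 3 cells).
#' @param n_var_genes Variable genes (default 2000).
#' @param max_fit_cells The PCA is fitted on at most this many evenly
#'   spaced cells and the remainder are projected (deterministic; keeps
#'   large cohorts tractable).
#' @return A tibble: `barcode`, `dim1`, `dim2`.
#' @export
compute_embedding <- function(norm, n_var_genes = 2000,
                              max_fit_cells = 5000) {
  if (ncol(norm) < 3) stop("need at least 3 cells", call. = FALSE)
  v <- rowVars_fast(norm)
  if (all(v == 0)) stop("constant matrix has no embedding", call. = FALSE)
  vg <- order(-v, rownames(norm))[seq_len(min(n_var_genes, nrow(norm)))]
  x <- t(norm[vg, , drop = FALSE])
  n <- nrow(x)
  if (n > max_fit_cells) {
    idx <- unique(round(seq(1, n, length.out = max_fit_cells)))
    fit <- pca_fit(as.matrix(x[idx, , drop = FALSE]), 2)
    sc <- pca_project(x, fit)
  } else {
    fit <- pca_fit(x, 2)
    sc <- fit$scores
  }
  tibble::tibble(barcode = colnames(norm), dim1 = sc[, 1], dim2 = sc[, 2])
}
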